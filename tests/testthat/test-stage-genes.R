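test_that("coefficient of variation follows sd/mean with a zero-mean guard", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5), g3 = c(-1, 1, 0))
  colnames(m) <- paste0("s", 1:3)
  expect_warning(st <- computeCV(m, paste0("s", 1:3)), "zero mean")
  expect_equal(st$mean[st$gene == "g1"], 2)
  expect_equal(st$sd[st$gene == "g1"], 1)
  expect_equal(st$cv[st$gene == "g1"], 0.5)
  expect_equal(st$cv[st$gene == "g2"], 0)
  expect_true(is.na(st$cv[st$gene == "g3"]))
})

test_that("CV filter keeps the top quantile of |CV| with boundary ties", {
  st <- data.frame(gene = paste0("g", 1:4), cv = c(0.1, 0.2, 0.3, 0.4))
  expect_setequal(cvFilter(st, 0.5), c("g3", "g4"))
  expect_setequal(cvFilter(st, 1), paste0("g", 1:4))
  tied <- data.frame(gene = paste0("g", 1:4), cv = rep(0.2, 4))
  expect_setequal(cvFilter(tied, 0.5), paste0("g", 1:4))
  allna <- data.frame(gene = "g1", cv = NA_real_)
  expect_error(cvFilter(allna), "defined CV")
})

test_that("unshrunk statistic equals the ordinary pooled two-sample t-test", {
  set.seed(8)
  m <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:20)))
  grp <- paste0("s", 1:8); ctl <- paste0("s", 9:20)
  de <- differentialExpression(m, grp, ctl, shrink = FALSE)
  for (g in c("g01", "g17", "g42")) {
    tt <- t.test(m[g, grp], m[g, ctl], var.equal = TRUE)
    expect_lt(abs(de$p_value[de$gene == g] - tt$p.value), 1e-9)
    expect_lt(abs(de$log_fc[de$gene == g] -
                    (mean(m[g, grp]) - mean(m[g, ctl]))), 1e-12)
  }
})

test_that("moderated statistic agrees with the reference empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(12)
  m <- matrix(rnorm(300 * 16), 300, 16,
              dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:16)))
  m[1:10, 1:6] <- m[1:10, 1:6] + 1.5
  grp <- paste0("s", 1:6); ctl <- paste0("s", 7:16)
  de <- differentialExpression(m, grp, ctl, shrink = TRUE)
  design <- cbind(1, c(rep(1, 6), rep(0, 10)))
  fit <- limma::eBayes(limma::lmFit(m[, c(grp, ctl)], design))
  lp <- fit$p.value[, 2]
  expect_equal(unname(fit$coefficients[de$gene, 2]), de$log_fc,
               tolerance = 1e-9)
  # prior estimation differs in detail; p-values must agree closely
  expect_gt(cor(-log10(de$p_value), -log10(lp[de$gene])), 0.995)
  expect_lt(max(abs(de$p_value - lp[de$gene])), 0.05)
  # the same genes are called at the usual threshold
  expect_gt(mean((de$p_value < 0.05) == (lp[de$gene] < 0.05)), 0.98)
})

test_that("identical groups give zero effect; planted shifts are recovered", {
  m <- rbind(g1 = rep(1:4, 2))
  colnames(m) <- paste0("s", 1:8)
  de <- differentialExpression(rbind(m, g2 = rnorm(8), g3 = rnorm(8)),
                               paste0("s", 1:4), paste0("s", 5:8))
  expect_equal(de$log_fc[de$gene == "g1"], 0)

  sim <- simulateStageData(nGenes = 400, groupSizes = c(40, 20, 30),
                           nDeEarly = 20, nDeLate = 20, nShared = 10,
                           shift = 2, nBlocks = 0, nPathways = 0, seed = 17)
  md <- sim$metadata
  eS <- md$sample_id[md$phase == "early"]
  cS <- md$sample_id[md$phase == "control"]
  de <- differentialExpression(sim$expression, eS, cS)
  tr <- sim$truth$planted_de
  g <- tr$gene[tr$phase %in% c("early", "both")]
  se <- sqrt(1 / length(eS) + 1 / length(cS))
  expect_true(all(abs(abs(de$log_fc[match(g, de$gene)]) - 2) < 3 * se))
  expect_true(all(de$p_value[match(g, de$gene)] < 0.05))
})

test_that("sample-set misuse is rejected", {
  m <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  expect_error(differentialExpression(m, paste0("s", 1:5), paste0("s", 5:10)),
               "overlap")
  expect_error(differentialExpression(m, "s1", paste0("s", 2:10)),
               ">= 2 samples")
})

test_that("stage set extraction is the thresholded intersection", {
  deE <- data.frame(gene = c("A", "B", "X"), log_fc = c(2, -2, 0.2),
                    p_value = c(0.01, 0.001, 0.5))
  deL <- data.frame(gene = c("B", "C", "X"), log_fc = c(-1.5, 3, 0.1),
                    p_value = c(0.02, 0.001, 0.9))
  sets <- extractStageSets(deE, deL, pCut = 0.05, lfcCut = 1)
  expect_setequal(delta0(sets)$gene, c("A", "B"))
  expect_setequal(delta1(sets)$gene, c("B", "C"))
  d2 <- delta2(sets)
  expect_identical(d2$gene, "B")
  expect_identical(d2$direction_early, "down")
  expect_identical(d2$direction_late, "down")

  # disjoint phases -> empty intersection
  deL2 <- data.frame(gene = c("C"), log_fc = 3, p_value = 0.001)
  expect_identical(nrow(delta2(extractStageSets(deE, deL2))), 0L)

  cnt <- stageSetCounts(sets)
  expect_identical(cnt$total, c(2L, 2L, 1L))
  expect_identical(cnt$up + cnt$down, cnt$total)
})

test_that("delta2 is always contained in delta0 and delta1", {
  set.seed(23)
  for (i in 1:5) {
    n <- 50
    deE <- data.frame(gene = paste0("g", 1:n), log_fc = rnorm(n, sd = 2),
                      p_value = runif(n))
    deL <- data.frame(gene = paste0("g", 1:n), log_fc = rnorm(n, sd = 2),
                      p_value = runif(n))
    sets <- extractStageSets(deE, deL)
    expect_true(all(delta2(sets)$gene %in% delta0(sets)$gene))
    expect_true(all(delta2(sets)$gene %in% delta1(sets)$gene))
  }
})

test_that("null data yield almost no stage-specific calls at |lfc| >= 1", {
  sim <- simulateStageData(nGenes = 2000, groupSizes = c(40, 20, 30),
                           nDeEarly = 0, nDeLate = 0, nShared = 0,
                           nBlocks = 0, nPathways = 0, seed = 19)
  md <- sim$metadata
  de <- differentialExpression(
    sim$expression, md$sample_id[md$phase == "early"],
    md$sample_id[md$phase == "control"])
  deL <- differentialExpression(
    sim$expression, md$sample_id[md$phase == "late"],
    md$sample_id[md$phase == "control"])
  sets <- extractStageSets(de, deL)
  expect_lt(nrow(delta0(sets)), 0.01 * 2000)
  expect_lt(nrow(delta1(sets)), 0.01 * 2000)
})
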