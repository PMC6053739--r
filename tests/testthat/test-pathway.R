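test_that("Fisher enrichment equals the hypergeometric tail", {
  universe <- paste0("g", 1:100)
  coll <- list(full = paste0("g", 1:10),
               none = paste0("g", 91:91),
               half = paste0("g", 6:15))
  query <- paste0("g", 1:10)
  res <- fisherEnrichment(query, coll, universe)
  p <- setNames(res$p_value, res$pathway)
  expect_equal(unname(p["full"]),
               phyper(9, 10, 90, 10, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(unname(p["full"]), 5.776904e-14, tolerance = 1e-6)
  # zero overlap: the vacuous tail is 1
  expect_equal(unname(p["none"]), 1)
  # saturation: query = universe makes every overlap certain
  res2 <- fisherEnrichment(universe, coll, universe)
  expect_true(all(res2$p_value == 1))
  expect_identical(res2$overlap, res2$pathway_size)
  expect_error(fisherEnrichment(query, coll, character(0)), "empty universe")
})

test_that("per-gene ANOVA matches the F oracle and handles degeneracy", {
  set.seed(53)
  n <- 10
  md <- data.frame(sample_id = paste0("s", 1:(3 * n)),
                   phase = rep(c("control", "early", "late"), each = n))
  m <- rbind(sep = c(rnorm(n, 0), rnorm(n, 5), rnorm(n, 10)),
             flat = rep(1, 3 * n),
             null = rnorm(3 * n))
  colnames(m) <- md$sample_id
  p <- geneAnova(m, md)
  expect_lt(p[["sep"]], 1e-10)
  expect_equal(p[["flat"]], 1)

  # cross-check against the standard one-way ANOVA fit
  grp <- factor(md$phase)
  ref <- anova(lm(m["null", ] ~ grp))[["Pr(>F)"]][1]
  expect_equal(unname(p["null"]), ref, tolerance = 1e-12)

  md2 <- md; md2$phase[md2$phase == "early"] <- "late"
  expect_error(geneAnova(m, md2), "no samples of phase")
})

test_that("p-to-Z conversion inverts the normal tail and applies the weight", {
  expect_equal(pToZ(0.5, 1), 0)
  expect_equal(pToZ(0.05, 1), qnorm(0.95), tolerance = 1e-12)
  expect_equal(pToZ(0.05, 1), 1.6449, tolerance = 1e-4)
  expect_equal(pToZ(0.05, 0.5), qnorm(0.95) / 2, tolerance = 1e-12)
  # flooring keeps Z finite
  expect_warning(z <- pToZ(0, 1), "floored")
  expect_equal(z, qnorm(1e-16, lower.tail = FALSE))
  expect_true(is.finite(pToZ(1e-300, 1)))
  expect_error(pToZ(1.2, 1), "> 1")
})

test_that("deviation score equals exhaustive prefix enumeration", {
  expect_equal(deviationScore(3), list(A = 3, t_max = 1L))
  expect_equal(deviationScore(c(3, 1)), list(A = 3, t_max = 1L))
  expect_equal(deviationScore(c(1, 3)), list(A = 3, t_max = 1L))
  expect_equal(deviationScore(rep(1, 4)), list(A = 2, t_max = 4L))
  expect_error(deviationScore(numeric(0)), "empty")

  set.seed(59)
  for (i in 1:200) {
    z <- rnorm(sample(1:50, 1), sd = sample(1:3, 1))
    got <- deviationScore(z)
    want <- prefixMaxOracle(z)
    expect_identical(got$A, want$A)
    expect_identical(got$t_max, want$t_max)
  }
})

test_that("deviation score is order-invariant, homogeneous and monotone", {
  set.seed(61)
  for (i in 1:20) {
    z <- rnorm(12)
    expect_identical(deviationScore(z)$A, deviationScore(sample(z))$A)
    cc <- runif(1, 0.5, 3)
    expect_equal(deviationScore(cc * z)$A, cc * deviationScore(z)$A,
                 tolerance = 1e-12)
    j <- sample(12, 1)
    z2 <- z; z2[j] <- z2[j] + runif(1, 0, 2)
    expect_gte(deviationScore(z2)$A, deviationScore(z)$A)
  }
})

test_that("permutation calibration centers the null and is reproducible", {
  set.seed(67)
  pool <- setNames(rnorm(300), paste0("g", 1:300))

  cal <- calibrateScore(A = 2, k = 5, geneZ = pool, nPerm = 500, seed = 9)
  cal2 <- calibrateScore(A = 2, k = 5, geneZ = pool, nPerm = 500, seed = 9)
  expect_identical(cal, cal2)
  # A at the null mean is corrected to exactly zero
  cal3 <- calibrateScore(A = cal$mu_k, k = 5, geneZ = pool, nPerm = 500,
                         seed = 9)
  expect_equal(cal3$A_corrected, 0)

  # independent re-implementation of the permutation loop, same protocol
  oracle <- local({
    set.seed(9)
    ap <- numeric(500)
    for (i in 1:500) {
      idx <- sample.int(300, 5)
      ap[i] <- prefixMaxOracle(unname(pool)[idx])$A
    }
    list(mu = mean(ap), sigma = sd(ap))
  })
  expect_equal(cal$mu_k, oracle$mu, tolerance = 1e-12)
  expect_equal(cal$sigma_k, oracle$sigma, tolerance = 1e-12)

  const <- setNames(rep(2, 50), paste0("g", 1:50))
  expect_error(calibrateScore(2, 5, const, nPerm = 100, seed = 1),
               "sigma = 0")
  expect_error(calibrateScore(2, 500, pool, nPerm = 100, seed = 1),
               "pool")
})

test_that("a planted pathway dominates size-matched competitors", {
  set.seed(71)
  gz <- setNames(rnorm(200), paste0("g", 1:200))
  top <- names(sort(gz, decreasing = TRUE))[1:10]
  pw <- list(planted = top,
             other1 = sample(names(gz), 10),
             other2 = sample(names(gz), 10))
  res <- scorePathways(pw, gz, nPerm = 400, seed = 5)
  expect_identical(res$pathway[1], "planted")

  # identical member multisets at a shared master seed score identically
  pw2 <- list(a = top, b = top)
  res2 <- scorePathways(pw2, gz, nPerm = 400, seed = 5)
  expect_equal(res2$A[1], res2$A[2])

  # results do not depend on evaluation order
  res3 <- scorePathways(pw[c(3, 1, 2)], gz, nPerm = 400, seed = 5)
  expect_equal(res3[match(res$pathway, res3$pathway), "A_corrected"],
               res$A_corrected)

  expect_message(
    scorePathways(list(planted = top, empty = "absent"), gz,
                  nPerm = 100, seed = 1), "skipped")
})

test_that("per-sample scores follow the running-mean closed forms", {
  m <- rbind(g1 = c(0, 2), g2 = c(0, 2), g3 = c(0, 2), g4 = c(0, 2))
  colnames(m) <- c("s1", "s2")
  w <- setNames(rep(1, 4), rownames(m))
  sc <- sampleScores(m, rownames(m), w, pathway = "P")
  expect_equal(sc$score[sc$sample_id == "s1"], 0)   # all prefixes 0
  expect_equal(sc$score[sc$sample_id == "s2"], 4)   # 2 * sqrt(4)

  # weights rescale the contribution
  w2 <- setNames(rep(0.5, 4), rownames(m))
  expect_equal(sampleScores(m, rownames(m), w2)$score[2], 2)
  expect_error(sampleScores(m, "gX", w), "member genes")
})

test_that("pathway ANOVA flags planted deviation and passes nulls", {
  sim <- simulateStageData(nGenes = 600, groupSizes = c(40, 20, 30),
                           nDeEarly = 40, nDeLate = 40, nShared = 25,
                           shift = 2, nBlocks = 0, nPathways = 10,
                           pathwaySize = 15, nDeviated = 2, seed = 73)
  md <- sim$metadata
  z <- sim$expression
  profs <- do.call(rbind, lapply(names(sim$pathways), function(nm)
    sampleScores(z, sim$pathways[[nm]], weights = NULL, pathway = nm)))
  pa <- pathwayAnova(profs, md)
  planted <- sim$truth$planted_pathways
  expect_true(all(pa$p_value[match(planted, pa$pathway)] < 0.001))

  # constant scores: degenerate guard
  const <- data.frame(pathway = "K", sample_id = md$sample_id, score = 1)
  expect_equal(pathwayAnova(const, md)$p_value, 1)
})
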