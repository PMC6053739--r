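#' One-sided Fisher over-representation test per pathway
#'
#' Tests each pathway of the collection (intersected with the gene
#' universe) for over-representation of the query genes, using the
#' hypergeometric upper tail, i.e. the one-sided Fisher exact test on the
#' 2x2 table with margins |query|, |pathway| and |universe|.
#'
#' @param query character, the gene set of interest (subset of
#'   `universe`).
#' @param collection named list of pathways (as from [readGmt()]).
#' @param universe character, the testable gene universe.
#' @param pCut significance threshold for the `significant` flag
#'   (default 0.05).
#' @return data.frame sorted by p-value with columns `pathway`,
#'   `overlap`, `pathway_size`, `p_value`, `significant`.
#' @export
fisherEnrichment <- function(query, collection, universe, pCut = 0.05) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  query <- intersect(unique(as.character(query)), universe)
  N <- length(universe); nq <- length(query)
  res <- lapply(names(collection), function(nm) {
    pw <- intersect(collection[[nm]], universe)
    K <- length(pw)
    ov <- length(intersect(pw, query))
    p <- if (K == 0L) 1 else phyper(ov - 1L, K, N - K, nq,
                                    lower.tail = FALSE)
    data.frame(pathway = nm, overlap = ov, pathway_size = K, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p_value, out$pathway), , drop = FALSE]
  out$significant <- out$p_value < pCut
  rownames(out) <- NULL
  out
}

#' One-way ANOVA of expression across the three phases, per gene
#'
#' Fixed-effects one-way ANOVA F-test of each gene's expression across
#' the control/early/late groups, computed from the group sums of
#' squares. Genes that are constant within every group and across groups
#' (zero between- and within-variance) get `p = 1` by convention; zero
#' within- but positive between-variance gives a vanishing p-value.
#'
#' @param x normalized matrix or [StageExperiment-class].
#' @param metadata data.frame with `sample_id`, `phase` (ignored for a
#'   `StageExperiment`).
#' @param genes genes to test (default all).
#' @return named numeric vector of p-values.
#' @export
geneAnova <- function(x, metadata = NULL, genes = NULL) {
  inp <- .resolveInput(x, metadata)
  mat <- inp$mat
  if (is.null(genes)) genes <- rownames(mat)
  genes <- intersect(rownames(mat), genes)
  groups <- lapply(.PHASES, function(ph)
    .phaseSamples(mat, inp$metadata, ph))
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("each phase needs >= 2 samples")
  m <- mat[genes, unlist(groups), drop = FALSE]
  N <- sum(sizes); k <- length(groups)
  gm <- rowMeans(m)
  ssb <- 0; ssw <- 0
  for (i in seq_along(groups)) {
    sub <- mat[genes, groups[[i]], drop = FALSE]
    mu <- rowMeans(sub)
    ssb <- ssb + sizes[i] * (mu - gm)^2
    ssw <- ssw + rowSums((sub - mu)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- pf(f, k - 1, N - k, lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1          # totally flat gene
  p[ssw == 0 & ssb > 0] <- 1e-300      # perfectly separated groups
  setNames(p, genes)
}

#' Convert a p-value to a network-weighted Z value
#'
#' `Z = qnorm(1 - p)` (upper-tail standard normal quantile), multiplied
#' by the gene's network weight. p-values are floored at 1e-16 before
#' conversion so the Z stays finite; `p <= 0` is floored with a warning
#' and `p > 1` is an error.
#'
#' @param p numeric p-value(s) in (0, 1].
#' @param weight numeric weight(s) in (0, 1], recycled.
#' @return weighted Z value(s).
#' @export
pToZ <- function(p, weight = 1) {
  if (any(p > 1)) stop("p-value > 1")
  if (any(p <= 0)) {
    warning("p-value(s) <= 0 floored at 1e-16")
  }
  p <- pmax(p, 1e-16)
  weight * qnorm(p, lower.tail = FALSE)
}

#' Maximum running-mean deviation score of a Z set
#'
#' Sorts the weighted Z values in decreasing order and returns
#' `A = max over t of (1/sqrt(t)) * sum of the t largest values`,
#' together with the smallest prefix size `t_max` achieving the maximum.
#' The statistic rewards a coherent subset of strongly deviating genes
#' without diluting it by the pathway's full size.
#'
#' @param z numeric vector of weighted Z values (length >= 1; order
#'   irrelevant).
#' @return list with `A` and `t_max`.
#' @export
deviationScore <- function(z) {
  if (!length(z)) stop("empty Z vector")
  zs <- sort(z, decreasing = TRUE)
  cand <- cumsum(zs) / sqrt(seq_along(zs))
  t_max <- which.max(cand)           # smallest t at ties
  list(A = cand[t_max], t_max = t_max)
}

# vectorized null scores: draw `nPerm` gene sets of size k (without
# replacement) from the pool and score each with the running-mean max
.permutationScores <- function(pool, k, nPerm, seed) {
  set.seed(seed)
  npool <- length(pool)
  idx <- vapply(seq_len(nPerm), function(i) sample.int(npool, k),
                integer(k))
  zm <- matrix(pool[idx], nrow = k)
  zm <- apply(zm, 2L, sort, decreasing = TRUE)
  if (k == 1L) return(as.numeric(zm))
  cs <- apply(matrix(zm, nrow = k), 2L, cumsum) / sqrt(seq_len(k))
  apply(cs, 2L, max)
}

#' Calibrate a deviation score against a size-matched permutation null
#'
#' Draws `nPerm` random gene sets of size `k` (without replacement) from
#' the background Z pool, scores each with [deviationScore()], and
#' standardizes the observed score against the mean and standard
#' deviation (n-1) of that null:
#' `A_corrected = (A - mu_k) / sigma_k`. This removes the dependence of
#' the raw score on pathway size.
#'
#' @param A observed score.
#' @param k number of scored member genes.
#' @param geneZ named numeric, the background pool of weighted Z values
#'   (length >= k).
#' @param nPerm number of permutations (default 10000).
#' @param seed integer RNG seed.
#' @return list with `mu_k`, `sigma_k`, `A_corrected`.
#' @export
calibrateScore <- function(A, k, geneZ, nPerm = 10000L, seed = 1L) {
  if (k > length(geneZ)) stop("k exceeds background pool size")
  if (nPerm < 2L) stop("need nPerm >= 2")
  ap <- .permutationScores(as.numeric(geneZ), k, nPerm, seed)
  mu <- mean(ap); sig <- sd(ap)
  if (sig == 0)
    stop("degenerate permutation null (sigma = 0); ",
         "the background Z pool is constant")
  list(mu_k = mu, sigma_k = sig, A_corrected = (A - mu) / sig)
}

# stable 31-bit hash of a pathway name, used to derive independent
# per-pathway permutation streams from one master seed
.nameSeed <- function(name, seed) {
  h <- 0
  for (v in utf8ToInt(name)) h <- (h * 131 + v) %% 1009001
  as.integer((as.numeric(seed) * 2053 + h) %% 2147483647)
}

#' Score a collection of pathways with the calibrated deviation score
#'
#' For each pathway, takes its differentially expressed member genes'
#' weighted Z values, computes the raw running-mean maximum score and
#' calibrates it against the size-matched permutation null drawn from
#' the full background pool. Each pathway gets its own RNG stream
#' derived from the master seed and the pathway name, so results do not
#' depend on evaluation order.
#'
#' @param pathwayGenes named list: per pathway, its DE member gene ids
#'   (typically pathway members intersected with the shared DE set).
#' @param geneZ named numeric, weighted Z per background gene (the pool
#'   for permutations; must cover the scored members).
#' @param nPerm permutations per pathway (default 10000).
#' @param seed master seed.
#' @return data.frame with columns `pathway`, `k`, `A`, `t_max`, `mu_k`,
#'   `sigma_k`, `A_corrected`, sorted by decreasing `A_corrected`.
#'   Pathways with no scored member are skipped with a message.
#' @export
scorePathways <- function(pathwayGenes, geneZ, nPerm = 10000L, seed = 1L) {
  rows <- lapply(names(pathwayGenes), function(nm) {
    z <- geneZ[intersect(pathwayGenes[[nm]], names(geneZ))]
    if (!length(z)) {
      message("pathway ", nm, ": no scored member genes, skipped")
      return(NULL)
    }
    ds <- deviationScore(as.numeric(z))
    cal <- calibrateScore(ds$A, length(z), geneZ, nPerm,
                          seed = .nameSeed(nm, seed))
    data.frame(pathway = nm, k = length(z), A = ds$A, t_max = ds$t_max,
               mu_k = cal$mu_k, sigma_k = cal$sigma_k,
               A_corrected = cal$A_corrected, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no pathway had scored member genes")
  out <- out[order(-out$A_corrected, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample pathway deviation scores
#'
#' For each sample, the pathway's member genes' normalized expression
#' values are multiplied by their network weights, sorted in decreasing
#' order and summarized with the same running-mean maximum statistic as
#' the gene-level score — yielding one deviation score per sample, the
#' quantity whose distribution across phases is screened by
#' [pathwayAnova()].
#'
#' @param mat normalized matrix.
#' @param pathwayGenes character, the pathway's (DE) member genes.
#' @param weights named numeric gene weights (from [degreeWeights()]),
#'   or `NULL` for unweighted scores.
#' @param pathway label recorded in the output.
#' @return data.frame with columns `pathway`, `sample_id`, `score`.
#' @export
sampleScores <- function(mat, pathwayGenes, weights = NULL,
                         pathway = "pathway") {
  genes <- intersect(rownames(mat), pathwayGenes)
  if (!length(genes)) stop("no pathway member genes in the matrix")
  w <- if (is.null(weights)) setNames(rep(1, length(genes)), genes)
       else weights[genes]
  if (anyNA(w)) stop("missing weight for gene(s): ",
                     paste(head(genes[is.na(w)], 5L), collapse = ", "))
  wm <- mat[genes, , drop = FALSE] * as.numeric(w)
  sc <- apply(wm, 2L, function(v) deviationScore(v)$A)
  data.frame(pathway = pathway, sample_id = colnames(mat),
             score = unname(sc), stringsAsFactors = FALSE)
}

#' ANOVA screening of per-sample pathway scores across phases
#'
#' One-way ANOVA of each pathway's per-sample deviation scores across
#' the control/early/late groups; pathways with `p < pCut` are flagged
#' significant.
#'
#' @param profiles data.frame binding one or more [sampleScores()]
#'   outputs (`pathway`, `sample_id`, `score`).
#' @param metadata data.frame with `sample_id`, `phase`.
#' @param pCut significance threshold (default 0.05).
#' @return data.frame with columns `pathway`, `p_value`, `significant`,
#'   sorted by p-value.
#' @export
pathwayAnova <- function(profiles, metadata, pCut = 0.05) {
  metadata <- as.data.frame(metadata)
  ph <- setNames(as.character(metadata$phase), metadata$sample_id)
  rows <- lapply(split(profiles, profiles$pathway), function(df) {
    grp <- factor(ph[df$sample_id], levels = .PHASES)
    if (anyNA(grp)) stop("sample(s) without phase metadata")
    if (any(table(grp) < 2L)) stop("each phase needs >= 2 samples")
    sc <- df$score
    if (var(sc) == 0) {
      p <- 1  # constant scores carry no between-group signal
    } else {
      p <- stats::anova(stats::lm(sc ~ grp))[["Pr(>F)"]][1L]
    }
    data.frame(pathway = df$pathway[1L], p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$pathway), , drop = FALSE]
  out$significant <- out$p_value < pCut
  rownames(out) <- NULL
  out
}
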