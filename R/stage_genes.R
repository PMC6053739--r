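#' Per-gene coefficient of variation over cancer samples
#'
#' `CV = sd / mean`, with mean and standard deviation (n-1) taken over the
#' case (cancer) samples only. Genes whose mean is exactly zero have an
#' undefined CV and are flagged (`cv = NA`) with a warning; they are
#' excluded from ranking by [cvFilter()]. The ratio is scale-dependent:
#' it measures relative fluctuation and is most meaningful on raw
#' (positive) intensities, computed before control-referenced
#' normalization.
#'
#' @param mat numeric matrix (genes x samples).
#' @param caseSamples character, the cancer sample ids (>= 2).
#' @return data.frame with columns `gene`, `mean`, `sd`, `cv`.
#' @export
computeCV <- function(mat, caseSamples) {
  stopifnot(is.matrix(mat))
  caseSamples <- intersect(colnames(mat), caseSamples)
  if (length(caseSamples) < 2L) stop("need >= 2 case samples")
  m <- mat[, caseSamples, drop = FALSE]
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  cv <- ifelse(mu == 0, NA_real_, s / mu)
  if (anyNA(cv))
    warning(sum(is.na(cv)), " gene(s) with zero mean: CV undefined")
  data.frame(gene = rownames(mat), mean = mu, sd = s, cv = cv,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Keep the genes in the top quantile of |CV|
#'
#' Returns the genes whose absolute CV is at or above the
#' `(1 - keepQuantile)` quantile of all defined |CV| values; boundary ties
#' are all kept. With the default `keepQuantile = 0.5` this is the
#' top-half fluctuation filter.
#'
#' @param stats data.frame from [computeCV()].
#' @param keepQuantile fraction of genes to keep, in (0, 1].
#' @return character vector of retained gene ids.
#' @export
cvFilter <- function(stats, keepQuantile = 0.5) {
  stopifnot(keepQuantile > 0, keepQuantile <= 1)
  ok <- !is.na(stats$cv)
  if (!any(ok)) stop("no genes with a defined CV")
  a <- abs(stats$cv[ok])
  cut <- stats::quantile(a, probs = 1 - keepQuantile, names = FALSE,
                         type = 7)
  stats$gene[ok][a >= cut]
}

#' Moderated two-sample differential expression versus controls
#'
#' For each gene, the effect is the difference of group means on the
#' normalized scale (`log_fc = mean(case group) - mean(control)`); the
#' test is a two-sample t-statistic whose pooled variance is shrunk
#' toward a common prior by empirical Bayes. The prior (degrees of
#' freedom `d0` and scale `s0^2`) is estimated by moment matching of the
#' per-gene sample variances to a scaled-F marginal across all tested
#' genes; the moderated variance is the `d0`/`d`-weighted average of
#' prior and per-gene variance and the statistic is referred to a t
#' distribution on `d + d0` degrees of freedom. With `shrink = FALSE`
#' the statistic reduces exactly to the ordinary pooled-variance
#' two-sample t-test.
#'
#' @param mat normalized matrix (genes x samples).
#' @param groupSamples,controlSamples disjoint character vectors of sample
#'   ids, each of length >= 2.
#' @param genes genes to test (default all rows).
#' @param shrink use empirical-Bayes variance shrinkage (default `TRUE`).
#' @return data.frame with columns `gene`, `log_fc`, `t`, `p_value`.
#' @export
differentialExpression <- function(mat, groupSamples, controlSamples,
                                   genes = rownames(mat), shrink = TRUE) {
  stopifnot(is.matrix(mat))
  if (length(intersect(groupSamples, controlSamples)))
    stop("case and control sample sets overlap")
  groupSamples <- intersect(colnames(mat), groupSamples)
  controlSamples <- intersect(colnames(mat), controlSamples)
  if (length(groupSamples) < 2L || length(controlSamples) < 2L)
    stop("need >= 2 samples per side")
  genes <- intersect(rownames(mat), genes)
  if (!length(genes)) stop("no genes to test")
  g <- mat[genes, groupSamples, drop = FALSE]
  c0 <- mat[genes, controlSamples, drop = FALSE]
  n1 <- ncol(g); n0 <- ncol(c0)
  lfc <- rowMeans(g) - rowMeans(c0)
  v1 <- apply(g, 1L, var); v0 <- apply(c0, 1L, var)
  d <- n1 + n0 - 2L
  s2 <- ((n1 - 1L) * v1 + (n0 - 1L) * v0) / d
  if (shrink && length(genes) >= 3L) {
    prior <- .fitVariancePrior(s2, d)
    d0 <- prior$df; s02 <- prior$s2
    s2mod <- if (is.finite(d0)) (d0 * s02 + d * s2) / (d0 + d) else s02
    dfTot <- d + d0
  } else {
    s2mod <- s2
    dfTot <- d
  }
  tstat <- lfc / sqrt(s2mod * (1 / n1 + 1 / n0))
  p <- 2 * pt(-abs(tstat), df = dfTot)
  # a gene constant and identical in both groups: 0/0 -> no evidence
  p[!is.finite(tstat)] <- 1
  tstat[!is.finite(tstat)] <- 0
  data.frame(gene = genes, log_fc = unname(lfc), t = unname(tstat),
             p_value = unname(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

# Moment-match the marginal distribution of per-gene sample variances
# s2 ~ s0^2 * F(d, d0) to estimate the prior (d0, s0^2):
#   E[s2]          = s0^2 * d0 / (d0 - 2)
#   Var/E^2        = 2 * (d + d0 - 2) / (d * (d0 - 4))
# Solving the second for d0 and backing out s0^2 from the first. When
# the empirical dispersion is at or below the no-heterogeneity level the
# prior df is infinite (full shrinkage to the pooled variance).
.fitVariancePrior <- function(s2, d) {
  m1 <- mean(s2)
  vr <- var(s2)
  if (!is.finite(vr) || vr <= 0 || m1 <= 0)
    return(list(df = Inf, s2 = max(m1, .Machine$double.eps)))
  r <- vr / m1^2
  denom <- r * d - 2
  if (denom <= 0) return(list(df = Inf, s2 = m1))
  d0 <- (4 * r * d + 2 * d - 4) / denom
  if (!is.finite(d0) || d0 <= 4) d0 <- 4.01  # keep moments finite
  list(df = d0, s2 = m1 * (d0 - 2) / d0)
}

#' Build the stage-specific gene sets from two DE result tables
#'
#' A gene enters the early set (`delta0`) or the late set (`delta1`) iff
#' its p-value is below `pCut` and `|log_fc| >= lfcCut`; direction is the
#' sign of `log_fc`. The shared set `delta2` is the gene-id intersection,
#' keeping the direction observed in each phase.
#'
#' @param deEarly,deLate data.frames from [differentialExpression()].
#' @param pCut p-value threshold (default 0.05).
#' @param lfcCut absolute effect threshold on the normalized scale
#'   (default 1).
#' @return a [StageGeneSets-class] object.
#' @export
extractStageSets <- function(deEarly, deLate, pCut = 0.05, lfcCut = 1) {
  stopifnot(pCut > 0, pCut < 1, lfcCut >= 0)
  pick <- function(de) {
    sig <- de$p_value < pCut & abs(de$log_fc) >= lfcCut
    data.frame(gene = de$gene[sig],
               direction = ifelse(de$log_fc[sig] > 0, "up", "down"),
               stringsAsFactors = FALSE)
  }
  d0 <- pick(deEarly); d1 <- pick(deLate)
  common <- sort(intersect(d0$gene, d1$gene))
  d2 <- data.frame(gene = common,
                   direction_early = d0$direction[match(common, d0$gene)],
                   direction_late = d1$direction[match(common, d1$gene)],
                   stringsAsFactors = FALSE)
  new("StageGeneSets", delta0 = d0, delta1 = d1, delta2 = d2)
}

#' Count summary of a StageGeneSets object
#'
#' @param sets a [StageGeneSets-class].
#' @return data.frame with one row per set and columns `set`, `total`,
#'   `up`, `down` (for `delta2`, up/down counts follow the early-phase
#'   direction).
#' @export
stageSetCounts <- function(sets) {
  d0 <- delta0(sets); d1 <- delta1(sets); d2 <- delta2(sets)
  data.frame(
    set = c("delta0", "delta1", "delta2"),
    total = c(nrow(d0), nrow(d1), nrow(d2)),
    up = c(sum(d0$direction == "up"), sum(d1$direction == "up"),
           sum(d2$direction_early == "up")),
    down = c(sum(d0$direction == "down"), sum(d1$direction == "down"),
             sum(d2$direction_early == "down")),
    stringsAsFactors = FALSE)
}
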