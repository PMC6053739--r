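#' Pearson correlation between all gene pairs over a sample window
#'
#' @param mat normalized matrix (genes x samples).
#' @param genes genes to correlate (default all rows).
#' @param samples sample window (default all columns); per-phase
#'   correlations are obtained by passing that phase's samples.
#' @return symmetric correlation matrix with unit diagonal. Pairs
#'   involving a gene that is constant over the window are `NA`
#'   (undefined), with a warning.
#' @export
pairwiseCorrelation <- function(mat, genes = rownames(mat),
                                samples = colnames(mat)) {
  stopifnot(is.matrix(mat))
  genes <- intersect(rownames(mat), genes)
  samples <- intersect(colnames(mat), samples)
  if (length(samples) < 3L) stop("need >= 3 samples")
  if (length(genes) < 1L) stop("no genes found in matrix")
  m <- t(mat[genes, samples, drop = FALSE])
  const <- apply(m, 2L, function(v) var(v) == 0)
  r <- suppressWarnings(cor(m, method = "pearson"))
  if (any(const)) {
    warning("constant gene(s) over the window: ",
            paste(head(genes[const], 5L), collapse = ", "))
    r[const, ] <- NA_real_
    r[, const] <- NA_real_
  }
  diag(r) <- 1
  r
}

#' Classify gene pairs by signed correlation threshold
#'
#' Each unordered pair appears once, endpoints in lexicographic order.
#' Classification uses strict inequalities: `positive` when the
#' correlation exceeds `threshold`, `negative` when it is below
#' `-threshold`, otherwise (including values exactly at the threshold and
#' undefined correlations) `none`.
#'
#' @param corr symmetric correlation matrix from [pairwiseCorrelation()].
#' @param phase label recorded in the table.
#' @param threshold correlation threshold in (0, 1), default 0.5.
#' @return data.frame with columns `gene_a`, `gene_b`, `phase`, `r`,
#'   `class`.
#' @export
classifyPairs <- function(corr, phase = "all", threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  g <- rownames(corr)
  idx <- which(upper.tri(corr), arr.ind = TRUE)
  a <- g[idx[, 1L]]; b <- g[idx[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  r <- corr[idx]
  cls <- rep("none", length(r))
  cls[!is.na(r) & r > threshold] <- "positive"
  cls[!is.na(r) & r < -threshold] <- "negative"
  out <- data.frame(gene_a = a, gene_b = b, phase = phase, r = r,
                    class = cls, stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Positive/negative/total pair counts per phase
#'
#' The count summary behind a per-phase correlated-pair table.
#'
#' @param ... one or more pair tables from [classifyPairs()] (or a single
#'   list of them).
#' @return data.frame with columns `phase`, `positive`, `negative`,
#'   `total`.
#' @export
pairCounts <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.data.frame(tabs[[1L]]) == FALSE)
    tabs <- tabs[[1L]]
  do.call(rbind, lapply(tabs, function(tb) {
    data.frame(phase = tb$phase[1L],
               positive = sum(tb$class == "positive"),
               negative = sum(tb$class == "negative"),
               total = sum(tb$class != "none"),
               stringsAsFactors = FALSE)
  }))
}

#' Pairs whose co-expression class is stable across phases
#'
#' A pair is stable when it is classified (non-`none`) with the same sign
#' in every supplied phase table. The result does not depend on the order
#' the tables are given.
#'
#' @param tables list of pair tables from [classifyPairs()], one per
#'   phase (>= 2).
#' @return list with `pairs` (data.frame `gene_a`, `gene_b`, `class`) and
#'   `genes` (character, union of the endpoints).
#' @export
stablePairs <- function(tables) {
  if (length(tables) < 2L) stop("need >= 2 phase tables")
  key <- function(tb) paste(tb$gene_a, tb$gene_b, sep = "\r")
  base <- tables[[1L]]
  keep <- base$class != "none"
  ks <- key(base)[keep]
  cls <- base$class[keep]
  for (tb in tables[-1L]) {
    m <- match(ks, key(tb))
    ok <- !is.na(m) & tb$class[m] == cls
    ks <- ks[ok]; cls <- cls[ok]
  }
  parts <- strsplit(ks, "\r", fixed = TRUE)
  pairs <- data.frame(gene_a = vapply(parts, `[[`, "", 1L),
                      gene_b = vapply(parts, `[[`, "", 2L),
                      class = cls, stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, genes = sort(unique(c(pairs$gene_a, pairs$gene_b))))
}

#' Hierarchical clustering of genes and samples by correlation distance
#'
#' Genes are clustered with distance `1 - r` where `r` is the Pearson
#' correlation of gene profiles across all supplied samples; samples are
#' clustered with distance `1 - r` over the given genes. Average linkage
#' throughout; `hclust`'s deterministic merge order makes the output
#' reproducible.
#'
#' @param mat normalized matrix.
#' @param genes genes to cluster (>= 2).
#' @param samples samples to cluster (default all).
#' @return list with `genes` and `samples` ([stats::hclust] trees) and
#'   `gene_order` / `sample_order` (leaf orders as label vectors).
#' @export
hierarchicalCluster <- function(mat, genes = rownames(mat),
                                samples = colnames(mat)) {
  genes <- intersect(rownames(mat), genes)
  samples <- intersect(colnames(mat), samples)
  if (length(genes) < 2L || length(samples) < 2L)
    stop("need >= 2 genes and >= 2 samples")
  m <- mat[genes, samples, drop = FALSE]
  rg <- suppressWarnings(cor(t(m)))
  rs <- suppressWarnings(cor(m))
  if (anyNA(rg))
    stop("undefined gene correlations (constant genes): ",
         paste(head(genes[apply(is.na(rg), 1L, any)], 5L), collapse = ", "))
  if (anyNA(rs))
    stop("undefined sample correlations")
  hg <- hclust(stats::as.dist(1 - rg), method = "average")
  hs <- hclust(stats::as.dist(1 - rs), method = "average")
  list(genes = hg, samples = hs,
       gene_order = hg$labels[hg$order],
       sample_order = hs$labels[hs$order])
}
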