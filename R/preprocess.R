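#' Remove genes and samples with too many missing values
#'
#' Two-pass filter: genes whose missing fraction exceeds `maxFraction` are
#' dropped first, then samples whose missing fraction over the surviving
#' genes exceeds `maxFraction`. Both comparisons are strict (`>`); row and
#' column order are otherwise preserved.
#'
#' @param mat numeric matrix (genes x samples), `NA` marks missing.
#' @param maxFraction largest tolerated missing fraction, default 0.10.
#' @return the filtered matrix.
#' @export
filterMissing <- function(mat, maxFraction = 0.10) {
  stopifnot(is.matrix(mat), maxFraction >= 0, maxFraction < 1)
  keepGenes <- rowMeans(is.na(mat)) <= maxFraction
  if (!any(keepGenes)) stop("all genes removed by missing-value filter")
  mat <- mat[keepGenes, , drop = FALSE]
  keepSamples <- colMeans(is.na(mat)) <= maxFraction
  if (!any(keepSamples)) stop("all samples removed by missing-value filter")
  mat[, keepSamples, drop = FALSE]
}

#' Impute missing cells with the gene's observed mean
#'
#' Each missing cell is replaced by the mean of that gene's observed
#' values over all samples (not group-restricted); observed cells are
#' untouched.
#'
#' @param mat numeric matrix, every gene with at least one observed value.
#' @return the completed matrix.
#' @export
imputeMissing <- function(mat) {
  stopifnot(is.matrix(mat))
  nObs <- rowSums(!is.na(mat))
  if (any(nObs == 0L))
    stop("gene(s) with no observed values: ",
         paste(head(rownames(mat)[nObs == 0L], 5L), collapse = ", "))
  miss <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(miss)) {
    gm <- rowMeans(mat, na.rm = TRUE)
    mat[miss] <- gm[miss[, 1L]]
  }
  mat
}

#' Z-score normalize every sample against the control group
#'
#' Computes each gene's mean and standard deviation (n-1 convention) over
#' the control samples and transforms every cell as
#' `(x - mean_control) / sd_control`, so that, per gene, the control group
#' has mean 0 and variance 1 and case samples are expressed in control-SD
#' units. A case-group departure from the standard normal then flags the
#' gene as differentially expressed.
#'
#' @param x numeric matrix (genes x samples, no missing values) or a
#'   [StageExperiment-class].
#' @param metadata data.frame with `sample_id`, `phase` (ignored when `x`
#'   is a `StageExperiment`).
#' @return the normalized matrix, with the per-gene control parameters in
#'   attributes `controlMean` and `controlSd` and the reference group in
#'   attribute `reference`.
#' @export
zscoreToControl <- function(x, metadata = NULL) {
  inp <- .resolveInput(x, metadata)
  mat <- inp$mat
  if (anyNA(mat)) stop("missing values present; impute or filter first")
  ctrl <- .phaseSamples(mat, inp$metadata, "control")
  if (length(ctrl) < 2L) stop("need >= 2 control samples")
  cm <- rowMeans(mat[, ctrl, drop = FALSE])
  cs <- apply(mat[, ctrl, drop = FALSE], 1L, sd)
  zero <- cs == 0
  if (any(zero))
    stop("zero control-group standard deviation for gene(s): ",
         paste(head(rownames(mat)[zero], 5L), collapse = ", "))
  out <- (mat - cm) / cs
  attr(out, "controlMean") <- setNames(cm, rownames(mat))
  attr(out, "controlSd") <- setNames(cs, rownames(mat))
  attr(out, "reference") <- "control"
  out
}

#' Full preprocessing pipeline: filter, impute, normalize
#'
#' Applies [filterMissing()], [imputeMissing()] and [zscoreToControl()] in
#' that order (imputation precedes normalization, so case-only missing
#' values are filled on the raw scale).
#'
#' @inheritParams zscoreToControl
#' @param maxMissing missing-fraction threshold, default 0.10.
#' @return list with `matrix` (normalized, complete) and `params`
#'   (data.frame gene, control_mean, control_sd).
#' @export
preprocessExpression <- function(x, metadata = NULL, maxMissing = 0.10) {
  inp <- .resolveInput(x, metadata)
  m <- filterMissing(inp$mat, maxMissing)
  m <- imputeMissing(m)
  z <- zscoreToControl(m, inp$metadata)
  list(matrix = z,
       params = data.frame(gene = rownames(z),
                           control_mean = unname(attr(z, "controlMean")),
                           control_sd = unname(attr(z, "controlSd")),
                           stringsAsFactors = FALSE))
}
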