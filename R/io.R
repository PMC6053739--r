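#' Read a genes-by-samples expression matrix from TSV
#'
#' Expects a tab-separated file with gene identifiers in the first column
#' and sample identifiers in the header row (the usual series-matrix
#' orientation). Empty cells and the configured sentinel denote missing
#' values and are kept as `NA`, never silently zeroed.
#'
#' @param path file path.
#' @param transpose read a samples-by-genes file instead and transpose.
#' @param na character vector of missing-value sentinels (default empty
#'   string and `"NA"`).
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
readExpression <- function(path, transpose = FALSE, na = c("", "NA")) {
  nf <- utils::count.fields(path, sep = "\t", quote = "",
                            blank.lines.skip = FALSE)
  if (length(nf) < 2L) stop("expression file needs a header and >=1 row")
  ragged <- which(nf != nf[1L])
  if (length(ragged))
    stop(sprintf("ragged row at line %d: %d fields, expected %d",
                 ragged[1L], nf[ragged[1L]], nf[1L]))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, na.strings = na,
                          quote = "", stringsAsFactors = FALSE,
                          colClasses = NA)
  ids <- as.character(df[[1L]])
  samples <- colnames(df)[-1L]
  dup <- samples[duplicated(samples)]
  if (length(dup))
    stop("duplicate sample identifier(s): ", paste(unique(dup), collapse = ", "))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate gene identifier(s): ", paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(ids, samples)
  if (transpose) m <- t(m)
  m
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpression()]; missing values are written as empty cells.
#'
#' @param mat numeric matrix with dimnames.
#' @param path output file path.
#' @param digits significant digits to keep (default 15, value-preserving
#'   for a round trip).
#' @export
writeExpression <- function(mat, path, digits = 15L) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  body <- matrix(ifelse(is.na(mat), "", formatC(mat, digits = digits,
                                                format = "g")),
                 nrow(mat), ncol(mat))
  lines <- c(paste(c("gene", colnames(mat)), collapse = "\t"),
             paste(rownames(mat), apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read sample metadata (sample id, phase, optional stage)
#'
#' @param path tab-separated file with header columns `sample_id`, `phase`
#'   and optionally `stage`.
#' @return data.frame with character `sample_id`, factor `phase`
#'   (control/early/late) and character `stage` (`NA` where absent).
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = c("", "NA"))
  if (!all(c("sample_id", "phase") %in% colnames(df)))
    stop("metadata needs columns sample_id, phase")
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(df$phase), .PHASES)
  if (length(bad))
    stop("unknown phase label(s): ", paste(bad, collapse = ", "))
  out <- data.frame(sample_id = as.character(df$sample_id),
                    phase = factor(df$phase, levels = .PHASES),
                    stringsAsFactors = FALSE)
  out$stage <- if ("stage" %in% colnames(df)) as.character(df$stage)
               else NA_character_
  bad <- setdiff(out$stage[!is.na(out$stage)], .STAGES)
  if (length(bad))
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  out
}

#' @rdname readSampleMetadata
#' @param metadata data.frame as returned by [readSampleMetadata()].
#' @param path output file path.
#' @export
writeSampleMetadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one pathway per line, tab-separated fields
#' name, description, member genes. Duplicate members within a line are
#' collapsed; pathway order is preserved.
#'
#' @param path file path.
#' @return named list of character vectors (one per pathway), with the
#'   per-pathway descriptions in `attr(, "description")`.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- list()
    attr(out, "description") <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1L]))
  nm <- vapply(fields, `[[`, "", 1L)
  dup <- nm[duplicated(nm)]
  if (length(dup))
    stop("duplicate pathway name(s): ", paste(unique(dup), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  empty <- !vapply(sets, length, 1L)
  if (any(empty)) stop("empty gene set: ", nm[which(empty)[1L]])
  names(sets) <- nm
  attr(sets, "description") <- setNames(vapply(fields, `[[`, "", 2L), nm)
  sets
}

#' @rdname readGmt
#' @param sets named list of character vectors; an optional
#'   `attr(, "description")` supplies the description field (default `"-"`).
#' @export
writeGmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("-", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a network edge list
#'
#' Three-plus-column tab-separated table `gene_a`, `gene_b`, `r`, `sign`
#' as exported from a [PhaseNetwork-class].
#'
#' @param net a `PhaseNetwork`.
#' @param path file path.
#' @export
writeEdgeList <- function(net, path) {
  utils::write.table(networkEdges(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

# internal: resolve (x, metadata) where x may be a StageExperiment
.resolveInput <- function(x, metadata = NULL) {
  if (is(x, "StageExperiment")) {
    ph <- phaseLabels(x)
    list(mat = exprsMatrix(x),
         metadata = data.frame(sample_id = names(ph),
                               phase = ph,
                               stage = unname(sampleStages(x)),
                               stringsAsFactors = FALSE))
  } else {
    stopifnot(is.matrix(x))
    if (is.null(metadata)) stop("metadata required with a plain matrix")
    list(mat = x, metadata = as.data.frame(metadata))
  }
}

# internal: sample ids of a phase, in matrix column order
.phaseSamples <- function(mat, metadata, phase) {
  ids <- metadata$sample_id[as.character(metadata$phase) %in% phase]
  out <- intersect(colnames(mat), ids)
  if (!length(out))
    stop(sprintf("no samples of phase '%s' present in the matrix",
                 paste(phase, collapse = "/")))
  out
}
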