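#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor cutree dist hclust pf phyper pnorm pt qnorm sd var
#'   setNames aggregate
#' @importFrom utils head tail
NULL

.PHASES <- c("control", "early", "late")
.STAGES <- c("I", "II", "III", "IV")

#' StageExperiment: expression matrix plus phase annotation
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding a
#' genes-by-samples expression matrix (assay `"exprs"`) together with the
#' three-way phase labelling (`control` / `early` / `late`) and, optionally,
#' the clinical stage (`I`--`IV`) in `colData`. Validity enforces the
#' labelling scheme: samples in the early phase may only carry stage I,
#' late-phase samples stages II--IV.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [StageExperiment()] for construction from a matrix and a
#'   metadata table, [phaseLabels()], [sampleStages()].
#' @export
setClass("StageExperiment", contains = "SummarizedExperiment")

setValidity("StageExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if (!"phase" %in% colnames(cd))
    return("colData must contain a 'phase' column")
  ph <- as.character(cd$phase)
  if (!all(ph %in% .PHASES))
    return(sprintf("unknown phase label(s): %s",
                   paste(unique(setdiff(ph, .PHASES)), collapse = ", ")))
  if ("stage" %in% colnames(cd)) {
    st <- as.character(cd$stage)
    bad <- !is.na(st) & !st %in% .STAGES
    if (any(bad))
      return(sprintf("unknown stage label(s): %s",
                     paste(unique(st[bad]), collapse = ", ")))
    if (any(!is.na(st) & ph == "early" & st != "I"))
      return("early-phase samples must have stage I when staged")
    if (any(!is.na(st) & ph == "late" & !st %in% c("II", "III", "IV")))
      return("late-phase samples must have stage II-IV when staged")
  }
  if (anyDuplicated(colnames(object)))
    return("duplicate sample identifiers")
  if (anyDuplicated(rownames(object)))
    return("duplicate gene identifiers")
  TRUE
})

#' Construct a StageExperiment
#'
#' @param exprs numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames).
#' @param metadata data frame with columns `sample_id`, `phase` and
#'   optionally `stage`, as returned by [readSampleMetadata()]. Every column
#'   of `exprs` must be present in `metadata`; order is taken from `exprs`.
#' @return A [StageExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' md <- data.frame(sample_id = paste0("s", 1:4),
#'                  phase = c("control", "control", "early", "late"))
#' se <- StageExperiment(m, md)
#' phaseLabels(se)
#' @export
StageExperiment <- function(exprs, metadata) {
  stopifnot(is.matrix(exprs))
  metadata <- as.data.frame(metadata)
  missing_md <- setdiff(colnames(exprs), metadata$sample_id)
  if (length(missing_md))
    stop("samples absent from metadata: ",
         paste(head(missing_md, 5L), collapse = ", "))
  idx <- match(colnames(exprs), metadata$sample_id)
  cd <- S4Vectors::DataFrame(
    phase = factor(as.character(metadata$phase[idx]), levels = .PHASES),
    row.names = colnames(exprs))
  if ("stage" %in% colnames(metadata))
    cd$stage <- as.character(metadata$stage[idx])
  new("StageExperiment",
      SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = exprs), colData = cd))
}

#' @describeIn StageExperiment phase label of each sample, as a factor with
#'   levels control/early/late, named by sample id.
#' @param x a `StageExperiment`.
#' @export
phaseLabels <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  setNames(factor(as.character(cd$phase), levels = .PHASES), rownames(cd))
}

#' @describeIn StageExperiment clinical stage of each sample (`NA` where
#'   unstaged), named by sample id.
#' @export
sampleStages <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  st <- if ("stage" %in% colnames(cd)) as.character(cd$stage)
        else rep(NA_character_, nrow(cd))
  setNames(st, rownames(cd))
}

#' @describeIn StageExperiment the expression assay as a plain matrix.
#' @export
exprsMatrix <- function(x) SummarizedExperiment::assay(x, "exprs")

#' Stage-specific differentially expressed gene sets
#'
#' Holds the early-specific (`delta0`), late-specific (`delta1`) and shared
#' (`delta2`) differentially expressed gene sets with their regulation
#' directions. `delta2` is, by construction and by validity, the
#' gene-identifier intersection of `delta0` and `delta1`, keeping the
#' direction observed in each phase.
#'
#' @slot delta0 data.frame with columns `gene`, `direction` (early phase).
#' @slot delta1 data.frame with columns `gene`, `direction` (late phase).
#' @slot delta2 data.frame with columns `gene`, `direction_early`,
#'   `direction_late`.
#' @seealso [extractStageSets()]
#' @export
setClass("StageGeneSets",
         representation(delta0 = "data.frame", delta1 = "data.frame",
                        delta2 = "data.frame"))

setValidity("StageGeneSets", function(object) {
  for (s in c("delta0", "delta1")) {
    df <- slot(object, s)
    if (!all(c("gene", "direction") %in% colnames(df)))
      return(sprintf("%s needs columns gene, direction", s))
    if (anyDuplicated(df$gene)) return(sprintf("duplicate genes in %s", s))
  }
  d2 <- object@delta2
  if (!all(c("gene", "direction_early", "direction_late") %in% colnames(d2)))
    return("delta2 needs columns gene, direction_early, direction_late")
  want <- sort(intersect(object@delta0$gene, object@delta1$gene))
  if (!identical(sort(d2$gene), want))
    return("delta2 genes must equal intersection of delta0 and delta1 genes")
  TRUE
})

#' @describeIn StageGeneSets early-phase set (gene, direction).
#' @param object a `StageGeneSets`.
#' @export
delta0 <- function(object) object@delta0
#' @describeIn StageGeneSets late-phase set (gene, direction).
#' @export
delta1 <- function(object) object@delta1
#' @describeIn StageGeneSets shared set (gene, direction in each phase).
#' @export
delta2 <- function(object) object@delta2

setMethod("show", "StageGeneSets", function(object) {
  up0 <- sum(object@delta0$direction == "up")
  up1 <- sum(object@delta1$direction == "up")
  cat("StageGeneSets\n",
      sprintf("  delta0 (early): %d genes (%d up, %d down)\n",
              nrow(object@delta0), up0, nrow(object@delta0) - up0),
      sprintf("  delta1 (late):  %d genes (%d up, %d down)\n",
              nrow(object@delta1), up1, nrow(object@delta1) - up1),
      sprintf("  delta2 (shared): %d genes\n", nrow(object@delta2)), sep = "")
})

#' Per-phase signed co-expression network
#'
#' An undirected graph whose nodes are genes and whose edges are
#' significantly co-expressed pairs (|r| above the construction threshold)
#' in one phase's samples, with the correlation and its sign retained on
#' each edge. Genes of the node universe that take part in no significant
#' pair remain as degree-zero nodes.
#'
#' @slot phase character, which phase's samples supplied the correlations
#'   (or `"nonspecific"` for the shared-gene network over all samples).
#' @slot nodes character vector of gene ids.
#' @slot edges data.frame with columns `gene_a`, `gene_b` (lexicographically
#'   ordered within each row), `r`, `sign` (`"positive"`/`"negative"`).
#' @seealso [buildNetwork()], [topologyMetrics()], [degreeWeights()]
#' @export
setClass("PhaseNetwork",
         representation(phase = "character", nodes = "character",
                        edges = "data.frame"))

setValidity("PhaseNetwork", function(object) {
  e <- object@edges
  need <- c("gene_a", "gene_b", "r", "sign")
  if (!all(need %in% colnames(e)))
    return("edges needs columns gene_a, gene_b, r, sign")
  if (nrow(e)) {
    if (any(e$gene_a == e$gene_b)) return("self-loop edge")
    if (any(e$gene_a > e$gene_b))
      return("edge endpoints must be lexicographically ordered")
    if (anyDuplicated(paste(e$gene_a, e$gene_b))) return("multi-edge")
    if (!all(c(e$gene_a, e$gene_b) %in% object@nodes))
      return("edge endpoint outside node set")
  }
  if (anyDuplicated(object@nodes)) return("duplicate nodes")
  TRUE
})

#' @describeIn PhaseNetwork node (gene) identifiers.
#' @param object a `PhaseNetwork`.
#' @export
networkNodes <- function(object) object@nodes
#' @describeIn PhaseNetwork edge table (gene_a, gene_b, r, sign).
#' @export
networkEdges <- function(object) object@edges
#' @describeIn PhaseNetwork phase label the network was built for.
#' @export
networkPhase <- function(object) object@phase

setMethod("show", "PhaseNetwork", function(object) {
  cat(sprintf("PhaseNetwork [%s]: %d nodes, %d edges (%d positive, %d negative)\n",
              object@phase, length(object@nodes), nrow(object@edges),
              sum(object@edges$sign == "positive"),
              sum(object@edges$sign == "negative")))
})

# internal: igraph view of a PhaseNetwork (unweighted; r kept as edge attr)
.asIgraph <- function(net) {
  igraph::graph_from_data_frame(
    net@edges[, c("gene_a", "gene_b", "r", "sign")],
    directed = FALSE,
    vertices = data.frame(name = net@nodes))
}

#' Trained diagnostic SVM model
#'
#' @slot features character, the gene features the model uses.
#' @slot kernel `"radial"` or `"linear"`.
#' @slot cost,gamma tuned hyperparameters.
#' @slot levels the two class labels (negative, positive).
#' @slot fit the underlying [e1071::svm] fit.
#' @seealso [trainSvm()], [evaluateCv()]
#' @export
setClass("DiagnosticModel",
         representation(features = "character", kernel = "character",
                        cost = "numeric", gamma = "numeric",
                        levels = "character", fit = "ANY"))

setMethod("show", "DiagnosticModel", function(object) {
  cat(sprintf("DiagnosticModel: %d features, %s kernel, cost=%g, gamma=%g\n",
              length(object@features), object@kernel, object@cost,
              object@gamma),
      sprintf("  classes: %s vs %s\n", object@levels[1], object@levels[2]),
      sep = "")
})
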