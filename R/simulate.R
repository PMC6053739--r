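#' Simulate a staged expression study with planted ground truth
#'
#' Generates a genes-by-samples matrix on the post-normalization scale
#' (control samples standard normal for every gene), with four kinds of
#' planted structure that the downstream analysis is designed to recover:
#'
#' * differentially expressed genes whose mean is shifted by `+/- shift`
#'   in the early phase, the late phase, or both (the shared genes);
#' * correlated gene blocks built from one latent factor per
#'   (block, phase), `x = sqrt(rho) * f + sqrt(1 - rho) * eps`, so every
#'   within-block pair has correlation `rho` in that phase's samples;
#' * pathways: `nDeviated` of them draw at least `deviatedFraction` of
#'   their members from the planted shared DE genes (so their activity is
#'   coordinately shifted in early and late samples), the rest draw from
#'   background genes;
#' * pure background genes, independent standard normal everywhere.
#'
#' Group sizes default to the three-group design of a blood-transcriptome
#' staging study: 81 controls, 28 early-phase (stage I) and 53 late-phase
#' (stage II--IV) samples.
#'
#' @param nGenes total number of genes.
#' @param groupSizes integer vector `(control, early, late)`.
#' @param nDeEarly,nDeLate,nShared numbers of early-phase, late-phase and
#'   shared DE genes (`nShared` counts toward both totals).
#' @param shift absolute mean shift of planted DE genes, in control-SD
#'   units (log2-like scale).
#' @param nBlocks,blockSize planted correlated blocks (drawn from
#'   background genes).
#' @param rho named numeric, target within-block correlation per phase
#'   (`control`, `early`, `late`), each in (-1, 1).
#' @param nPathways,pathwaySize,nDeviated,deviatedFraction pathway
#'   collection layout; deviated pathways take
#'   `ceiling(deviatedFraction * pathwaySize)` members from shared DE genes.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @param rawScale if `TRUE`, apply a per-gene affine de-normalization
#'   (`x * sd_g + mean_g`, with gene means in ~U(6, 12) and SDs in
#'   ~U(0.5, 2)) so the matrix looks like raw log-intensities; the
#'   parameters are recorded in `truth$denorm`.
#' @return list with `expression` (matrix), `metadata` (data.frame),
#'   `pathways` (named list, GMT-shaped), `truth` (planted ground truth:
#'   `planted_de` data.frame, `planted_blocks`, `planted_pathways`,
#'   `group_sizes`).
#' @examples
#' sim <- simulateStageData(nGenes = 200, groupSizes = c(20, 10, 10),
#'                          nDeEarly = 10, nDeLate = 10, nShared = 5,
#'                          nBlocks = 1, blockSize = 5,
#'                          nPathways = 10, pathwaySize = 8, nDeviated = 2,
#'                          seed = 1)
#' dim(sim$expression)
#' @export
simulateStageData <- function(nGenes = 2000,
                              groupSizes = c(control = 81, early = 28,
                                             late = 53),
                              nDeEarly = 60, nDeLate = 60, nShared = 30,
                              shift = 2,
                              nBlocks = 3, blockSize = 10,
                              rho = c(control = 0.1, early = 0.7,
                                      late = 0.7),
                              nPathways = 50, pathwaySize = 20,
                              nDeviated = 5, deviatedFraction = 0.8,
                              seed = 1, rawScale = FALSE) {
  groupSizes <- setNames(as.integer(groupSizes), .PHASES)
  if (any(groupSizes < 1L)) stop("each group needs >= 1 sample")
  if (nShared > min(nDeEarly, nDeLate))
    stop("nShared must be <= min(nDeEarly, nDeLate)")
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1")
  if (shift == 0 && (nDeEarly + nDeLate) > 0)
    stop("planted shifts must be nonzero")
  nDe <- nDeEarly + nDeLate - nShared
  if (nDe + nBlocks * blockSize > nGenes)
    stop("planted genes exceed nGenes")
  nSamples <- sum(groupSizes)
  set.seed(seed)

  genes <- sprintf("g%05d", seq_len(nGenes))
  samples <- sprintf("s%03d", seq_len(nSamples))
  phase <- rep(.PHASES, groupSizes)
  stage <- rep(NA_character_, nSamples)
  stage[phase == "early"] <- "I"
  stage[phase == "late"] <- sample(c("II", "III", "IV"),
                                   sum(phase == "late"), replace = TRUE)
  metadata <- data.frame(sample_id = samples, phase = phase, stage = stage,
                         stringsAsFactors = FALSE)

  mat <- matrix(stats::rnorm(nGenes * nSamples), nGenes, nSamples,
                dimnames = list(genes, samples))

  # planted DE genes: first the shared ones, then phase-exclusive ones
  de_genes <- sample(genes, nDe)
  shared <- de_genes[seq_len(nShared)]
  early_only <- de_genes[nShared + seq_len(nDeEarly - nShared)]
  late_only <- de_genes[nDeEarly + seq_len(nDeLate - nShared)]
  planted_de <- data.frame(
    gene = c(shared, early_only, late_only),
    phase = c(rep("both", length(shared)), rep("early", length(early_only)),
              rep("late", length(late_only))),
    direction = sample(c("up", "down"),
                       length(shared) + length(early_only) +
                         length(late_only), replace = TRUE),
    stringsAsFactors = FALSE)
  planted_de$shift <- ifelse(planted_de$direction == "up", shift, -shift)
  eSamp <- phase == "early"; lSamp <- phase == "late"
  for (i in seq_len(nrow(planted_de))) {
    g <- planted_de$gene[i]
    w <- switch(planted_de$phase[i],
                both = eSamp | lSamp, early = eSamp, late = lSamp)
    mat[g, w] <- mat[g, w] + planted_de$shift[i]
  }

  # correlated blocks on background genes, one latent factor per
  # (block, phase); unit variance is preserved
  background <- setdiff(genes, planted_de$gene)
  planted_blocks <- list()
  if (nBlocks > 0L && blockSize > 1L) {
    block_pool <- sample(background, nBlocks * blockSize)
    for (b in seq_len(nBlocks)) {
      bg <- block_pool[(b - 1L) * blockSize + seq_len(blockSize)]
      for (ph in .PHASES) {
        w <- phase == ph
        r <- rho[[ph]]
        f <- stats::rnorm(sum(w))
        eps <- matrix(stats::rnorm(blockSize * sum(w)), blockSize)
        sgn <- sign(r); if (sgn == 0) sgn <- 1
        mat[bg, w] <- sgn * sqrt(abs(r)) * rep(f, each = blockSize) +
          sqrt(1 - abs(r)) * eps
      }
      planted_blocks[[b]] <- list(genes = bg, rho = rho)
    }
    background <- setdiff(background, block_pool)
  }

  # pathway collection
  pathways <- list()
  planted_pathways <- character(0)
  if (nPathways > 0L) {
    nms <- sprintf("PW%03d", seq_len(nPathways))
    deviated <- if (nDeviated > 0L) nms[seq_len(nDeviated)] else character(0)
    nPlantedMembers <- ceiling(deviatedFraction * pathwaySize)
    if (nDeviated > 0L && nPlantedMembers > length(shared))
      stop("not enough shared DE genes to populate deviated pathways")
    for (j in seq_along(nms)) {
      if (nms[j] %in% deviated) {
        members <- c(sample(shared, nPlantedMembers),
                     sample(background, pathwaySize - nPlantedMembers))
      } else {
        members <- sample(background, pathwaySize)
      }
      pathways[[nms[j]]] <- members
    }
    attr(pathways, "description") <- setNames(
      ifelse(nms %in% deviated, "planted-deviated", "background"), nms)
    planted_pathways <- deviated
  }

  truth <- list(planted_de = planted_de, planted_blocks = planted_blocks,
                planted_pathways = planted_pathways,
                group_sizes = groupSizes)

  if (rawScale) {
    gm <- stats::runif(nGenes, 6, 12)
    gs <- stats::runif(nGenes, 0.5, 2)
    mat <- mat * gs + gm
    truth$denorm <- data.frame(gene = genes, mean = gm, sd = gs,
                               stringsAsFactors = FALSE)
  }

  list(expression = mat, metadata = metadata, pathways = pathways,
       truth = truth)
}

#' Set a fixed fraction of matrix cells to missing
#'
#' Exactly `floor(fraction * length(mat))` cells are chosen uniformly at
#' random (reproducibly by `seed`) and set to `NA`.
#'
#' @param mat numeric matrix.
#' @param fraction fraction of cells in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return the matrix with missing cells injected.
#' @export
injectMissing <- function(mat, fraction, seed = 1) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  n <- floor(fraction * length(mat))
  if (n == 0L) return(mat)
  set.seed(seed)
  mat[sample.int(length(mat), n)] <- NA_real_
  mat
}
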