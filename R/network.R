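#' Build a phase co-expression network from a classified pair table
#'
#' Edges are exactly the non-`none` pairs of the table (duplicates
#' collapsed); genes of the node universe with no significant pair are
#' retained as degree-zero nodes, so that per-phase networks over the
#' same universe are directly comparable.
#'
#' @param pairs pair table from [classifyPairs()].
#' @param phase label stored on the network (default taken from the
#'   table).
#' @param nodeUniverse character vector of node gene ids; pairs outside
#'   the universe are dropped. Defaults to the genes appearing in the
#'   table.
#' @return a [PhaseNetwork-class].
#' @export
buildNetwork <- function(pairs, phase = NULL, nodeUniverse = NULL) {
  if (is.null(phase))
    phase <- if (nrow(pairs)) as.character(pairs$phase[1L]) else "unknown"
  if (is.null(nodeUniverse))
    nodeUniverse <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  nodeUniverse <- sort(unique(as.character(nodeUniverse)))
  e <- pairs[pairs$class != "none", c("gene_a", "gene_b", "r", "class"),
             drop = FALSE]
  e <- e[e$gene_a %in% nodeUniverse & e$gene_b %in% nodeUniverse, ,
         drop = FALSE]
  names(e)[names(e) == "class"] <- "sign"
  e <- e[!duplicated(paste(e$gene_a, e$gene_b)), , drop = FALSE]
  e <- e[order(e$gene_a, e$gene_b), , drop = FALSE]
  rownames(e) <- NULL
  new("PhaseNetwork", phase = phase, nodes = nodeUniverse, edges = e)
}

#' Topology metrics of a co-expression network
#'
#' Computes the four standard connectivity summaries on the unweighted,
#' undirected graph:
#'
#' * average shortest path: the mean geodesic distance over all ordered
#'   reachable node pairs (components of size >= 2);
#' * degree of every node;
#' * closeness centrality with the Wasserman-Faust correction for
#'   disconnected graphs: `(r_v / sum of distances) * (r_v / (n - 1))`
#'   where `r_v` is the number of nodes reachable from `v` (0 for
#'   isolated nodes);
#' * local clustering coefficient `2 * triangles / (deg * (deg - 1))`, 0
#'   when the degree is below 2.
#'
#' @param net a [PhaseNetwork-class] with at least one node.
#' @return list with `avg_shortest_path`, `degree`, `closeness`,
#'   `clustering` (the last three named per node), `n_nodes`, `n_edges`.
#' @export
topologyMetrics <- function(net) {
  n <- length(net@nodes)
  if (n == 0L) stop("empty network")
  g <- .asIgraph(net)
  dmat <- igraph::distances(g, weights = NA)
  reach <- is.finite(dmat) & dmat > 0
  aslp <- if (any(reach)) mean(dmat[reach]) else NA_real_
  deg <- igraph::degree(g)
  rv <- rowSums(reach)
  dsum <- rowSums(ifelse(reach, dmat, 0))
  clo <- ifelse(rv == 0, 0, (rv / pmax(dsum, 1)) * (rv / max(n - 1L, 1L)))
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(cc) <- names(deg)
  list(avg_shortest_path = aslp,
       degree = deg[net@nodes],
       closeness = setNames(clo[net@nodes], net@nodes),
       clustering = cc[net@nodes],
       n_nodes = n,
       n_edges = nrow(net@edges))
}

#' Sigmoid degree weights for a gene universe
#'
#' Maps each gene's network degree to a (0, 1) weight through the
#' logistic sigmoid `1 / (1 + exp(-degree))`, so that hub genes carry
#' more weight in pathway scoring. Universe genes absent from the
#' network receive the minimum weight observed among in-network genes
#' (0.5, the sigmoid of zero, whenever the network has a degree-zero
#' node). If the network is empty, every gene gets 0.5 with a warning.
#'
#' @param net a [PhaseNetwork-class].
#' @param universe character vector of genes to weight (default the
#'   network's nodes).
#' @return data.frame with columns `gene`, `degree` (`NA` for
#'   out-of-network genes), `weight`, `in_network`.
#' @export
degreeWeights <- function(net, universe = networkNodes(net)) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  if (!length(net@nodes)) {
    warning("empty network: all genes weighted sigmoid(0) = 0.5")
    return(data.frame(gene = universe, degree = NA_integer_, weight = 0.5,
                      in_network = FALSE, stringsAsFactors = FALSE))
  }
  g <- .asIgraph(net)
  deg <- igraph::degree(g)[net@nodes]
  w_in <- stats::plogis(deg)
  minw <- min(w_in)
  idx <- match(universe, net@nodes)
  data.frame(gene = universe,
             degree = ifelse(is.na(idx), NA_integer_, deg[idx]),
             weight = ifelse(is.na(idx), minw, w_in[idx]),
             in_network = !is.na(idx),
             stringsAsFactors = FALSE)
}
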