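# shared fixtures and independent oracles used across test files

# a classified pair table from an edge matrix (2 columns of gene ids)
makePairTable <- function(edges, phase = "x", r = 0.9) {
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  data.frame(gene_a = a, gene_b = b,
             phase = rep_len(phase, length(a)),
             r = rep_len(r, length(a)),
             class = rep_len(ifelse(r > 0, "positive", "negative"),
                             length(a)),
             stringsAsFactors = FALSE)
}

# all-pairs BFS distances, independent of igraph
bfsDistances <- function(nodes, edges) {
  n <- length(nodes)
  adj <- setNames(vector("list", n), nodes)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges$gene_a[i]; b <- edges$gene_b[i]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (s in nodes) {
    frontier <- s; dist <- 0
    while (length(frontier)) {
      nxt <- character(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (d[s, w] > dist + 1) {
            d[s, w] <- dist + 1
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
      dist <- dist + 1
    }
  }
  d
}

# brute-force running-mean maximum via explicit prefix enumeration
prefixMaxOracle <- function(z) {
  zs <- sort(z, decreasing = TRUE)
  vals <- vapply(seq_along(zs),
                 function(t) sum(zs[seq_len(t)]) / sqrt(t), 0)
  list(A = max(vals), t_max = which.max(vals))
}

# random undirected graph over a node universe, as a pair table
randomPairTable <- function(nNodes, pEdge) {
  nodes <- sprintf("n%02d", seq_len(nNodes))
  pairs <- t(combn(nodes, 2L))
  keep <- runif(nrow(pairs)) < pEdge
  if (!any(keep))
    return(list(nodes = nodes,
                table = makePairTable(pairs[0, , drop = FALSE])))
  list(nodes = nodes, table = makePairTable(pairs[keep, , drop = FALSE]))
}

# small two-class expression design for classifier tests:
# informative genes shifted by `shift` in the second class
twoClassMatrix <- function(n, p, nInformative, shift, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("g%03d", seq_len(p))))
  y <- factor(rep(c("benign", "malignant"), length.out = n))
  informative <- colnames(X)[seq_len(nInformative)]
  X[y == "malignant", informative] <-
    X[y == "malignant", informative] + shift
  list(X = X, y = y, informative = informative)
}
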