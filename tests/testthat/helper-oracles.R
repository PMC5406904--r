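# Independent oracles and small generators used across the suite.
# These deliberately avoid the code paths they check.

# Brute-force hypergeometric upper tail: sum the pmf written out with
# binomial coefficients, never through phyper().
oracle_hyper_tail <- function(k, K, n, N) {
  i <- seq.int(k, min(K, n))
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# All upper tails (k = 0..min(K, n)) at once, by reversed cumulative sum of
# the brute-force pmf.
oracle_hyper_tails_all <- function(K, n, N) {
  i <- seq.int(0L, min(K, n))
  pmf <- exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n))
  rev(cumsum(rev(pmf)))
}

# Hand-rolled BH step-up: sort ascending, apply p * m / rank, enforce
# monotonicity with a cumulative minimum from the largest rank down, then
# undo the sort.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact Steiner minimal node count by exhaustive enumeration: try adding
# k = 0, 1, 2, ... non-seed nodes until the induced subgraph connects all
# seeds.  Assumes the seeds are connected somewhere in g.
oracle_steiner_nodes <- function(g, seeds) {
  nonseeds <- setdiff(igraph::V(g)$name, seeds)
  for (extra in 0:length(nonseeds)) {
    sets <- if (extra == 0L) list(character(0)) else
      utils::combn(nonseeds, extra, simplify = FALSE)
    for (s in sets) {
      sub <- igraph::induced_subgraph(g, c(seeds, s))
      if (igraph::components(sub)$no == 1L) return(length(seeds) + extra)
    }
  }
  stop("seeds not connected in g")
}

# Random connected labelled graph: random spanning tree (uniform attach)
# plus `extra` random additional edges.  Node labels V01, V02, ...
random_connected_graph <- function(n, extra = 0L) {
  labels <- sprintf("V%02d", seq_len(n))
  a <- character(0); b <- character(0)
  for (i in seq_len(n - 1L)) {
    a <- c(a, labels[sample.int(i, 1L)])
    b <- c(b, labels[i + 1L])
  }
  if (extra > 0L) {
    for (e in seq_len(extra)) {
      ij <- sample.int(n, 2L)
      a <- c(a, labels[ij[1L]]); b <- c(b, labels[ij[2L]])
    }
  }
  interactome(cbind(a, b), nodes = labels)
}

# Enumerate every labelled connected graph on `n` nodes (edge subsets of
# the complete graph, connectivity-checked).  Only sane for n <= 5.
all_connected_graphs <- function(n) {
  labels <- sprintf("V%02d", seq_len(n))
  pairs <- utils::combn(labels, 2L)
  n_pairs <- ncol(pairs)
  out <- list()
  for (mask in seq_len(2^n_pairs) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n_pairs) - 1L)) > 0L)
    if (length(sel) < n - 1L) next
    g <- interactome(t(pairs[, sel, drop = FALSE]), nodes = labels)
    if (igraph::components(g)$no == 1L) out[[length(out) + 1L]] <- g
  }
  out
}

# Tree validity: edge count, connectivity, acyclicity of a subnetwork.
expect_valid_tree <- function(sn) {
  g <- interactome(sn$edges, nodes = sn$nodes)
  expect_equal(nrow(sn$edges), length(sn$nodes) - 1L)
  expect_equal(igraph::components(g)$no, 1L)
}
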