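#' Generate an Erdos-Renyi G(n, m) null ensemble
#'
#' Each replicate is a simple undirected graph drawn uniformly among graphs
#' with exactly `n_nodes` vertices and exactly `n_edges` edges — the
#' "same number of vertices and interactions" matching used when asking
#' whether an observed network is distinguishable from random.  G(n, m)
#' rather than G(n, p) is used precisely because the edge count must match
#' exactly, not just in expectation.
#'
#' @param n_nodes Number of vertices.
#' @param n_edges Number of edges, at most `choose(n_nodes, 2)`.
#' @param n_replicates Number of replicates (default 1).
#' @param seed RNG seed; the ensemble is reproducible from it.
#' @return A list of `igraph` graphs (vertices named `N1..Nn`).
#' @export
generate_gnm <- function(n_nodes, n_edges, n_replicates = 1L, seed = 1L) {
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_nodes < 1L || n_edges < 0L || n_edges > max_edges) {
    stop(sprintf("infeasible G(n, m) spec: n = %d allows at most %d edges",
                 n_nodes, max_edges))
  }
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(i) {
      g <- igraph::sample_gnm(n_nodes, n_edges, directed = FALSE)
      igraph::set_vertex_attr(g, "name", value = paste0("N", seq_len(n_nodes)))
    })
  })
}

# Registry of topological statistics used for null comparison.
net_statistic <- function(g, statistic) {
  switch(statistic,
    clustering = {
      x <- igraph::transitivity(g, type = "global")
      if (is.nan(x)) 0 else x     # no connected triple => no clustering
    },
    mean_path = {
      comp <- igraph::components(g)
      if (max(comp$csize) < 2L) return(NA_real_)
      big <- which.max(comp$csize)
      sub <- igraph::induced_subgraph(g, which(comp$membership == big))
      igraph::mean_distance(sub)
    },
    largest_component_frac = {
      if (igraph::vcount(g) == 0L) return(NA_real_)
      max(igraph::components(g)$csize) / igraph::vcount(g)
    },
    assortativity = igraph::assortativity_degree(g),
    stop("unknown statistic: ", statistic)
  )
}

#' Compare a network to a size-matched random ensemble
#'
#' Generates `n_replicates` G(n, m) graphs matched to the observed
#' network's node and edge counts and, for each requested topological
#' statistic, reports the observed value, the null mean and standard
#' deviation, a z-score, and a two-sided empirical p-value
#' `(r + 1) / (R + 1)` where `r` counts replicates at least as far from
#' the null mean as the observation (the add-one rule avoids zero
#' p-values at finite R).
#'
#' @param observed The observed interactome (`igraph`).
#' @param n_replicates Ensemble size R (default 1000).
#' @param seed RNG seed for the ensemble.
#' @param statistics Character vector from `"clustering"` (global
#'   clustering coefficient), `"mean_path"` (mean shortest path on the
#'   largest component), `"largest_component_frac"`, `"assortativity"`
#'   (degree assortativity).  Default: all four.
#' @return Data frame with one row per statistic: `statistic`, `observed`,
#'   `null_mean`, `null_sd`, `z`, `p_empirical`.
#' @export
compare_to_null <- function(observed, n_replicates = 1000L, seed = 1L,
                            statistics = c("clustering", "mean_path",
                                           "largest_component_frac",
                                           "assortativity")) {
  known <- c("clustering", "mean_path", "largest_component_frac",
             "assortativity")
  bad <- setdiff(statistics, known)
  if (length(bad)) stop("unknown statistic: ", paste(bad, collapse = ", "))
  if (n_replicates < 1L) stop("need at least one null replicate")
  n <- igraph::vcount(observed)
  m <- igraph::ecount(observed)
  nulls <- generate_gnm(n, m, n_replicates = n_replicates, seed = seed)
  rows <- lapply(statistics, function(s) {
    obs <- net_statistic(observed, s)
    null_vals <- vapply(nulls, net_statistic, numeric(1), statistic = s)
    mu <- mean(null_vals, na.rm = TRUE)
    sdv <- stats::sd(null_vals, na.rm = TRUE)
    z <- if (is.na(obs) || is.na(sdv) || sdv == 0) NA_real_ else (obs - mu) / sdv
    r <- sum(abs(null_vals - mu) >= abs(obs - mu), na.rm = TRUE)
    data.frame(
      statistic = s, observed = obs, null_mean = mu, null_sd = sdv, z = z,
      p_empirical = if (is.na(obs)) NA_real_ else (r + 1) / (n_replicates + 1),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
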