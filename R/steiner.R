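#' Infer a disease subnetwork with a greedy Steiner-tree heuristic
#'
#' Connects the seed (disease) genes present in the interactome through a
#' low node-count tree, following the network-parsimony principle that
#' disease components tend to communicate along short molecular paths.
#' The heuristic iteratively links smaller trees into larger ones: starting
#' from one singleton tree per seed, the two trees at minimal hop distance
#' are merged through a shortest path (Kruskal-style merging on the seed
#' metric closure), the interior nodes of each path entering the result as
#' *linker* genes.  The union of merge paths is then reduced to a spanning
#' tree and non-seed leaves are pruned.  On tree-shaped graphs this
#' recovers the exact Steiner minimal tree; in general the node count is at
#' most `2 * optimal - 1` (the classical shortest-path heuristic
#' guarantee).
#'
#' All tie-breaking is total and byte-wise lexicographic — equal-length
#' merges are ordered by seed-pair labels and equal-length paths resolved
#' toward the smallest interior label — so identical inputs yield identical
#' output regardless of construction order (see [interactome()]).
#'
#' Seeds absent from the graph, and seeds outside the component holding the
#' most seeds (ties broken toward the component containing the smallest
#' tied seed label), are reported in `excluded_seeds`; the result spans the
#' largest seed-containing component only.
#'
#' @param g An interactome (`igraph`), see [interactome()].
#' @param seeds Seed genes ([gene_set] or character vector).
#' @return An object of class `subnetwork`: list with `nodes`,
#'   `seed_nodes`, `linker_nodes`, `edges` (canonical two-column matrix),
#'   `excluded_seeds`, and `is_tree` (`TRUE` here).
#' @export
steiner_tree <- function(g, seeds) {
  if (!inherits(g, "igraph") || igraph::vcount(g) == 0L) {
    stop("g must be a non-empty interactome")
  }
  seeds_in <- as_genes(seeds)
  nodes <- igraph::V(g)$name
  present <- intersect(seeds_in, nodes)
  absent <- setdiff(seeds_in, nodes)
  if (!length(present)) stop("no seeds in network")

  comp <- igraph::components(g)
  memb <- comp$membership[present]
  tab <- table(memb)
  tied <- names(tab)[tab == max(tab)]
  if (length(tied) > 1L) {
    # component of the lexicographically smallest seed among tied components
    chosen <- as.character(memb[[present[memb %in% as.integer(tied)][1L]]])
  } else {
    chosen <- tied
  }
  main <- present[as.character(memb) == chosen]
  excluded <- sort_sym(c(absent, setdiff(present, main)))

  if (length(main) == 1L) {
    return(new_subnetwork(nodes = main, seed_nodes = main,
                          edges = empty_edge_matrix(),
                          excluded_seeds = excluded, is_tree = TRUE))
  }

  # --- metric closure over seeds, Kruskal-style tree merging -------------
  D <- igraph::distances(g, v = main, to = main)
  m <- length(main)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  pa <- main[idx[, 1L]]
  pb <- main[idx[, 2L]]
  dd <- D[idx]
  o <- order_sym(dd, pa, pb)
  pa <- pa[o]; pb <- pb[o]; dd <- dd[o]

  parent <- stats::setNames(seq_len(m), main)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  mst_a <- character(m - 1L); mst_b <- character(m - 1L)
  taken <- 0L
  ia <- match(pa, main); ib <- match(pb, main)
  for (e in seq_along(pa)) {
    ra <- find(ia[e]); rb <- find(ib[e])
    if (ra != rb) {
      parent[[ra]] <- rb
      taken <- taken + 1L
      mst_a[taken] <- pa[e]; mst_b[taken] <- pb[e]
      if (taken == m - 1L) break
    }
  }

  # --- realize each merge as the lexicographically smallest shortest path
  edge_rows <- vector("list", taken)
  for (e in seq_len(taken)) {
    p <- lex_shortest_path(g, mst_a[e], mst_b[e])
    edge_rows[[e]] <- cbind(p[-length(p)], p[-1L])
  }
  union_g <- interactome(do.call(rbind, edge_rows))

  # --- spanning tree of the path union, then prune non-seed leaves ------
  tree <- bfs_spanning_edges(union_g, root = main[1L])
  tree <- prune_nonseed_leaves(tree, main)
  tree_nodes <- sort_sym(unique(c(as.vector(tree), main)))

  new_subnetwork(nodes = tree_nodes, seed_nodes = main, edges = tree,
                 excluded_seeds = excluded, is_tree = TRUE)
}

# Lexicographically smallest shortest path from `from` to `to`: walk from
# `from`, at each step stepping to the smallest-labelled neighbor that is
# one hop closer to `to` (by BFS distances from `to`).
lex_shortest_path <- function(g, from, to) {
  dist_to <- igraph::distances(g, v = to)[1L, ]
  cur <- from
  path <- character(dist_to[[from]] + 1L)
  path[1L] <- from
  step <- 1L
  while (cur != to) {
    nb <- names(igraph::neighbors(g, cur))
    cand <- nb[dist_to[nb] == dist_to[[cur]] - 1]
    cur <- sort_sym(cand)[1L]
    step <- step + 1L
    path[step] <- cur
  }
  path
}

# Deterministic BFS spanning tree over a canonical interactome: vertices
# are visited in lexicographic order because neighbors are sorted.
bfs_spanning_edges <- function(g, root) {
  adj <- lapply(igraph::as_adj_list(g), function(v) sort_sym(names(v)))
  names(adj) <- igraph::V(g)$name
  visited <- stats::setNames(logical(length(adj)), names(adj))
  visited[[root]] <- TRUE
  queue <- root
  out_a <- character(0); out_b <- character(0)
  while (length(queue)) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    for (nb in adj[[cur]]) {
      if (!visited[[nb]]) {
        visited[[nb]] <- TRUE
        out_a <- c(out_a, cur); out_b <- c(out_b, nb)
        queue <- c(queue, nb)
      }
    }
  }
  canonical_pairs(out_a, out_b)
}

# Iteratively strip degree-1 nodes that are not seeds; a Steiner tree never
# needs a non-terminal leaf.
prune_nonseed_leaves <- function(edges, seeds) {
  repeat {
    if (!nrow(edges)) break
    deg <- table(as.vector(edges))
    leaves <- names(deg)[deg == 1L]
    drop <- setdiff(leaves, seeds)
    if (!length(drop)) break
    keep <- !(edges[, 1L] %in% drop | edges[, 2L] %in% drop)
    edges <- edges[keep, , drop = FALSE]
  }
  edges
}

canonical_pairs <- function(a, b) {
  if (!length(a)) return(empty_edge_matrix())
  swap <- lt_sym(b, a)
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  o <- order_sym(a, b)
  cbind(a = a[o], b = b[o])
}

empty_edge_matrix <- function() {
  matrix(character(0), ncol = 2L, dimnames = list(NULL, c("a", "b")))
}

new_subnetwork <- function(nodes, seed_nodes, edges, excluded_seeds,
                           is_tree) {
  structure(
    list(
      nodes = nodes,
      seed_nodes = sort_sym(intersect(seed_nodes, nodes)),
      linker_nodes = sort_sym(setdiff(nodes, seed_nodes)),
      edges = edges,
      excluded_seeds = excluded_seeds,
      is_tree = is_tree
    ),
    class = "subnetwork"
  )
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf(
    "<subnetwork> %d nodes (%d seeds, %d linkers), %d edges%s; %d seeds excluded\n",
    length(x$nodes), length(x$seed_nodes), length(x$linker_nodes),
    nrow(x$edges), if (x$is_tree) " (tree)" else "",
    length(x$excluded_seeds)))
  invisible(x)
}

#' Densify a subnetwork with all induced interactome edges
#'
#' Replaces the edge set of a subnetwork with every interactome edge whose
#' two endpoints are both in the subnetwork — the subgraph induced on the
#' tree's nodes.  The node set is unchanged; the operation is idempotent.
#' A reported disease module usually carries these induced edges rather
#' than the bare tree, since they are real interactions among the selected
#' proteins.
#'
#' @param g The interactome the subnetwork was inferred from.
#' @param subnet A `subnetwork` (its nodes must all be in `g`).
#' @return A `subnetwork` with the induced edge set (`is_tree = FALSE`).
#' @export
densify <- function(g, subnet) {
  if (!inherits(subnet, "subnetwork")) stop("expected a subnetwork")
  if (!all(subnet$nodes %in% igraph::V(g)$name)) {
    stop("subnetwork nodes must be contained in the interactome")
  }
  sub <- igraph::induced_subgraph(g, subnet$nodes)
  out <- subnet
  out$edges <- canonical_edges(sub)
  out$is_tree <- FALSE
  out
}

#' Partition subnetwork nodes into seeds and linkers
#'
#' @param subnet A `subnetwork`.
#' @param seeds The full seed list the inference started from.
#' @return List with `seeds` (subnetwork nodes that are seeds), `linkers`
#'   (added intermediate genes), and `seed_coverage` (fraction of all
#'   input seeds included in the subnetwork).
#' @export
classify_nodes <- function(subnet, seeds) {
  if (!inherits(subnet, "subnetwork")) stop("expected a subnetwork")
  seeds <- as_genes(seeds)
  inc <- sort_sym(intersect(subnet$nodes, seeds))
  list(
    seeds = inc,
    linkers = sort_sym(setdiff(subnet$nodes, seeds)),
    seed_coverage = if (length(seeds)) length(inc) / length(seeds) else NA_real_
  )
}

#' Write a subnetwork as node and edge TSV files
#'
#' @param subnet A `subnetwork`.
#' @param prefix Output path prefix; writes `<prefix>_nodes.tsv` (node,
#'   role, degree within the subnetwork) and `<prefix>_edges.tsv`.
#' @export
write_subnetwork <- function(subnet, prefix) {
  node_path <- paste0(prefix, "_nodes.tsv")
  edge_path <- paste0(prefix, "_edges.tsv")
  deg <- table(factor(as.vector(subnet$edges), levels = subnet$nodes))
  nodes <- data.frame(
    node = subnet$nodes,
    role = ifelse(subnet$nodes %in% subnet$seed_nodes, "seed", "linker"),
    degree = as.integer(deg[subnet$nodes]),
    stringsAsFactors = FALSE
  )
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(a = subnet$edges[, 1L], b = subnet$edges[, 2L],
               stringsAsFactors = FALSE),
    edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(node_path, edge_path))
}
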