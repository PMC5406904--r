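#' Jaccard coefficient of two gene sets
#'
#' `JC = |A intersect B| / |A union B|`.
#'
#' @param a,b Gene sets ([gene_set] or character vectors); not both empty.
#' @return A ratio in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- as_genes(a); b <- as_genes(b)
  if (!length(a) && !length(b)) stop("jaccard: both sets are empty")
  length(intersect(a, b)) / length(union(a, b))
}

#' Overlap coefficient of two gene sets
#'
#' `OC = |A intersect B| / min(|A|, |B|)`.  Always at least as large as the
#' Jaccard coefficient; saturates at 1 when one set contains the other.
#'
#' @inheritParams jaccard
#' @return A ratio in `[0, 1]`.
#' @export
overlap_coef <- function(a, b) {
  a <- as_genes(a); b <- as_genes(b)
  if (!length(a) || !length(b)) stop("overlap_coef: sets must be non-empty")
  length(intersect(a, b)) / min(length(a), length(b))
}

# Coerce supported inputs to a named list of candidate-gene vectors:
#   - a named list of character vectors / gene_sets
#   - the fixture table from load_alzgset_pathways() (pathway + genes cols)
#   - an enrich() result (pathway_id + comma-joined overlap_genes)
as_pathway_sets <- function(x) {
  if (is.data.frame(x)) {
    if (all(c("pathway", "genes") %in% names(x))) {
      sets <- lapply(x$genes, normalize_symbols)
      names(sets) <- x$pathway
    } else if (all(c("pathway_id", "overlap_genes") %in% names(x))) {
      sets <- lapply(strsplit(x$overlap_genes, ",", fixed = TRUE),
                     normalize_symbols)
      names(sets) <- x$pathway_id
    } else {
      stop("unrecognized pathway table; need columns pathway/genes or pathway_id/overlap_genes")
    }
  } else if (is.list(x)) {
    sets <- lapply(x, as_genes)
    if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
      stop("pathway list must be named")
    }
  } else {
    stop("expected a data frame or a named list of gene sets")
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate pathway names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  sets
}

#' Build a pathway-crosstalk network
#'
#' Constructs the crosstalk network among enriched pathways from their
#' candidate-gene sets (pathway membership restricted to the disease gene
#' set).  The filter cascade is: (1) discard pathways with fewer than
#' `min_genes` candidate genes (too few genes give sparse or biased
#' connections); (2) among the survivors form all unordered pairs and keep
#' those sharing at least `min_shared` candidate genes; (3) score each kept
#' pair by the Jaccard coefficient, the overlap coefficient, and their
#' average.  Pathways left without any kept pair do not appear as nodes.
#'
#' @param enriched Enriched pathways with their candidate-gene sets: the
#'   table from [load_alzgset_pathways()], an [enrich()] result (its
#'   `overlap_genes` are the candidates), or a named list of gene sets.
#'   Inputs are expected to have already passed the FDR gate.
#' @param min_genes Minimum candidate-gene count per pathway (default 6,
#'   i.e. pathways with five or fewer candidates are discarded).
#' @param min_shared Minimum shared candidate genes per pair (default 2).
#' @return An object of class `crosstalk_network`: a list with `nodes`
#'   (character), `edges` (data frame: `pathway_a`, `pathway_b`,
#'   `n_shared`, `shared_genes`, `jc`, `oc`, `score`), and the filter
#'   bookkeeping counts `n_input` and `n_size_filtered`.
#' @examples
#' net <- build_crosstalk(load_alzgset_pathways())
#' length(net$nodes); nrow(net$edges)   # 37 pathways, 207 crosstalks
#' @export
build_crosstalk <- function(enriched, min_genes = 6L, min_shared = 2L) {
  if (min_genes < 1L || min_shared < 1L) {
    stop("min_genes and min_shared must be >= 1")
  }
  sets <- as_pathway_sets(enriched)
  n_input <- length(sets)
  sets <- sets[lengths(sets) >= min_genes]
  sets <- sets[order_sym(names(sets))]
  m <- length(sets)

  rows <- list()
  if (m >= 2L) {
    nm <- names(sets)
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        shared <- intersect(sets[[i]], sets[[j]])
        if (length(shared) < min_shared) next
        jc <- length(shared) / length(union(sets[[i]], sets[[j]]))
        oc <- length(shared) / min(length(sets[[i]]), length(sets[[j]]))
        rows[[length(rows) + 1L]] <- data.frame(
          pathway_a = nm[i], pathway_b = nm[j],
          n_shared = length(shared),
          shared_genes = paste(sort_sym(shared), collapse = ","),
          jc = jc, oc = oc, score = (jc + oc) / 2,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else data.frame(
    pathway_a = character(0), pathway_b = character(0),
    n_shared = integer(0), shared_genes = character(0),
    jc = numeric(0), oc = numeric(0), score = numeric(0),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      nodes = sort_sym(unique(c(edges$pathway_a, edges$pathway_b))),
      edges = edges,
      n_input = n_input,
      n_size_filtered = m
    ),
    class = "crosstalk_network"
  )
}

#' @export
print.crosstalk_network <- function(x, ...) {
  cat(sprintf(
    "<crosstalk_network> %d pathways in, %d passed the size filter, %d nodes, %d crosstalks\n",
    x$n_input, x$n_size_filtered, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Score-weighted igraph view of a crosstalk network.
crosstalk_graph <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = net$edges$pathway_a, to = net$edges$pathway_b,
               weight = net$edges$score, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
}

#' Partition a crosstalk network into modules
#'
#' Multilevel (Louvain) modularity maximization on score-weighted crosstalk
#' edges, run under a fixed seed so the partition is reproducible.  The
#' published groupings of such networks are typically drawn by eye, so any
#' deterministic community-detection method is an acceptable — and clearly
#' approximate — stand-in; the partition is reported for orientation, not
#' as a reproduction target.
#'
#' @param net A `crosstalk_network` with at least one edge.
#' @param seed RNG seed controlling the (otherwise order-sensitive)
#'   modularity optimization.
#' @return Named integer vector: module id per pathway.
#' @export
detect_modules <- function(net, seed = 1L) {
  if (!inherits(net, "crosstalk_network")) stop("expected a crosstalk_network")
  if (!nrow(net$edges)) stop("cannot partition an empty network")
  g <- crosstalk_graph(net)
  cl <- with_seed(seed, {
    igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  })
  stats::setNames(as.integer(igraph::membership(cl)),
                  igraph::V(g)$name)
}

#' Write a crosstalk network as edge and node TSV files
#'
#' @param net A `crosstalk_network`.
#' @param prefix Output path prefix; writes `<prefix>_edges.tsv` and
#'   `<prefix>_nodes.tsv`.
#' @export
write_crosstalk <- function(net, prefix) {
  edge_path <- paste0(prefix, "_edges.tsv")
  node_path <- paste0(prefix, "_nodes.tsv")
  utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  deg <- table(c(net$edges$pathway_a, net$edges$pathway_b))
  nodes <- data.frame(
    pathway = net$nodes,
    n_crosstalks = as.integer(deg[net$nodes]),
    stringsAsFactors = FALSE
  )
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edge_path, node_path))
}
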