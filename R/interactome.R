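#' Build an interactome from an edge table
#'
#' An interactome is represented as an undirected simple [igraph] graph over
#' gene symbols.  Construction canonicalizes the input: symbols are
#' normalized as in [gene_set()], self-interactions are dropped, each
#' unordered pair is stored once (endpoints in byte-wise lexicographic
#' order), and vertices are sorted so that two interactomes built from the
#' same edges in any row order are identical, including internal vertex
#' numbering.  That last point is what makes downstream tie-breaking (e.g.
#' in [steiner_tree()]) independent of input order.
#'
#' @param edges Two-column character matrix or data frame of endpoint
#'   symbols; may have zero rows.
#' @param nodes Optional additional isolated node symbols.
#' @return An undirected simple `igraph` object with a `name` vertex
#'   attribute.
#' @export
interactome <- function(edges = NULL, nodes = character()) {
  if (is.null(edges)) {
    a <- character(0); b <- character(0)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L && nrow(edges) > 0L) {
      stop("edge table must have exactly two columns")
    }
    a <- toupper(trimws(as.character(edges[, 1L])))
    b <- toupper(trimws(as.character(edges[, 2L])))
    if (any(!nzchar(a)) || any(!nzchar(b))) {
      stop("edge endpoints must be non-empty symbols")
    }
  }
  keep <- a != b                       # drop self-interactions
  a <- a[keep]; b <- b[keep]
  swap <- lt_sym(b, a)                 # canonical order within each pair
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, sep = "\t")
  first <- !duplicated(key)
  a <- a[first]; b <- b[first]
  o <- order_sym(a, b)
  a <- a[o]; b <- b[o]
  vs <- sort_sym(unique(c(a, b, normalize_symbols_allow_empty(nodes))))
  igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = vs, stringsAsFactors = FALSE)
  )
}

normalize_symbols_allow_empty <- function(x) {
  if (!length(x)) return(character(0))
  normalize_symbols(x)
}

#' Read an interactome from an edge-list file
#'
#' Two dialects are supported: `"tsv"` (two whitespace- or tab-separated
#' symbol columns per line) and `"sif"` (Cytoscape simple interaction
#' format: `source<TAB>relation<TAB>target [target ...]`).  Lines starting
#' with `#` and blank lines are skipped.  The result is canonicalized as in
#' [interactome()], so duplicated rows, swapped endpoints, and
#' self-interactions never inflate the edge count.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"sif"`.
#' @return An interactome (`igraph`).
#' @export
read_edge_list <- function(path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  use <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(use)) return(interactome())
  toks <- strsplit(trimws(lines[use]), "[ \t]+")
  if (dialect == "tsv") {
    nf <- lengths(toks)
    bad <- which(nf != 2L)
    if (length(bad)) {
      stop(sprintf("malformed edge-list line %d in %s: expected 2 fields, got %d",
                   use[bad[1L]], path, nf[bad[1L]]))
    }
    a <- vapply(toks, `[[`, character(1), 1L)
    b <- vapply(toks, `[[`, character(1), 2L)
  } else {
    nf <- lengths(toks)
    bad <- which(nf < 3L)
    if (length(bad)) {
      stop(sprintf("malformed SIF line %d in %s: expected >= 3 fields, got %d",
                   use[bad[1L]], path, nf[bad[1L]]))
    }
    a <- rep(vapply(toks, `[[`, character(1), 1L), nf - 2L)
    b <- unlist(lapply(toks, function(t) t[-(1:2)]), use.names = FALSE)
  }
  interactome(cbind(a, b))
}

#' Write an interactome as a two-column edge list
#'
#' Edges are written once per unordered pair, endpoints in lexicographic
#' order, rows sorted, so serialization is canonical and diffs are stable.
#' The edge-list dialect carries no isolated-node declarations, so nodes
#' without any edge are not preserved by a write/read round trip.
#'
#' @param g An interactome (`igraph`).
#' @param path Output path.
#' @export
write_edge_list <- function(g, path) {
  el <- canonical_edges(g)
  writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), path)
  invisible(path)
}

# Canonical edge matrix: each pair once, endpoints ordered, rows sorted.
canonical_edges <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (!nrow(el)) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("a", "b"))))
  }
  a <- el[, 1L]; b <- el[, 2L]
  swap <- lt_sym(b, a)
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  o <- order_sym(a, b)
  cbind(a = a[o], b = b[o])
}

#' Merge interactomes
#'
#' Set-semantics union of nodes and edges across sources, with
#' self-interactions and redundant (duplicated or endpoint-swapped) pairs
#' removed — the standard compilation step when pooling protein-protein
#' interaction databases that have already been mapped to a common gene
#' symbol space.  The operation is commutative, associative, and idempotent.
#'
#' @param sources A non-empty list of interactomes (`igraph` objects).
#' @return The merged interactome.
#' @export
merge_interactomes <- function(sources) {
  if (inherits(sources, "igraph")) sources <- list(sources)
  if (!is.list(sources) || !length(sources)) {
    stop("need at least one interactome to merge")
  }
  els <- lapply(sources, function(g) canonical_edges(g))
  nodes <- unique(unlist(lapply(sources, function(g) igraph::V(g)$name)))
  interactome(do.call(rbind, els), nodes = nodes)
}

#' Summarize an interactome
#'
#' @param g An interactome (`igraph`).
#' @return A list with `n_nodes`, `n_edges`, `degree_quantiles` (0, 25, 50,
#'   75, 100 percent), `n_components`, and `component_sizes` (decreasing).
#' @export
network_summary <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) {
    return(list(n_nodes = 0L, n_edges = 0L,
                degree_quantiles = stats::setNames(rep(0, 5),
                  c("0%", "25%", "50%", "75%", "100%")),
                n_components = 0L, component_sizes = integer(0)))
  }
  comp <- igraph::components(g)
  list(
    n_nodes = n,
    n_edges = igraph::ecount(g),
    degree_quantiles = stats::quantile(igraph::degree(g)),
    n_components = comp$no,
    component_sizes = sort(as.integer(comp$csize), decreasing = TRUE)
  )
}
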