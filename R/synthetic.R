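#' Synthetic gene universe
#'
#' Index-based symbols `G000001, G000002, ...`.  The universe is purely
#' positional, so it is identical across seeds by design; randomness enters
#' only through the sampling generators that draw from it.
#'
#' @param n_genes Number of genes (>= 1).
#' @return A [gene_set] named `"universe"`.
#' @export
make_universe <- function(n_genes) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  gene_set(sprintf("G%06d", seq_len(n_genes)), name = "universe")
}

#' Synthetic pathway database with controlled overlap
#'
#' Samples `n_pathways` pathways from a universe such that a fraction
#' `overlap_frac` of each pathway is drawn from one common shared pool (of
#' size `max(size_range)`) and the remainder from genes not used by any
#' other pathway.  Pairwise overlap therefore comes exclusively from the
#' shared pool: `overlap_frac = 0` gives mutually disjoint pathways,
#' `overlap_frac = 1` with a fixed size makes all pathways identical, and
#' intermediate values tune the expected pairwise Jaccard coefficient
#' monotonically — the structure pathway-crosstalk analysis assumes.
#'
#' @param universe A [gene_set] or character vector.
#' @param n_pathways Number of pathways.
#' @param size_range Length-2 integer vector, inclusive size bounds.
#' @param overlap_frac Fraction in `[0, 1]` of each pathway drawn from the
#'   shared pool.
#' @param seed RNG seed.
#' @return A list of [pathway_record] objects (`P001`, `P002`, ...).
#' @export
make_pathway_db <- function(universe, n_pathways, size_range = c(10L, 50L),
                            overlap_frac = 0.3, seed = 1L) {
  uni <- as_genes(universe)
  if (length(size_range) != 2L || size_range[1L] > size_range[2L] ||
      size_range[1L] < 1L) {
    stop("size_range must be increasing positive bounds")
  }
  if (overlap_frac < 0 || overlap_frac > 1) {
    stop("overlap_frac must be in [0, 1]")
  }
  pool_size <- size_range[2L]
  # worst-case unique-gene budget across all pathways
  max_unique <- ceiling((1 - overlap_frac) * size_range[2L]) * n_pathways
  if (pool_size + max_unique > length(uni)) {
    stop("infeasible: universe too small for disjoint unique parts")
  }
  if (pool_size > length(uni)) stop("infeasible: pool exceeds universe")
  with_seed(seed, {
    pool <- sample(uni, pool_size)
    remaining <- setdiff(uni, pool)
    lapply(seq_len(n_pathways), function(i) {
      s <- if (size_range[1L] == size_range[2L]) size_range[1L] else
        sample(seq.int(size_range[1L], size_range[2L]), 1L)
      n_shared <- round(overlap_frac * s)
      shared <- if (n_shared > 0L) sample(pool, n_shared) else character(0)
      n_uni <- s - n_shared
      uniq <- if (n_uni > 0L) sample(remaining, n_uni) else character(0)
      remaining <<- setdiff(remaining, uniq)
      pathway_record(sprintf("P%03d", i), members = c(shared, uniq),
                     source = "synthetic")
    })
  })
}

#' Synthetic query gene set with planted enrichment
#'
#' Draws `round(planted_frac * n_query)` query genes uniformly from the
#' members of the target pathways and the remainder uniformly from the rest
#' of the universe, giving a direct effect-size knob for power and type-I
#' calibration of [enrich()].
#'
#' @param universe A [gene_set] or character vector.
#' @param target_pathways List of [pathway_record] objects to plant from.
#' @param n_query Query size.
#' @param planted_frac Fraction in `[0, 1]` of the query planted from the
#'   targets.
#' @param seed RNG seed.
#' @return A [gene_set] named `"query"`.
#' @export
make_query <- function(universe, target_pathways, n_query,
                       planted_frac = 0.3, seed = 1L) {
  uni <- as_genes(universe)
  if (planted_frac < 0 || planted_frac > 1) {
    stop("planted_frac must be in [0, 1]")
  }
  if (inherits(target_pathways, "pathway_record")) {
    target_pathways <- list(target_pathways)
  }
  target <- sort_sym(unique(unlist(
    lapply(target_pathways, function(r) r$members$genes))))
  n_planted <- round(planted_frac * n_query)
  if (n_planted > length(target)) {
    stop("infeasible: planted_frac * n_query exceeds target membership")
  }
  background <- setdiff(uni, target)
  if (n_query - n_planted > length(background)) {
    stop("infeasible: not enough non-target genes in the universe")
  }
  with_seed(seed, {
    planted <- if (n_planted > 0L) sample(target, n_planted) else character(0)
    rest <- if (n_query - n_planted > 0L) {
      sample(background, n_query - n_planted)
    } else character(0)
    gene_set(c(planted, rest), name = "query")
  })
}

#' Synthetic interactome with planted connector paths
#'
#' A random background graph — Erdos-Renyi G(n, m) by default, or
#' preferential attachment (`model = "pa"`) for a heavy-tailed degree
#' distribution closer to real interactomes — optionally augmented with
#' planted simple paths between designated seed pairs.  Each planted path
#' of length L runs through L - 1 fresh low-degree linker nodes
#' (`LNK0001, ...`) added on top of the background, emulating the
#' parsimony structure the Steiner step is designed to recover.
#'
#' @param n_nodes Background node count (symbols `G000001...` by default).
#' @param n_edges Background edge count (G(n, m) model).
#' @param planted_paths Optional data frame with columns `from`, `to`,
#'   `length` (hop count >= 1); `from`/`to` must be background node
#'   symbols.
#' @param seed RNG seed.
#' @param model `"gnm"` or `"pa"`.
#' @param node_names Optional custom background symbols (length
#'   `n_nodes`); defaults to [make_universe()] symbols.
#' @return An interactome (`igraph`).
#' @export
make_interactome <- function(n_nodes, n_edges, planted_paths = NULL,
                             seed = 1L, model = c("gnm", "pa"),
                             node_names = NULL) {
  model <- match.arg(model)
  names_bg <- node_names %||% make_universe(n_nodes)$genes
  if (length(names_bg) != n_nodes) {
    stop("node_names must have length n_nodes")
  }
  names_bg <- normalize_symbols(names_bg)
  if (length(names_bg) != n_nodes) stop("node_names must be unique")
  bg <- with_seed(seed, {
    if (model == "gnm") {
      max_edges <- n_nodes * (n_nodes - 1) / 2
      if (n_edges > max_edges) stop("infeasible edge count for G(n, m)")
      igraph::sample_gnm(n_nodes, n_edges, directed = FALSE)
    } else {
      igraph::sample_pa(n_nodes, m = max(1L, round(n_edges / n_nodes)),
                        directed = FALSE)
    }
  })
  bg <- igraph::set_vertex_attr(bg, "name", value = names_bg)
  el <- igraph::as_edgelist(bg, names = TRUE)

  if (!is.null(planted_paths) && nrow(planted_paths)) {
    need <- c("from", "to", "length")
    if (!all(need %in% names(planted_paths))) {
      stop("planted_paths needs columns from, to, length")
    }
    linker_count <- 0L
    extra <- list()
    for (i in seq_len(nrow(planted_paths))) {
      a <- toupper(trimws(planted_paths$from[i]))
      b <- toupper(trimws(planted_paths$to[i]))
      len <- as.integer(planted_paths$length[i])
      if (!a %in% names_bg || !b %in% names_bg) {
        stop("planted path endpoints must be background nodes")
      }
      if (len < 1L) stop("planted path length must be >= 1")
      inner <- if (len > 1L) {
        sprintf("LNK%04d", linker_count + seq_len(len - 1L))
      } else character(0)
      linker_count <- linker_count + length(inner)
      chain <- c(a, inner, b)
      extra[[i]] <- cbind(chain[-length(chain)], chain[-1L])
    }
    el <- rbind(el, do.call(rbind, extra))
  }
  interactome(el, nodes = names_bg)
}
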