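#' Upper-tail hypergeometric probability
#'
#' Probability of observing `k` or more annotated genes in the overlap of a
#' query of size `n` with a pathway of size `K` inside a universe of size
#' `N`, i.e. the one-sided over-representation p-value of Fisher's exact
#' test: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k Observed overlap count, `0 <= k <= min(K, n)`.
#' @param K Pathway size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return `P(X >= k)`, in `(0, 1]`.  Arguments are vectorized.
#' @examples
#' hypergeom_tail(5, 5, 5, 20)  # 1 / choose(20, 5)
#' @export
hypergeom_tail <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | N < 0 | K > N | n > N | k > pmin(K, n)
  if (any(bad)) {
    stop("hypergeom_tail: arguments out of range (need 0 <= k <= min(K, n), K <= N, n <= N)")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment in the original input order.
#' Thin validating wrapper around [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted p-values, each `>=` its input and `<= 1`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("bh_adjust: p-values must be in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' Tests every pathway in `db` for over-representation in `query` with the
#' one-sided hypergeometric test, then adjusts across *all* tested pathways
#' with Benjamini-Hochberg.  The universe defaults to the union of all
#' pathway members in `db` (a self-contained, conventional background);
#' pass an explicit `universe` to override.  Query genes absent from the
#' universe are dropped (with a message) so the 2x2 table stays coherent.
#'
#' @param query Query gene set ([gene_set] or character vector).
#' @param db Pathway database: a list of [pathway_record] objects, e.g.
#'   from [read_gmt()].
#' @param universe Optional background ([gene_set] or character vector).
#' @param fdr_threshold Significance threshold on the adjusted p (default
#'   0.05), strictly inside `(0, 1)`.
#' @return A data frame, one row per pathway with overlap `k >= 1`, sorted
#'   by raw p then pathway id, with columns `pathway_id`, `name`, `k`, `K`,
#'   `n`, `N`, `overlap_genes` (comma-joined), `p_raw`, `p_bh`,
#'   `significant`.  The number of pathways tested (the BH family size) is
#'   in attribute `n_tested`; dropped query genes in `n_query_dropped`.
#' @export
enrich <- function(query, db, universe = NULL, fdr_threshold = 0.05) {
  if (!is.numeric(fdr_threshold) || length(fdr_threshold) != 1L ||
      fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop("fdr_threshold must be strictly between 0 and 1")
  }
  if (!is.list(db) || !length(db) ||
      !all(vapply(db, inherits, logical(1), "pathway_record"))) {
    stop("db must be a non-empty list of pathway_record objects")
  }
  query <- as_genes(query)
  members <- lapply(db, function(r) r$members$genes)
  uni <- if (is.null(universe)) {
    sort_sym(unique(unlist(members)))
  } else {
    as_genes(universe)
  }
  if (!length(uni)) stop("empty universe")
  dropped <- sum(!(query %in% uni))
  if (dropped > 0L) {
    message(sprintf("enrich: dropped %d query gene(s) absent from the universe",
                    dropped))
  }
  query <- intersect(query, uni)
  if (!length(query)) stop("empty query after restriction to the universe")

  N <- length(uni)
  n <- length(query)
  Kv <- integer(length(db))
  kv <- integer(length(db))
  overlaps <- vector("list", length(db))
  for (i in seq_along(db)) {
    mem <- intersect(members[[i]], uni)
    ov <- intersect(query, mem)
    Kv[i] <- length(mem)
    kv[i] <- length(ov)
    overlaps[[i]] <- sort_sym(ov)
  }
  p_raw <- hypergeom_tail(kv, Kv, n, N)
  p_bh <- bh_adjust(p_raw)   # family = all tested pathways, incl. k = 0

  res <- data.frame(
    pathway_id = vapply(db, function(r) r$pathway_id, character(1)),
    name = vapply(db, function(r) r$display_name, character(1)),
    k = kv, K = Kv, n = n, N = N,
    overlap_genes = vapply(overlaps, paste, character(1), collapse = ","),
    p_raw = p_raw, p_bh = p_bh,
    significant = p_bh < fdr_threshold,
    stringsAsFactors = FALSE
  )
  n_tested <- nrow(res)
  res <- res[res$k >= 1L, , drop = FALSE]
  res <- res[order_sym(res$p_raw, res$pathway_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_tested") <- n_tested
  attr(res, "n_query_dropped") <- dropped
  res
}

#' Write an enrichment result table as TSV
#'
#' @param res Result of [enrich()].
#' @param path Output path.
#' @export
write_enrichment <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
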