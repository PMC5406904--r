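#' Load the packaged Alzheimer pathway-enrichment table
#'
#' The package ships a transcription of a curated enrichment analysis of
#' "Alzgset", a set of 430 genes reported to be associated with Alzheimer's
#' disease in genetic association studies.  The table lists, for each of 68
#' pathways significantly over-represented in Alzgset (BH-adjusted p <
#' 0.05), the raw and adjusted p-values and the pathway's *candidate genes*
#' — the intersection of the pathway membership with Alzgset.  These
#' candidate-gene lists, not full pathway memberships, are the inputs to
#' pathway-crosstalk analysis ([build_crosstalk()]).
#'
#' On load the table is validated: every adjusted p must be below 0.05 and
#' at least as large as its raw p, every candidate set non-empty, and
#' pathway names unique.  A failed check is a hard error (corrupt fixture).
#'
#' @param path Path to a fixture in the same four-column TSV format
#'   (`pathway`, `p_raw`, `p_bh`, comma-joined `candidate_genes`); defaults
#'   to the packaged table.
#' @return A data frame with columns `pathway`, `p_raw`, `p_bh`,
#'   `n_genes`, and a list-column `genes` of character vectors.
#' @examples
#' tab <- load_alzgset_pathways()
#' nrow(tab)   # 68 enriched pathways
#' @export
load_alzgset_pathways <- function(path = NULL) {
  path <- path %||% system.file("extdata", "alzgset_pathways.tsv",
                                package = "netpathad", mustWork = FALSE)
  if (is.null(path) || !nzchar(path) || !file.exists(path)) {
    stop("pathway fixture not found; reinstall the package")
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "numeric", "numeric",
                                        "character"))
  need <- c("pathway", "p_raw", "p_bh", "candidate_genes")
  if (!all(need %in% names(d))) {
    stop("corrupt pathway fixture: missing columns ",
         paste(setdiff(need, names(d)), collapse = ", "))
  }
  genes <- lapply(strsplit(d$candidate_genes, ",", fixed = TRUE),
                  normalize_symbols)
  ok <- !anyDuplicated(d$pathway) &&
    all(lengths(genes) >= 1L) &&
    all(is.finite(d$p_raw)) && all(is.finite(d$p_bh)) &&
    all(d$p_raw > 0) && all(d$p_bh >= d$p_raw) && all(d$p_bh < 0.05)
  if (!ok) stop("corrupt pathway fixture: integrity checks failed")
  data.frame(
    pathway = d$pathway,
    p_raw = d$p_raw,
    p_bh = d$p_bh,
    n_genes = lengths(genes),
    genes = I(genes),
    stringsAsFactors = FALSE
  )
}

#' Load the synthetic Alzgset seed-gene list
#'
#' The curated Alzgset contains 430 gene symbols, but only a subset of them
#' (the candidate genes of the enriched pathways plus genes named in the
#' accompanying text) is printed anywhere the package can transcribe; the
#' complete list lives in a supplementary file that is not redistributed
#' here.  This loader therefore returns a *synthetic stand-in* of exactly
#' 430 symbols: the transcribable real symbols, padded to 430 with clearly
#' artificial placeholders (`SYNAD###`).  The stand-in has the right size
#' and a realistic real/placeholder mix for exercising seed-list plumbing
#' and for scale-matched synthetic benchmarks; it must not be used for
#' biological interpretation.
#'
#' @return A [gene_set] of 430 symbols named `"alzgset_synthetic"`.
#' @export
load_alzgset_synthetic <- function() {
  path <- system.file("extdata", "alzgset_synthetic.txt",
                      package = "netpathad", mustWork = FALSE)
  if (is.null(path) || !nzchar(path) || !file.exists(path)) {
    stop("synthetic Alzgset fixture not found; reinstall the package")
  }
  read_gene_list(path, name = "alzgset_synthetic")
}
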