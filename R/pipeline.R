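#' Run the end-to-end network/pathway analysis pipeline
#'
#' Orchestrates the four analysis stages — over-representation analysis,
#' pathway-crosstalk network construction, Steiner subnetwork inference,
#' and random-network null comparison — with bookkeeping at every filter so
#' that `records_in = records_out + records_dropped` holds at each stage.
#' Any stage failure aborts with the stage name and cause.  All stage
#' outputs are plain TSV, so each stage can also be run standalone through
#' its underlying function.
#'
#' @param config A named list (or path to a YAML / `key=value` file) with
#'   entries:
#'   \describe{
#'     \item{genes}{Path to a gene-list file, or a [gene_set]: the query /
#'       seed genes.}
#'     \item{gmt}{Path to a GMT file, or a list of [pathway_record]s
#'       (enables the `enrich` stage).}
#'     \item{pathway_table}{Path to a candidate-gene table in the
#'       [load_alzgset_pathways()] TSV format, or such a data frame:
#'       alternative crosstalk input when enrichment was done elsewhere.}
#'     \item{universe}{Optional background gene list (path or [gene_set]).}
#'     \item{network}{Path to an edge-list file, or an interactome
#'       (`igraph`): enables `subnet` and `nullcmp`.}
#'     \item{fdr, min_genes, min_shared}{Thresholds; defaults 0.05, 6, 2.}
#'     \item{replicates}{Null-ensemble size; default 1000.}
#'     \item{seed}{RNG seed; default 1.}
#'     \item{densify}{Restore induced interactome edges on the subnetwork;
#'       default `TRUE`.}
#'     \item{stages}{Subset of `c("enrich", "crosstalk", "subnet",
#'       "nullcmp")`; default: every stage its inputs allow.}
#'     \item{out_dir}{Optional output directory for stage TSVs.}
#'   }
#' @return A `pipeline_report`: named list of per-stage reports (counts,
#'   filter bookkeeping, headline statistics) plus the stage result
#'   objects in `$results`.
#' @export
run_pipeline <- function(config) {
  config <- load_config(config)
  fdr <- config$fdr %||% 0.05
  min_genes <- config$min_genes %||% 6L
  min_shared <- config$min_shared %||% 2L
  replicates <- config$replicates %||% 1000L
  seed <- config$seed %||% 1L
  do_densify <- config$densify %||% TRUE
  out_dir <- config$out_dir

  genes <- if (!is.null(config$genes)) coerce_gene_set(config$genes)
  db <- if (!is.null(config$gmt)) coerce_gmt(config$gmt)
  ptab <- if (!is.null(config$pathway_table)) {
    coerce_pathway_table(config$pathway_table)
  }
  net <- if (!is.null(config$network)) coerce_network(config$network)

  all_stages <- c("enrich", "crosstalk", "subnet", "nullcmp")
  stages <- config$stages %||% c(
    if (!is.null(genes) && !is.null(db)) "enrich",
    if (!is.null(db) || !is.null(ptab)) "crosstalk",
    if (!is.null(net) && !is.null(genes)) c("subnet", "nullcmp")
  )
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  report <- list()
  results <- list()

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  if ("enrich" %in% stages) {
    report$enrich <- run_stage("enrich", {
      if (is.null(genes) || is.null(db)) stop("needs 'genes' and 'gmt'")
      universe <- if (!is.null(config$universe)) {
        coerce_gene_set(config$universe)
      }
      res <- enrich(genes, db, universe = universe, fdr_threshold = fdr)
      results$enrichment <- res
      if (!is.null(out_dir)) {
        write_enrichment(res, file.path(out_dir, "enrichment.tsv"))
      }
      n_tested <- attr(res, "n_tested")
      list(records_in = n_tested,
           records_out = sum(res$significant),
           records_dropped = n_tested - sum(res$significant),
           n_query_dropped = attr(res, "n_query_dropped"))
    })
  }

  if ("crosstalk" %in% stages) {
    report$crosstalk <- run_stage("crosstalk", {
      input <- if (!is.null(ptab)) ptab else {
        res <- results$enrichment
        if (is.null(res)) stop("needs 'pathway_table' or an enrich stage")
        res[res$significant, , drop = FALSE]
      }
      ct <- build_crosstalk(input, min_genes = min_genes,
                            min_shared = min_shared)
      results$crosstalk <- ct
      if (!is.null(out_dir)) {
        write_crosstalk(ct, file.path(out_dir, "crosstalk"))
      }
      list(records_in = ct$n_input,
           records_out = length(ct$nodes),
           records_dropped = ct$n_input - length(ct$nodes),
           n_size_filtered = ct$n_size_filtered,
           n_nodes = length(ct$nodes),
           n_edges = nrow(ct$edges))
    })
  }

  if ("subnet" %in% stages) {
    report$subnet <- run_stage("subnet", {
      if (is.null(net) || is.null(genes)) stop("needs 'network' and 'genes'")
      sn <- steiner_tree(net, genes)
      if (isTRUE(do_densify)) sn <- densify(net, sn)
      results$subnetwork <- sn
      if (!is.null(out_dir)) {
        write_subnetwork(sn, file.path(out_dir, "subnet"))
      }
      cls <- classify_nodes(sn, genes)
      list(records_in = length(genes$genes),
           records_out = length(cls$seeds),
           records_dropped = length(sn$excluded_seeds),
           n_nodes = length(sn$nodes),
           n_edges = nrow(sn$edges),
           n_linkers = length(cls$linkers),
           seed_coverage = cls$seed_coverage)
    })
  }

  if ("nullcmp" %in% stages) {
    report$nullcmp <- run_stage("nullcmp", {
      sn <- results$subnetwork
      if (is.null(sn)) stop("needs a subnet stage")
      obs <- interactome(sn$edges, nodes = sn$nodes)
      cmp <- compare_to_null(obs, n_replicates = replicates, seed = seed)
      results$null_comparison <- cmp
      if (!is.null(out_dir)) {
        utils::write.table(cmp, file.path(out_dir, "null_comparison.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      list(records_in = replicates, records_out = replicates,
           records_dropped = 0L,
           z = stats::setNames(cmp$z, cmp$statistic))
    })
  }

  report$results <- results
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (stage in setdiff(names(x), "results")) {
    r <- x[[stage]]
    cat(sprintf("  %-9s in=%d out=%d dropped=%d\n", stage,
                r$records_in, r$records_out, r$records_dropped))
  }
  invisible(x)
}

# ---- config plumbing -----------------------------------------------------

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (grepl("\\.ya?ml$", config) &&
        requireNamespace("yaml", quietly = TRUE)) {
      config <- yaml::read_yaml(config)
    } else {
      lines <- readLines(config, warn = FALSE)
      lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
      kv <- strsplit(lines, "=", fixed = TRUE)
      config <- stats::setNames(
        lapply(kv, function(x) utils::type.convert(trimws(paste(x[-1L], collapse = "=")),
                                                   as.is = TRUE)),
        vapply(kv, function(x) trimws(x[[1L]]), character(1)))
      if (!is.null(config$stages)) {
        config$stages <- trimws(strsplit(as.character(config$stages), ",")[[1L]])
      }
    }
  }
  if (!is.list(config)) stop("config must be a named list or a file path")
  config
}

coerce_gene_set <- function(x) {
  if (inherits(x, "gene_set")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(read_gene_list(x))
  }
  if (is.character(x)) return(gene_set(x))
  stop("cannot interpret gene-set input")
}

coerce_gmt <- function(x) {
  if (is.list(x) && length(x) &&
      all(vapply(x, inherits, logical(1), "pathway_record"))) {
    return(x)
  }
  if (is.character(x) && length(x) == 1L) return(read_gmt(x))
  stop("cannot interpret GMT input")
}

coerce_pathway_table <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.character(x) && length(x) == 1L) return(load_alzgset_pathways(x))
  stop("cannot interpret pathway-table input")
}

coerce_network <- function(x) {
  if (inherits(x, "igraph")) return(x)
  if (is.character(x) && length(x) == 1L) {
    dialect <- if (grepl("\\.sif$", x)) "sif" else "tsv"
    return(read_edge_list(x, dialect = dialect))
  }
  stop("cannot interpret network input")
}
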