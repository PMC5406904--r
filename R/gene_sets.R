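#' Create a gene set
#'
#' A gene set is a named collection of unique gene symbols.  Symbols are
#' normalized on construction: whitespace-trimmed, upper-cased, and
#' deduplicated.  Mixed-case aliases of the same symbol therefore collapse to
#' a single entry, which is the convention used throughout the package for
#' query gene lists, pathway memberships, and network node labels.
#'
#' @param genes Character vector of gene symbols (may be empty).
#' @param name Non-empty identifier for the set.
#' @return An object of class `gene_set` with fields `name` and `genes`
#'   (sorted, unique, upper-case).
#' @examples
#' gene_set(c("apoe", "APOE", "App"), name = "demo")
#' @export
gene_set <- function(genes = character(), name = "gene_set") {
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name))) {
    stop("gene set 'name' must be a non-empty string")
  }
  genes <- normalize_symbols(genes)
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  if (length(x$genes)) {
    shown <- utils::head(x$genes, 10L)
    cat(" ", paste(shown, collapse = ", "),
        if (length(x$genes) > 10L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' @export
as.character.gene_set <- function(x, ...) x$genes

# Normalize raw symbols: trim, uppercase, drop duplicates, reject empties.
normalize_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  if (any(!nzchar(x))) stop("gene symbols must be non-empty strings")
  sort_sym(unique(x))
}

# Coerce gene_set | character to a plain character vector of symbols.
as_genes <- function(x) {
  if (inherits(x, "gene_set")) return(x$genes)
  if (is.character(x)) return(normalize_symbols(x))
  stop("expected a gene_set or a character vector of symbols")
}

#' Read a plain-text gene list
#'
#' One symbol per line; blank lines are ignored.  Lines containing internal
#' whitespace (more than one token) are rejected with the offending line
#' number, because they usually signal a misformatted multi-column file.
#' Header auto-detection is deliberately off: pass `header = TRUE` to skip
#' the first line explicitly.
#'
#' @param path Path to the file.
#' @param header Logical; drop the first line as a header.
#' @param name Name for the resulting set (default: file base name).
#' @return A [gene_set].
#' @export
read_gene_list <- function(path, header = FALSE, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (isTRUE(header) && length(lines)) lines <- lines[-1L]
  keep <- nzchar(trimws(lines))
  bad <- which(keep & grepl("\\S\\s+\\S", trimws(lines)))
  if (length(bad)) {
    stop(sprintf("unreadable gene-list line %d in %s: expected one symbol per line",
                 bad[1L] + as.integer(isTRUE(header)), path))
  }
  genes <- trimws(lines[keep])
  if (!length(genes)) stop("empty gene list: ", path)
  gene_set(genes, name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a gene list to a plain-text file
#'
#' @param x A [gene_set] or character vector.
#' @param path Output path; one upper-case symbol per line, sorted.
#' @export
write_gene_list <- function(x, path) {
  writeLines(as_genes(x), path)
  invisible(path)
}

#' Create a pathway record
#'
#' @param pathway_id Unique identifier within a database.
#' @param members Pathway membership, a [gene_set] or character vector
#'   (must be non-empty).
#' @param display_name Human-readable name (defaults to the id).
#' @param source Free-text tag for the originating database.
#' @return An object of class `pathway_record`.
#' @export
pathway_record <- function(pathway_id, members, display_name = pathway_id,
                           source = "") {
  if (!is.character(pathway_id) || length(pathway_id) != 1L ||
      !nzchar(pathway_id)) {
    stop("pathway_id must be a non-empty string")
  }
  members <- as_genes(members)
  if (!length(members)) stop("pathway '", pathway_id, "' has no members")
  structure(
    list(pathway_id = pathway_id, display_name = display_name,
         members = gene_set(members, name = pathway_id), source = source),
    class = "pathway_record"
  )
}

#' @export
print.pathway_record <- function(x, ...) {
  cat(sprintf("<pathway_record> %s (%s): %d members\n",
              x$pathway_id, x$source, length(x$members$genes)))
  invisible(x)
}

#' Read a GMT pathway database
#'
#' GMT is the de-facto standard gene-set format: one set per line,
#' tab-separated as `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate member symbols within a line are collapsed; duplicate set names
#' across lines are an error because set names are used as keys downstream.
#'
#' @param path Path to a `.gmt` file.
#' @param source Source tag stored on each record (default: file base name).
#' @return A list of [pathway_record] objects.
#' @export
read_gmt <- function(path, source = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  source <- source %||% basename(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  records <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d in %s: fewer than 3 fields", i, path))
    }
    records[[i]] <- pathway_record(
      pathway_id = trimws(fields[[1L]]),
      display_name = trimws(fields[[2L]]),
      members = fields[-(1:2)],
      source = source
    )
  }
  ids <- vapply(records, function(r) r$pathway_id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate pathway names in ", path, ": ", paste(dup, collapse = ", "))
  }
  records
}

#' Write pathway records to a GMT file
#'
#' @param records List of [pathway_record] objects.
#' @param path Output path.
#' @export
write_gmt <- function(records, path) {
  lines <- vapply(records, function(r) {
    paste(c(r$pathway_id, r$display_name, r$members$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
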