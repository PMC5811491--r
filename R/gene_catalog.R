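#' Normalize gene symbols
#'
#' Canonicalizes raw gene identifiers to trimmed, uppercased HGNC-style
#' tokens. No alias or cross-identifier mapping is attempted: normalization
#' is deliberately restricted to whitespace and case so that every mapping
#' decision is auditable from the input files alone.
#'
#' @param x character vector of raw symbols.
#' @param context optional label (e.g. a file name) used in error messages.
#' @return character vector of normalized symbols, same length as `x`.
#' @export
#' @examples
#' normalize_symbols(c(" drd2 ", "CHRNA7"))
normalize_symbols <- function(x, context = NULL) {
  x <- as.character(x)
  trimmed <- trimws(x)
  bad <- is.na(trimmed) | !nzchar(trimmed)
  where <- if (is.null(context)) "" else paste0(" in ", context)
  if (any(bad)) {
    stop_("malformed gene symbol%s: entry %d is empty after trimming",
          where, which(bad)[1L])
  }
  if (any(grepl("[\t\n]", trimmed))) {
    stop_("malformed gene symbol%s: entry %d contains a tab or newline",
          where, which(grepl("[\t\n]", trimmed))[1L])
  }
  toupper(trimmed)
}

#' Construct a disease gene set
#'
#' A `gene_set` is a named, deduplicated, normalized set of gene symbols for
#' one disease, optionally tagged with the evidence sources it was merged
#' from (e.g. core / prioritized / association-study lists).
#'
#' @param members character vector of gene symbols (normalized on input).
#' @param name label for the set.
#' @param disease free-text disease label; defaults to `name`.
#' @param source_tags character vector of provenance labels.
#' @param provenance optional named list mapping each source name to the
#'   member symbols it contributed; retained for reporting only.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(members, name, disease = name,
                     source_tags = character(), provenance = NULL) {
  members <- sort(unique(normalize_symbols(members, context = name)))
  if (length(members) == 0L) stop_("gene set '%s' has no members", name)
  structure(
    list(name = as.character(name), disease = as.character(disease),
         source_tags = unique(as.character(source_tags)),
         members = members, provenance = provenance),
    class = "gene_set"
  )
}

#' @export
length.gene_set <- function(x) length(x$members)

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s (%s): %d genes\n", x$name, x$disease,
              length(x$members)))
  if (length(x$source_tags)) {
    cat("  sources:", paste(x$source_tags, collapse = ", "), "\n")
  }
  shown <- utils::head(x$members, 8L)
  cat("  ", paste(shown, collapse = ", "),
      if (length(x$members) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read a disease gene list from disk
#'
#' Supports plain-text lists (one symbol per line, `#` comments allowed) and
#' TSV files with a configurable symbol column. Duplicate symbols (after
#' normalization) are collapsed and the number collapsed is reported via
#' [message()].
#'
#' @param path path to the file.
#' @param name label for the resulting set; defaults to the file name stem.
#' @param format `"plain"` or `"tsv"`.
#' @param column for TSV input, the symbol column name or index.
#' @param disease,source_tag provenance labels; default to `name`.
#' @return a [gene_set()].
#' @export
read_gene_list <- function(path, name = NULL,
                           format = c("plain", "tsv"), column = 1L,
                           disease = NULL, source_tag = NULL) {
  if (!file.exists(path)) stop_("gene list file not found: '%s'", path)
  format <- match.arg(format)
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  disease <- disease %||% name
  source_tag <- source_tag %||% name

  if (format == "plain") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    raw <- lines[nzchar(lines)]
  } else {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    if (is.character(column)) {
      if (!column %in% names(tab)) {
        stop_("column '%s' not found in '%s' (columns: %s)", column, path,
              paste(names(tab), collapse = ", "))
      }
      raw <- tab[[column]]
    } else {
      if (ncol(tab) < column) stop_("'%s' has no column %d", path, column)
      raw <- tab[[column]]
    }
  }
  if (length(raw) == 0L) stop_("no gene symbols found in '%s'", path)

  syms <- normalize_symbols(raw, context = path)
  n_dup <- length(syms) - length(unique(syms))
  if (n_dup > 0L) {
    message(sprintf("%s: collapsed %d duplicate symbol(s)", path, n_dup))
  }
  members <- sort(unique(syms))
  gene_set(members, name = name, disease = disease, source_tags = source_tag,
           provenance = stats::setNames(list(members), name))
}

#' Merge gene sets from several evidence sources
#'
#' Takes the union of the member sets (the analysis downstream uses only the
#' union) while retaining a per-source provenance map so reports can break a
#' merged disease set down by evidence source.
#'
#' @param sets list of [gene_set()] objects (at least one).
#' @param name label for the merged set.
#' @param disease disease label; defaults to `name`.
#' @return a [gene_set()] whose members are the union of the inputs.
#' @export
merge_gene_sets <- function(sets, name, disease = name) {
  if (!is.list(sets) || length(sets) == 0L) {
    stop_("merge_gene_sets() needs at least one input gene set")
  }
  if (!all(vapply(sets, inherits, logical(1), "gene_set"))) {
    stop_("all inputs to merge_gene_sets() must be gene_set objects")
  }
  members <- sort(unique(unlist(lapply(sets, `[[`, "members"))))
  tags <- unique(unlist(lapply(sets, `[[`, "source_tags")))
  prov <- stats::setNames(lapply(sets, `[[`, "members"),
                          vapply(sets, `[[`, "", "name"))
  gene_set(members, name = name, disease = disease, source_tags = tags,
           provenance = prov)
}

#' Compare two disease gene sets
#'
#' Partitions the union of two gene sets into genes exclusive to each set and
#' genes shared by both.
#'
#' @param a,b [gene_set()] objects.
#' @return an `overlap_report`: a list with sorted character vectors
#'   `a_only`, `shared`, `b_only`, the input names and sizes, and a `counts`
#'   vector.
#' @export
compare_gene_sets <- function(a, b) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  shared <- intersect(a$members, b$members)
  a_only <- setdiff(a$members, shared)
  b_only <- setdiff(b$members, shared)
  structure(
    list(name_a = a$name, name_b = b$name,
         n_a = length(a$members), n_b = length(b$members),
         a_only = sort(a_only), shared = sort(shared), b_only = sort(b_only),
         counts = c(a_only = length(a_only), shared = length(shared),
                    b_only = length(b_only))),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> %s (%d) vs %s (%d)\n", x$name_a, x$n_a,
              x$name_b, x$n_b))
  cat(sprintf("  shared: %d | %s-only: %d | %s-only: %d\n",
              x$counts[["shared"]], x$name_a, x$counts[["a_only"]],
              x$name_b, x$counts[["b_only"]]))
  invisible(x)
}

#' Write a gene set as a sorted plain-text list
#'
#' @param x a [gene_set()] or character vector of symbols.
#' @param path output path.
#' @export
write_gene_list <- function(x, path) {
  writeLines(as_symbols(x), path)
  invisible(path)
}

#' Write an overlap report as TSV
#'
#' One row per gene in the union, with a `status` column taking values
#' `a_only`, `shared`, `b_only`.
#'
#' @param report an `overlap_report` from [compare_gene_sets()].
#' @param path output path.
#' @export
write_overlap_report <- function(report, path) {
  stopifnot(inherits(report, "overlap_report"))
  df <- data.frame(
    gene = c(report$a_only, report$shared, report$b_only),
    status = rep(c("a_only", "shared", "b_only"), report$counts),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$status, df$gene), , drop = FALSE]
  write_tsv(df, path)
}
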