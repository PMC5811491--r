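#' Construct an annotation collection
#'
#' An annotation collection maps term identifiers (KEGG pathways, GO
#' biological-process terms, ...) to member gene sets, together with the
#' background universe used for over-representation testing. When no explicit
#' universe is supplied, the union of all term members is used
#' (annotation-closure background, the usual convention for ORA tools).
#'
#' @param category label for the collection (e.g. `"pathway"`, `"go_bp"`).
#' @param term_ids character vector of unique term identifiers.
#' @param term_names character vector of human-readable names, parallel to
#'   `term_ids`.
#' @param members named list (by term id) of member symbol vectors.
#' @param universe optional explicit background; must contain every member.
#' @return object of class `annotation_collection`.
#' @export
annotation_collection <- function(category, term_ids, term_names, members,
                                  universe = NULL) {
  term_ids <- as.character(term_ids)
  if (anyDuplicated(term_ids)) {
    stop_("duplicate term id: '%s'", term_ids[duplicated(term_ids)][1L])
  }
  if (length(term_names) != length(term_ids) ||
      length(members) != length(term_ids)) {
    stop_("term_ids, term_names and members must have equal length")
  }
  members <- lapply(members, function(m) sort(unique(normalize_symbols(m))))
  if (any(lengths(members) == 0L)) {
    stop_("term '%s' has no members", term_ids[lengths(members) == 0L][1L])
  }
  names(members) <- term_ids
  all_members <- unique(unlist(members, use.names = FALSE))
  if (is.null(universe)) {
    universe <- all_members
  } else {
    universe <- sort(unique(normalize_symbols(universe)))
    missing <- setdiff(all_members, universe)
    if (length(missing)) {
      stop_("universe does not cover all term members (e.g. %s)", missing[1L])
    }
  }
  structure(
    list(category = as.character(category), term_ids = term_ids,
         term_names = stats::setNames(as.character(term_names), term_ids),
         members = members, universe = sort(universe)),
    class = "annotation_collection"
  )
}

#' @export
print.annotation_collection <- function(x, ...) {
  cat(sprintf("<annotation_collection> %s: %d terms, universe of %d genes\n",
              x$category, length(x$term_ids), length(x$universe)))
  invisible(x)
}

#' Read an annotation collection from a GMT file
#'
#' Standard GMT: one term per line, tab-separated fields
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path path to the GMT file.
#' @param category collection label.
#' @param universe optional explicit background universe; default is the
#'   union of all term members.
#' @return an [annotation_collection()].
#' @export
read_gmt <- function(path, category = "pathway", universe = NULL) {
  if (!file.exists(path)) stop_("GMT file not found: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) stop_("GMT file '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop_("malformed GMT line %d in '%s': expected >= 3 tab-separated fields",
          which(keep)[which(nf < 3L)[1L]], path)
  }
  ids <- vapply(fields, `[[`, "", 1L)
  nms <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  annotation_collection(category, ids, nms, members, universe = universe)
}

#' Write an annotation collection as GMT
#'
#' @param collection an [annotation_collection()].
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "annotation_collection"))
  lines <- vapply(collection$term_ids, function(id) {
    paste(c(id, collection$term_names[[id]], collection$members[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

check_hyper_counts <- function(k, n, K, N) {
  vals <- c(k, n, K, N)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != floor(vals))) {
    stop_("invalid counts: k, n, K, N must be non-negative integers")
  }
  if (any(n > N) || any(K > N) || any(k > pmin(n, K))) {
    stop_("invalid counts: require k <= min(n, K) and n, K <= N")
  }
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` for `X ~ hypergeometric(N, K, n)`:
#' the chance of drawing at least `k` annotated genes when `n` genes are
#' sampled without replacement from a universe of `N` genes of which `K`
#' carry the annotation. Arguments are recycled, so whole result tables can
#' be computed in one call.
#'
#' @param k observed overlap between the tested set and the term.
#' @param n tested-set size within the universe.
#' @param K term size within the universe.
#' @param N universe size.
#' @return numeric vector of upper-tail probabilities in (0, 1].
#' @export
#' @examples
#' hyper_tail_p(4, 5, 4, 10)  # 6/252
hyper_tail_p <- function(k, n, K, N) {
  check_hyper_counts(k, n, K, N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' EASE-style conservative over-representation p-value
#'
#' DAVID's EASE score: the hypergeometric upper tail recomputed with one
#' member removed from the observed overlap (`max(k - 1, 0)`) on the same
#' margins. Always at least as large as [hyper_tail_p()]; provided for
#' comparability with DAVID-based analyses.
#'
#' @inheritParams hyper_tail_p
#' @return numeric vector of probabilities in (0, 1].
#' @export
ease_p <- function(k, n, K, N) {
  if (any(k < 1)) stop_("ease_p() requires overlap k >= 1")
  check_hyper_counts(k, n, K, N)
  stats::phyper(pmax(k - 1, 0) - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: with `m` p-values sorted ascending,
#' `q_(i) = min_{j >= i} min(1, p_(j) * m / j)`, returned in input order.
#'
#' @param p numeric vector of raw p-values, each in (0, 1].
#' @return adjusted values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop_("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation analysis of a gene set
#'
#' Tests every term of the collection whose overlap with the gene set is at
#' least `min_overlap`, using `n` = number of input genes present in the
#' background universe. BH correction is applied across all tested terms of
#' this one run (one collection, one gene set). Input genes absent from the
#' universe are counted and reported via [message()] but never tested.
#'
#' @param genes a [gene_set()] or character vector of symbols.
#' @param collection an [annotation_collection()].
#' @param alpha significance threshold on the BH-adjusted value, in (0, 1).
#'   Conventional gates: 0.01 for pathway collections, 0.05 for GO-BP.
#' @param min_overlap minimum overlap for a term to enter testing (>= 1).
#' @param method `"hypergeometric"` (default) or `"ease"`.
#' @return data frame of class `enrichment_result`, sorted by raw p then
#'   term name, with columns `term_id`, `term_name`, `k`, `K`, `n`, `N`,
#'   `genes` (comma-joined sorted overlap), `p`, `p_bh`, `significant`.
#'   Attributes record `alpha`, `method`, the BH family size `m`, the number
#'   of unmapped input genes and the collection category.
#' @export
run_enrichment <- function(genes, collection, alpha = 0.01,
                           min_overlap = 2L,
                           method = c("hypergeometric", "ease")) {
  stopifnot(inherits(collection, "annotation_collection"))
  method <- match.arg(method)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop_("alpha must be a single value in (0, 1)")
  }
  if (min_overlap < 1L) stop_("min_overlap must be >= 1")

  gs <- as_symbols(genes)
  universe <- collection$universe
  mapped <- intersect(gs, universe)
  n_unmapped <- length(gs) - length(mapped)
  if (length(mapped) == 0L) {
    stop_("none of the %d input genes occur in the annotation universe",
          length(gs))
  }
  if (n_unmapped > 0L) {
    message(sprintf(
      "%d of %d input genes are outside the %s universe and were not tested",
      n_unmapped, length(gs), collection$category))
  }

  n <- length(mapped)
  N <- length(universe)
  overlap <- lapply(collection$members, function(m) intersect(mapped, m))
  k <- lengths(overlap)
  K <- lengths(collection$members)
  tested <- k >= min_overlap

  ids <- collection$term_ids[tested]
  kt <- unname(k[tested])
  Kt <- unname(K[tested])
  p <- switch(method,
              hypergeometric = hyper_tail_p(kt, n, Kt, N),
              ease = ease_p(kt, n, Kt, N))
  p_bh <- bh_adjust(p)

  res <- data.frame(
    term_id = ids,
    term_name = unname(collection$term_names[ids]),
    k = kt, K = Kt, n = n, N = N,
    genes = vapply(overlap[tested], function(g) paste(sort(g), collapse = ","),
                   ""),
    p = p, p_bh = p_bh,
    significant = p_bh < alpha,
    stringsAsFactors = FALSE
  )
  res <- res[order(res$p, res$term_name), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  attr(res, "method") <- method
  attr(res, "m") <- sum(tested)
  attr(res, "n_unmapped") <- n_unmapped
  attr(res, "category") <- collection$category
  class(res) <- c("enrichment_result", "data.frame")
  res
}

significant_terms <- function(tab, alpha = NULL) {
  if ("significant" %in% names(tab)) {
    tab[as.logical(tab$significant), , drop = FALSE]
  } else {
    if (is.null(alpha)) {
      stop_("table has no 'significant' column; supply alpha to gate on p_bh")
    }
    tab[tab$p_bh < alpha, , drop = FALSE]
  }
}

#' Compare the significant terms of two enrichment analyses
#'
#' Partitions the union of significant terms of two enrichment tables (from
#' the same collection, so term ids are comparable) into shared terms and
#' terms specific to either disease.
#'
#' @param table_a,table_b data frames with at least `term_id` and either a
#'   logical `significant` column or a `p_bh` column (gated at `alpha`).
#'   Typically [run_enrichment()] outputs.
#' @param alpha optional threshold used when a table lacks a `significant`
#'   column.
#' @return object of class `pathway_comparison`: data frames `shared`,
#'   `a_specific`, `b_specific` (term id/name with both tables' statistics
#'   where available, sorted by term name) and a `counts` vector.
#' @export
compare_enrichments <- function(table_a, table_b, alpha = NULL) {
  sa <- significant_terms(table_a, alpha)
  sb <- significant_terms(table_b, alpha)
  col_or_na <- function(tab, col, ids) {
    i <- match(ids, tab$term_id)
    if (col %in% names(tab)) tab[[col]][i] else rep(NA_real_, length(ids))
  }
  build <- function(ids) {
    name_a <- if ("term_name" %in% names(sa)) sa$term_name[match(ids, sa$term_id)] else NULL
    name_b <- if ("term_name" %in% names(sb)) sb$term_name[match(ids, sb$term_id)] else NULL
    nm <- name_a %||% rep(NA_character_, length(ids))
    if (!is.null(name_b)) nm <- ifelse(is.na(nm), name_b, nm)
    nm <- ifelse(is.na(nm), ids, nm)
    out <- data.frame(
      term_id = ids, term_name = nm,
      p_a = col_or_na(sa, "p", ids), p_bh_a = col_or_na(sa, "p_bh", ids),
      p_b = col_or_na(sb, "p", ids), p_bh_b = col_or_na(sb, "p_bh", ids),
      stringsAsFactors = FALSE
    )
    out <- out[order(out$term_name, out$term_id), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  shared_ids <- intersect(sa$term_id, sb$term_id)
  structure(
    list(shared = build(shared_ids),
         a_specific = build(setdiff(sa$term_id, shared_ids)),
         b_specific = build(setdiff(sb$term_id, shared_ids)),
         counts = c(shared = length(shared_ids),
                    a_specific = length(setdiff(sa$term_id, shared_ids)),
                    b_specific = length(setdiff(sb$term_id, shared_ids)))),
    class = "pathway_comparison"
  )
}

#' @export
print.pathway_comparison <- function(x, ...) {
  cat(sprintf(
    "<pathway_comparison> shared: %d | A-specific: %d | B-specific: %d\n",
    x$counts[["shared"]], x$counts[["a_specific"]], x$counts[["b_specific"]]))
  invisible(x)
}

#' Break a term's members down by disease membership
#'
#' Partitions the member genes of one annotation term into genes found only
#' in disease set A, only in B, in both, or in neither ("unassigned"). This
#' is the per-pathway view used to discuss disease-specific pathways that
#' still carry genes of the other disease.
#'
#' @param term_id the term to break down.
#' @param collection the [annotation_collection()] containing the term.
#' @param set_a,set_b [gene_set()] objects.
#' @return list of class `term_gene_breakdown` with sorted character vectors
#'   `a_only`, `b_only`, `both`, `unassigned` partitioning the term members.
#' @export
pathway_gene_breakdown <- function(term_id, collection, set_a, set_b) {
  stopifnot(inherits(collection, "annotation_collection"))
  if (!term_id %in% collection$term_ids) {
    stop_("unknown term id: '%s'", term_id)
  }
  m <- collection$members[[term_id]]
  a <- as_symbols(set_a)
  b <- as_symbols(set_b)
  structure(
    list(term_id = term_id,
         term_name = unname(collection$term_names[[term_id]]),
         a_only = sort(setdiff(intersect(m, a), b)),
         b_only = sort(setdiff(intersect(m, b), a)),
         both = sort(intersect(m, intersect(a, b))),
         unassigned = sort(setdiff(m, union(a, b)))),
    class = "term_gene_breakdown"
  )
}

#' Read an enrichment table from TSV
#'
#' Reads a tab-separated significant-term table (such as the shipped
#' published pathway tables, or a [write_enrichment_tsv()] output) into a
#' data frame usable by [compare_enrichments()]. Requires a `term_id`
#' column; `p` and `p_bh` are parsed as numeric when present.
#'
#' @param path path to the TSV file.
#' @return data frame.
#' @export
read_enrichment_tsv <- function(path) {
  if (!file.exists(path)) stop_("enrichment table not found: '%s'", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"term_id" %in% names(tab)) {
    stop_("'%s' has no 'term_id' column", path)
  }
  for (col in intersect(c("p", "p_bh"), names(tab))) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  if ("significant" %in% names(tab)) {
    tab$significant <- as.logical(tab$significant)
  }
  tab
}

#' Write an enrichment table as TSV
#'
#' P-values are serialized in scientific notation with six significant
#' digits so reruns produce byte-identical tables.
#'
#' @param result an `enrichment_result` (or compatible data frame).
#' @param path output path.
#' @export
write_enrichment_tsv <- function(result, path) {
  out <- as.data.frame(result)
  for (col in intersect(c("p", "p_bh"), names(out))) {
    out[[col]] <- sprintf("%.5e", out[[col]])
  }
  write_tsv(out, path)
}
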