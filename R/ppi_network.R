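#' Construct an interaction network from endpoint vectors
#'
#' Internal-facing constructor; most users should start from
#' [read_ppi_edges()] / [clean_ppi()] or [generate_ppi()]. Edges are stored
#' as an explicit two-column data frame; when `cleaned = TRUE` they are
#' assumed canonical (from < to, unique, no self-loops) and the object
#' carries that promise for downstream operations.
#'
#' @param from,to character vectors of interaction endpoints.
#' @param cleaned whether the edge list is already canonical.
#' @return object of class `ppi_network` with fields `edges` (data frame
#'   `from`/`to`), `nodes` (sorted unique endpoints) and `cleaned`.
#' @export
ppi_network <- function(from, to, cleaned = FALSE) {
  stopifnot(length(from) == length(to))
  edges <- data.frame(from = normalize_symbols(as.character(from)),
                      to = normalize_symbols(as.character(to)),
                      stringsAsFactors = FALSE)
  if (nrow(edges)) edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(edges = edges, nodes = sort(unique(c(edges$from, edges$to))),
         cleaned = isTRUE(cleaned)),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d %s\n", length(x$nodes),
              nrow(x$edges),
              if (x$cleaned) "edges (cleaned)" else "raw interaction records"))
  invisible(x)
}

#' Read a protein-protein interaction edge list
#'
#' Two dialects are supported: two-column TSV (`geneA<TAB>geneB`, extra
#' columns ignored, `#` comment lines allowed) and SIF
#' (`source<WS>relation<WS>target1 target2 ...`, fanned out to one edge per
#' target). Parsing is raw: duplicates and self-interactions are retained so
#' that [clean_ppi()] can report exactly what it removed.
#'
#' @param path path to the edge-list file.
#' @param format `"tsv"` or `"sif"`.
#' @return an uncleaned [ppi_network()].
#' @export
read_ppi_edges <- function(path, format = c("tsv", "sif")) {
  if (!file.exists(path)) stop_("edge list file not found: '%s'", path)
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop_("edge list '%s' contains no records", path)

  if (format == "tsv") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    # drop a header line if the first two fields are not data-like; accept
    # conventional headers only (keeps the parser predictable)
    if (identical(tolower(fields[[1]][1:2]), c("from", "to"))) {
      fields <- fields[-1]
      lineno <- lineno[-1]
      if (length(fields) == 0L) stop_("edge list '%s' contains no records", path)
    }
    nf <- lengths(fields)
    if (any(nf < 2L)) {
      stop_("malformed edge record at line %d of '%s': expected >= 2 columns",
            lineno[which(nf < 2L)[1L]], path)
    }
    from <- vapply(fields, `[[`, "", 1L)
    to <- vapply(fields, `[[`, "", 2L)
  } else {
    fields <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 3L)) {
      stop_("malformed SIF record at line %d of '%s': expected source, relation and >= 1 target",
            lineno[which(nf < 3L)[1L]], path)
    }
    from <- unlist(lapply(fields, function(f) rep(f[[1L]], length(f) - 2L)))
    to <- unlist(lapply(fields, function(f) f[-(1:2)]))
  }
  ppi_network(normalize_symbols(from, context = path),
              normalize_symbols(to, context = path), cleaned = FALSE)
}

#' Clean an interaction network
#'
#' Removes self-interacting pairs, collapses redundant records (unordered
#' duplicates), canonicalizes edge orientation (from < to), and drops nodes
#' left without any interaction. The number of loops and duplicates removed
#' is reported via [message()]. Idempotent.
#'
#' @param net a [ppi_network()].
#' @return a cleaned [ppi_network()].
#' @export
clean_ppi <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  e <- net$edges
  loops <- e$from == e$to
  n_loops <- sum(loops)
  e <- e[!loops, , drop = FALSE]
  from <- pmin(e$from, e$to)
  to <- pmax(e$from, e$to)
  dup <- duplicated(edge_key(from, to))
  n_dup <- sum(dup)
  out <- ppi_network(from[!dup], to[!dup], cleaned = TRUE)
  if (n_loops > 0L || n_dup > 0L) {
    message(sprintf("clean_ppi: removed %d self-interaction(s) and %d redundant pair(s)",
                    n_loops, n_dup))
  }
  n_isolated <- length(net$nodes) - length(out$nodes)
  if (n_isolated > 0L) {
    message(sprintf("clean_ppi: dropped %d node(s) left without interactions",
                    n_isolated))
  }
  out
}

#' Extract a disease-specific seed + first-neighbor subnetwork
#'
#' Maps the disease genes ("seeds") onto the cleaned network and extracts
#' the subnetwork anchored at them. In the default `"seed_incident"` mode
#' the subnetwork keeps exactly the edges with at least one mapped-seed
#' endpoint; first neighbors are the non-seed endpoints of those edges. In
#' `"induced"` mode all edges among seeds and first neighbors are kept
#' (neighbor-neighbor edges included); the neighbor definition itself is
#' unchanged. Seeds absent from the network are reported, not an error.
#'
#' @param net a cleaned [ppi_network()].
#' @param seeds a [gene_set()] or character vector of seed symbols.
#' @param mode `"seed_incident"` (default) or `"induced"`.
#' @return object of class `disease_subnetwork` with fields `seeds` (mapped
#'   seeds), `neighbors`, `edges`, `unmapped_seeds` and `mode`.
#' @export
extract_disease_subnetwork <- function(net, seeds,
                                       mode = c("seed_incident", "induced")) {
  stopifnot(inherits(net, "ppi_network"))
  if (!isTRUE(net$cleaned)) {
    stop_("network must be cleaned first; run clean_ppi()")
  }
  mode <- match.arg(mode)
  sd <- as_symbols(seeds)
  mapped <- intersect(sd, net$nodes)
  unmapped <- setdiff(sd, net$nodes)
  if (length(mapped) == 0L) {
    stop_("none of the %d seed genes map onto the interaction network",
          length(sd))
  }
  if (length(unmapped) > 0L) {
    message(sprintf("%d of %d seed genes are absent from the network",
                    length(unmapped), length(sd)))
  }
  e <- net$edges
  inc <- e[e$from %in% mapped | e$to %in% mapped, , drop = FALSE]
  neighbors <- setdiff(unique(c(inc$from, inc$to)), mapped)
  edges <- if (mode == "induced") {
    keep_nodes <- c(mapped, neighbors)
    e[e$from %in% keep_nodes & e$to %in% keep_nodes, , drop = FALSE]
  } else {
    inc
  }
  rownames(edges) <- NULL
  structure(
    list(seeds = sort(mapped), neighbors = sort(neighbors), edges = edges,
         unmapped_seeds = sort(unmapped), mode = mode),
    class = "disease_subnetwork"
  )
}

#' @export
print.disease_subnetwork <- function(x, ...) {
  cat(sprintf("<disease_subnetwork> %d seeds + %d first neighbors, %d edges (%s mode)\n",
              length(x$seeds), length(x$neighbors), nrow(x$edges), x$mode))
  if (length(x$unmapped_seeds)) {
    cat(sprintf("  %d seed(s) unmapped\n", length(x$unmapped_seeds)))
  }
  invisible(x)
}

subnetwork_nodes <- function(sub) c(sub$seeds, sub$neighbors)

#' Intersect two disease subnetworks
#'
#' The shared (common) subnetwork: nodes present in both disease
#' subnetworks and interaction pairs present in both edge sets. Each shared
#' node is assigned a role from its membership in the two full disease gene
#' lists: `common_seed` (in both), `seed_a_only`, `seed_b_only`, or
#' `neighbor` (in neither). An empty intersection is a valid result and is
#' flagged via [message()].
#'
#' @param a,b `disease_subnetwork` objects extracted from the same cleaned
#'   parent network.
#' @param set_a,set_b the full disease gene lists ([gene_set()] or character
#'   vectors) used for role assignment.
#' @return object of class `shared_subnetwork` with fields `nodes`, `edges`,
#'   `roles` (named character vector over nodes) and `role_counts`.
#' @export
intersect_subnetworks <- function(a, b, set_a, set_b) {
  stopifnot(inherits(a, "disease_subnetwork"),
            inherits(b, "disease_subnetwork"))
  shared_nodes <- sort(intersect(subnetwork_nodes(a), subnetwork_nodes(b)))
  in_b <- edge_key(a$edges$from, a$edges$to) %in%
    edge_key(b$edges$from, b$edges$to)
  shared_edges <- a$edges[in_b, , drop = FALSE]
  rownames(shared_edges) <- NULL
  if (nrow(shared_edges) == 0L) {
    message("subnetwork intersection contains no shared interactions")
  }
  ga <- shared_nodes %in% as_symbols(set_a)
  gb <- shared_nodes %in% as_symbols(set_b)
  roles <- ifelse(ga & gb, "common_seed",
                  ifelse(ga, "seed_a_only",
                         ifelse(gb, "seed_b_only", "neighbor")))
  structure(
    list(nodes = shared_nodes, edges = shared_edges,
         roles = stats::setNames(roles, shared_nodes),
         role_counts = c(seed_a_only = sum(roles == "seed_a_only"),
                         seed_b_only = sum(roles == "seed_b_only"),
                         common_seed = sum(roles == "common_seed"),
                         neighbor = sum(roles == "neighbor"))),
    class = "shared_subnetwork"
  )
}

#' @export
print.shared_subnetwork <- function(x, ...) {
  cat(sprintf("<shared_subnetwork> %d shared nodes, %d shared interactions\n",
              length(x$nodes), nrow(x$edges)))
  cat(sprintf("  roles: %s\n",
              paste(names(x$role_counts), x$role_counts, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Degree of a node towards a target gene set
#'
#' Number of shared-subnetwork interactions joining `node` to a member of
#' `targets` (typically the common disease genes).
#'
#' @param shared a `shared_subnetwork`.
#' @param node a single gene symbol present in the shared subnetwork.
#' @param targets character vector or [gene_set()] of target genes.
#' @return integer count.
#' @export
degree_to_targets <- function(shared, node, targets) {
  stopifnot(inherits(shared, "shared_subnetwork"), length(node) == 1L)
  node <- normalize_symbols(node)
  if (!node %in% shared$nodes) {
    stop_("node '%s' is not in the shared subnetwork", node)
  }
  targets <- as_symbols(targets)
  e <- shared$edges
  sum((e$from == node & e$to %in% targets) |
        (e$to == node & e$from %in% targets))
}

# degree towards targets for every shared node at once
degrees_to_targets <- function(shared, targets) {
  e <- shared$edges
  hits <- c(e$to[e$from %in% targets], e$from[e$to %in% targets])
  counts <- table(factor(hits, levels = shared$nodes))
  stats::setNames(as.integer(counts), shared$nodes)
}

#' Predict new candidate genes by guilt-by-association
#'
#' Implements the degree-threshold rule: a node of the shared subnetwork
#' that is not itself a known disease gene, but directly interacts with at
#' least `min_degree` of the common disease genes, is reported as a new
#' candidate for both diseases. The exclusion set is the union of the two
#' full input gene lists, not only the mapped seeds.
#'
#' @param shared a `shared_subnetwork` from [intersect_subnetworks()].
#' @param common_genes the common disease genes present in the network (the
#'   degree targets); character vector or [gene_set()].
#' @param known_a,known_b the full disease gene lists; any member is
#'   excluded from candidacy.
#' @param min_degree minimum degree towards `common_genes` (default 5).
#' @return data frame of class `candidate_ranking` with columns `gene`,
#'   `degree_to_common` and `common_partners` (comma-joined sorted),
#'   ordered by degree descending then gene name.
#' @export
predict_candidates <- function(shared, common_genes, known_a, known_b,
                               min_degree = 5L) {
  stopifnot(inherits(shared, "shared_subnetwork"))
  if (min_degree < 1L) stop_("min_degree must be >= 1")
  common <- as_symbols(common_genes)
  known <- union(as_symbols(known_a), as_symbols(known_b))
  deg <- degrees_to_targets(shared, common)
  candidates <- setdiff(shared$nodes, known)
  keep <- candidates[deg[candidates] >= min_degree]
  e <- shared$edges
  partners <- vapply(keep, function(g) {
    p <- c(e$to[e$from == g], e$from[e$to == g])
    paste(sort(intersect(p, common)), collapse = ",")
  }, "")
  out <- data.frame(gene = keep,
                    degree_to_common = unname(deg[keep]),
                    common_partners = unname(partners),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree_to_common, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "min_degree") <- min_degree
  attr(out, "n_targets") <- length(common)
  class(out) <- c("candidate_ranking", "data.frame")
  out
}

#' Write an edge list as TSV or SIF
#'
#' @param x a `ppi_network`, `disease_subnetwork`, `shared_subnetwork` or a
#'   data frame with `from`/`to` columns.
#' @param path output path.
#' @param format `"tsv"` or `"sif"` (relation written as `pp`).
#' @export
write_edge_list <- function(x, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  edges <- if (is.data.frame(x)) x else x$edges
  stopifnot(all(c("from", "to") %in% names(edges)))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  if (format == "tsv") {
    write_tsv(edges[, c("from", "to")], path)
  } else {
    writeLines(paste(edges$from, "pp", edges$to, sep = "\t"), path)
  }
  invisible(path)
}
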