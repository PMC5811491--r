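#' Generate a synthetic gene universe
#'
#' Produces `n_genes` distinct zero-padded symbols (`G0001`, `G0002`, ...).
#' The universe is deterministic by construction; the `seed` argument is
#' accepted for interface symmetry with the other generators.
#'
#' @param n_genes number of genes (>= 1).
#' @param seed ignored; the universe carries no randomness.
#' @return character vector of `n_genes` distinct symbols.
#' @export
generate_universe <- function(n_genes, seed = NULL) {
  if (n_genes < 1L) stop_("n_genes must be >= 1")
  width <- max(4L, nchar(as.character(n_genes)))
  sprintf("G%0*d", width, seq_len(n_genes))
}

#' Generate a synthetic annotation collection
#'
#' Draws `n_terms` terms with sizes uniform on `size_range`, each term's
#' members sampled without replacement from the universe. The collection's
#' background universe is the full input universe, so enrichment tests on
#' synthetic data use exactly the generating population.
#'
#' @param universe character vector of gene symbols.
#' @param n_terms number of terms.
#' @param size_range integer vector `c(min, max)` of term sizes.
#' @param seed integer random seed.
#' @param category collection label.
#' @return an [annotation_collection()].
#' @export
generate_annotations <- function(universe, n_terms, size_range = c(10L, 50L),
                                 seed = 1L, category = "synthetic") {
  if (size_range[1] < 1L || size_range[2] > length(universe) ||
      size_range[1] > size_range[2]) {
    stop_("infeasible size_range [%d, %d] for a universe of %d genes",
          size_range[1], size_range[2], length(universe))
  }
  set.seed(seed)
  size_pool <- seq.int(size_range[1], size_range[2])
  sizes <- if (length(size_pool) == 1L) rep.int(size_pool, n_terms)
           else sample(size_pool, n_terms, replace = TRUE)
  members <- lapply(sizes, function(s) sort(sample(universe, s)))
  ids <- sprintf("T%04d", seq_len(n_terms))
  annotation_collection(category, ids,
                        paste("synthetic process", seq_len(n_terms)),
                        members, universe = universe)
}

#' Generate two overlapping disease gene sets with planted enrichment
#'
#' Builds two disease gene sets over a common universe so that (i) each set
#' contains `ceiling(hit_fraction * |term|)` members of each of its planted
#' terms, (ii) the two sets share exactly `shared_count` genes, and (iii)
#' everything else is uniform background. Shared genes are drawn
#' preferentially from the members of terms planted in both diseases, so the
#' shared-pathway comparison has known ground truth; background fill is
#' drawn outside all planted terms and kept disjoint between the two sets,
#' which makes the planted overlap counts exact.
#'
#' @param universe character vector of gene symbols.
#' @param collection an [annotation_collection()] over that universe.
#' @param planted_a,planted_b term ids planted in disease A / B.
#' @param set_size_a,set_size_b final set sizes.
#' @param shared_count exact number of genes common to both sets.
#' @param hit_fraction fraction of each planted term carried by its disease
#'   set (default 0.8).
#' @param seed integer random seed.
#' @param name_a,name_b labels for the generated sets.
#' @return list with elements `set_a`, `set_b` ([gene_set()] objects) and
#'   `truth` (class `synthetic_truth`: planted term ids, planted shared
#'   genes and the generation parameters).
#' @export
generate_disease_sets <- function(universe, collection, planted_a, planted_b,
                                  set_size_a, set_size_b, shared_count,
                                  hit_fraction = 0.8, seed = 1L,
                                  name_a = "disease_a", name_b = "disease_b") {
  stopifnot(inherits(collection, "annotation_collection"))
  bad <- setdiff(c(planted_a, planted_b), collection$term_ids)
  if (length(bad)) stop_("planted term id not in collection: '%s'", bad[1L])
  if (hit_fraction <= 0 || hit_fraction > 1) {
    stop_("hit_fraction must be in (0, 1]")
  }
  set.seed(seed)

  take_hits <- function(id) {
    m <- collection$members[[id]]
    sort(sample(m, ceiling(hit_fraction * length(m))))
  }
  planted_shared <- intersect(planted_a, planted_b)
  shared_hits <- stats::setNames(lapply(planted_shared, take_hits),
                                 planted_shared)
  hits_for <- function(ids) {
    unique(unlist(lapply(ids, function(id) {
      if (id %in% planted_shared) shared_hits[[id]] else take_hits(id)
    })))
  }
  hits_a <- hits_for(planted_a)
  hits_b <- hits_for(planted_b)

  core_shared <- intersect(hits_a, hits_b)
  if (length(core_shared) > shared_count) {
    stop_("infeasible: planted-term hits already share %d genes > shared_count = %d",
          length(core_shared), shared_count)
  }
  planted_members <- unique(unlist(
    collection$members[unique(c(planted_a, planted_b))]))

  extras <- character(0)
  need <- shared_count - length(core_shared)
  if (need > 0L) {
    pool1 <- setdiff(unique(unlist(collection$members[planted_shared])),
                     core_shared)
    take1 <- if (length(pool1)) sample(pool1, min(need, length(pool1)))
             else character(0)
    still <- need - length(take1)
    if (still > 0L) {
      pool2 <- setdiff(universe, c(planted_members, hits_a, hits_b, take1))
      if (still > length(pool2)) {
        stop_("infeasible: cannot place %d shared genes outside planted terms",
              still)
      }
      take1 <- c(take1, sample(pool2, still))
    }
    extras <- take1
  }
  shared_genes <- sort(unique(c(core_shared, extras)))

  base_a <- union(hits_a, shared_genes)
  base_b <- union(hits_b, shared_genes)
  fill_a <- set_size_a - length(base_a)
  fill_b <- set_size_b - length(base_b)
  if (fill_a < 0L || fill_b < 0L) {
    stop_("infeasible: planted content exceeds the requested set size")
  }
  bg_pool <- setdiff(universe, c(planted_members, base_a, base_b))
  if (fill_a + fill_b > length(bg_pool)) {
    stop_("infeasible: universe too small for the requested background fill")
  }
  bg <- sample(bg_pool, fill_a + fill_b)
  members_a <- sort(c(base_a, bg[seq_len(fill_a)]))
  members_b <- sort(c(base_b, bg[fill_a + seq_len(fill_b)]))

  truth <- structure(
    list(planted_terms_a = planted_a, planted_terms_b = planted_b,
         planted_shared_terms = planted_shared,
         planted_shared_genes = shared_genes,
         planted_candidates = NULL,
         params = list(hit_fraction = hit_fraction,
                       set_size_a = set_size_a, set_size_b = set_size_b,
                       shared_count = shared_count, seed = seed)),
    class = "synthetic_truth"
  )
  list(set_a = gene_set(members_a, name_a, source_tags = "synthetic"),
       set_b = gene_set(members_b, name_b, source_tags = "synthetic"),
       truth = truth)
}

# map linear indices of unordered pairs (i < j) over n items back to (i, j)
pair_from_index <- function(idx, n) {
  cum <- cumsum(seq(n - 1L, 1L))
  i <- findInterval(idx - 1, cum) + 1L
  j <- idx - c(0, cum)[i] + i
  cbind(i, j)
}

#' Generate a synthetic PPI network with planted candidate hubs
#'
#' Background interactions are drawn with an independent-pair
#' (Erdos-Renyi) model over the universe; each planted candidate node is
#' then wired to exactly its requested number of distinct shared genes.
#' Background edges between any planted candidate and any shared gene are
#' suppressed so the recorded wired degree always equals the realized
#' degree towards the shared genes, and every shared gene is guaranteed at
#' least one interaction (so the designated common genes are all present as
#' network nodes). The emitted network is clean by construction (no
#' self-loops, no duplicate pairs).
#'
#' @param universe character vector of gene symbols eligible as nodes.
#' @param background_edge_prob per-pair edge probability.
#' @param candidate_degrees integer vector; one planted candidate per entry,
#'   wired to that many shared genes (hubs at or above the prediction
#'   threshold, decoys below it).
#' @param shared_genes the designated common disease genes to wire against.
#' @param exclude genes barred from being picked as planted candidates
#'   (typically the two disease gene lists).
#' @param ensure_shared_nodes guarantee every shared gene at least one
#'   interaction (default `TRUE`); set `FALSE` for minimal networks whose
#'   edges are exactly the planted wiring plus background.
#' @param seed integer random seed.
#' @return list with `network` (cleaned [ppi_network()]) and `truth`
#'   (class `synthetic_truth`: `planted_candidates` data frame with the
#'   wired degrees, background edge count and generation parameters).
#' @export
generate_ppi <- function(universe, background_edge_prob, candidate_degrees,
                         shared_genes, exclude = character(),
                         ensure_shared_nodes = TRUE, seed = 1L) {
  shared_genes <- sort(unique(normalize_symbols(shared_genes)))
  if (any(candidate_degrees < 1L) ||
      any(candidate_degrees > length(shared_genes))) {
    stop_("infeasible wiring: candidate degrees must be in [1, %d]",
          length(shared_genes))
  }
  n <- length(universe)
  npairs <- n * (n - 1) / 2
  if (npairs >= 2^31) stop_("universe too large for pair indexing")
  set.seed(seed)

  pool <- setdiff(universe, c(shared_genes, as.character(exclude)))
  if (length(candidate_degrees) > length(pool)) {
    stop_("infeasible wiring: not enough eligible candidate nodes")
  }
  cands <- sample(pool, length(candidate_degrees))
  planted_from <- rep(cands, candidate_degrees)
  planted_to <- unlist(lapply(candidate_degrees,
                              function(d) sample(shared_genes, d)))

  n_bg <- stats::rbinom(1L, npairs, background_edge_prob)
  if (n_bg > 0L) {
    ij <- pair_from_index(sort(sample.int(npairs, n_bg)), n)
    bf <- universe[ij[, 1L]]
    bt <- universe[ij[, 2L]]
    drop <- (bf %in% cands & bt %in% shared_genes) |
      (bt %in% cands & bf %in% shared_genes)
    bf <- bf[!drop]
    bt <- bt[!drop]
  } else {
    bf <- bt <- character(0)
  }

  # every designated shared gene must exist as a network node: give genes
  # the planted wiring and background missed one interaction to a random
  # non-candidate partner (candidate degrees stay exact)
  present <- unique(c(planted_to, bf, bt))
  uncovered <- if (ensure_shared_nodes) setdiff(shared_genes, present)
               else character(0)
  cf <- ct <- character(0)
  if (length(uncovered)) {
    partner_pool <- setdiff(universe, cands)
    cf <- uncovered
    ct <- vapply(uncovered,
                 function(g) sample(setdiff(partner_pool, g), 1L), "")
  }
  from <- c(pmin(planted_from, planted_to), bf, pmin(cf, ct))
  to <- c(pmax(planted_from, planted_to), bt, pmax(cf, ct))
  dup <- duplicated(edge_key(from, to))
  net <- ppi_network(from[!dup], to[!dup], cleaned = TRUE)

  truth <- structure(
    list(planted_terms_a = NULL, planted_terms_b = NULL,
         planted_shared_terms = NULL,
         planted_shared_genes = shared_genes,
         planted_candidates = data.frame(gene = cands,
                                         wired_degree = as.integer(candidate_degrees),
                                         stringsAsFactors = FALSE),
         params = list(n_nodes = n,
                       background_edge_prob = background_edge_prob,
                       n_background_edges = length(bf),
                       n_coverage_edges = length(cf), seed = seed)),
    class = "synthetic_truth"
  )
  list(network = net, truth = truth)
}

fixture_presets <- list(
  desk = list(
    n_genes = 500L, n_terms = 40L, size_range = c(8L, 15L),
    n_planted_a = 3L, n_planted_b = 3L, n_planted_shared = 1L,
    set_size_a = 60L, set_size_b = 70L, shared_count = 15L,
    hit_fraction = 0.8, background_edge_prob = 2e-3,
    hub_degrees = c(5L, 6L, 7L), decoy_degrees = c(2L, 3L),
    n_absent_shared = 1L
  ),
  # the configuration of the comorbidity study this package models:
  # 276- and 331-gene disease sets sharing 52 genes, of which 51 occur in
  # the interaction network, and 11 plantable candidate hubs
  paper = list(
    n_genes = 2000L, n_terms = 100L, size_range = c(10L, 50L),
    n_planted_a = 5L, n_planted_b = 5L, n_planted_shared = 1L,
    set_size_a = 276L, set_size_b = 331L, shared_count = 52L,
    hit_fraction = 0.8, background_edge_prob = 5e-4,
    hub_degrees = c(5L, 6L, 7L, 8L, 9L, 5L, 6L, 7L, 8L, 9L, 7L),
    decoy_degrees = c(1L, 2L, 3L, 4L),
    n_absent_shared = 1L
  )
)

#' Write a complete synthetic input bundle
#'
#' Generates a universe, an annotation collection with planted terms, two
#' overlapping disease gene sets, and a PPI network with planted candidate
#' hubs, then writes them in the same formats the pipeline reads: plain-text
#' gene lists, a GMT collection, a TSV edge list, a ground-truth JSON and a
#' ready-to-run pipeline config. One integer seed drives child seeds for
#' every artifact, so bundles are byte-identical across reruns.
#'
#' The `"paper"` preset mirrors the comorbidity-study configuration this
#' package models (set sizes 276/331 sharing 52 genes, one shared gene
#' absent from the interaction network, 11 plantable hubs at degrees 5-9
#' plus 4 sub-threshold decoys); `"desk"` is a small variant for quick runs.
#'
#' @param dir output directory (created if needed).
#' @param preset `"desk"` or `"paper"`.
#' @param seed integer master seed.
#' @return (invisibly) list with the written `paths`, the combined `truth`
#'   record and the generated in-memory objects.
#' @export
write_fixture_bundle <- function(dir, preset = c("desk", "paper"), seed = 1L) {
  preset <- match.arg(preset)
  p <- fixture_presets[[preset]]
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop_("cannot create directory '%s'", dir)
  }

  universe <- generate_universe(p$n_genes)
  collection <- generate_annotations(universe, p$n_terms, p$size_range,
                                     seed = child_seed(seed, 1L),
                                     category = "pathway")

  set.seed(child_seed(seed, 2L))
  n_distinct <- p$n_planted_a + p$n_planted_b - p$n_planted_shared
  ids <- sample(collection$term_ids, n_distinct)
  planted_a <- ids[seq_len(p$n_planted_a)]
  planted_b <- c(ids[seq_len(p$n_planted_shared)],
                 ids[p$n_planted_a + seq_len(p$n_planted_b - p$n_planted_shared)])

  ds <- generate_disease_sets(universe, collection, planted_a, planted_b,
                              p$set_size_a, p$set_size_b, p$shared_count,
                              hit_fraction = p$hit_fraction,
                              seed = child_seed(seed, 3L))

  # hold some shared genes out of the network so unmapped seeds are exercised
  set.seed(child_seed(seed, 4L))
  absent <- sample(ds$truth$planted_shared_genes, p$n_absent_shared)
  wiring_targets <- setdiff(ds$truth$planted_shared_genes, absent)
  ppi <- generate_ppi(setdiff(universe, absent), p$background_edge_prob,
                      c(p$hub_degrees, p$decoy_degrees), wiring_targets,
                      exclude = union(ds$set_a$members, ds$set_b$members),
                      seed = child_seed(seed, 5L))

  paths <- list(
    genes_a = file.path(dir, "genes_a.txt"),
    genes_b = file.path(dir, "genes_b.txt"),
    gmt = file.path(dir, "pathways.gmt"),
    ppi = file.path(dir, "ppi_edges.tsv"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.yaml")
  )
  write_gene_list(ds$set_a, paths$genes_a)
  write_gene_list(ds$set_b, paths$genes_b)
  write_gmt(collection, paths$gmt)
  write_edge_list(ppi$network, paths$ppi)

  truth <- list(
    preset = preset, seed = seed,
    planted_terms_a = planted_a, planted_terms_b = planted_b,
    planted_shared_terms = intersect(planted_a, planted_b),
    planted_shared_genes = ds$truth$planted_shared_genes,
    shared_genes_absent_from_network = absent,
    planted_candidates = ppi$truth$planted_candidates,
    params = utils::modifyList(ds$truth$params, ppi$truth$params)
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)

  yaml::write_yaml(list(
    genes_a = "genes_a.txt", genes_b = "genes_b.txt",
    name_a = "disease_a", name_b = "disease_b",
    collections = list(list(path = "pathways.gmt", category = "pathway",
                            alpha = 0.01)),
    ppi = "ppi_edges.tsv",
    min_overlap = 2L, method = "hypergeometric",
    min_degree = 5L, edge_mode = "seed_incident"
  ), paths$config)

  invisible(list(paths = paths, truth = truth, universe = universe,
                 collection = collection, set_a = ds$set_a, set_b = ds$set_b,
                 network = ppi$network))
}
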