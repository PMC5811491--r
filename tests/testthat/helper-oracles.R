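# Independent oracles and small in-code fixtures shared across tests.

# Exhaustive-draw hypergeometric upper tail: enumerate every one of the
# C(N, n) equally likely draws of n genes from a universe 1..N in which the
# annotated genes are 1..K, and count draws with >= k annotated members.
# Only usable for small N; deliberately avoids phyper/dhyper.
oracle_hyper_tail <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  annotated_per_draw <- colSums(matrix(draws <= K, nrow = n))
  mean(annotated_per_draw >= k)
}

# Literal Benjamini-Hochberg step-up definition:
# q_(i) = min_{j >= i} min(1, p_(j) * m / j), mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q <- vapply(seq_len(m), function(i) {
    min(1, min(sorted[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

# igraph-based oracle for seed-incident subnetwork content
oracle_seed_incident <- function(edges, seeds) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  seeds <- intersect(seeds, igraph::V(g)$name)
  inc <- igraph::incident_edges(g, seeds)
  eids <- unique(unlist(lapply(inc, as.integer)))
  ends <- igraph::ends(g, eids)
  nbrs <- setdiff(unique(c(ends[, 1], ends[, 2])), seeds)
  list(seeds = sort(seeds), neighbors = sort(nbrs),
       edge_keys = sort(paste(pmin(ends[, 1], ends[, 2]),
                              pmax(ends[, 1], ends[, 2]))))
}

# small deterministic annotation collection over a 12-gene universe
tiny_collection <- function() {
  universe <- sprintf("U%02d", 1:12)
  annotation_collection(
    category = "pathway",
    term_ids = c("t1", "t2", "t3"),
    term_names = c("term one", "term two", "term three"),
    members = list(universe[1:4], universe[3:8], universe[9:12]),
    universe = universe
  )
}

random_edges <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- sprintf("N%03d", seq_len(n_nodes))
  pairs <- t(replicate(n_edges, sort(sample(nodes, 2))))
  pairs <- pairs[!duplicated(paste(pairs[, 1], pairs[, 2])), , drop = FALSE]
  data.frame(from = pairs[, 1], to = pairs[, 2], stringsAsFactors = FALSE)
}
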