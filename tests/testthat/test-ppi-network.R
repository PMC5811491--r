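test_that("edge-list parsing keeps raw records and flags malformed input", {
  f <- withr::local_tempfile(lines = c("A\tB", "B\tA", "C\tC"))
  net <- read_ppi_edges(f)
  expect_identical(nrow(net$edges), 3L)
  expect_false(net$cleaned)

  sif <- withr::local_tempfile(lines = c("A interacts B C", "d pp e"))
  nsif <- read_ppi_edges(sif, format = "sif")
  expect_identical(nrow(nsif$edges), 3L)
  expect_true(all(c("A", "B", "C", "D", "E") %in% nsif$nodes))

  empty <- withr::local_tempfile(lines = "# nothing here")
  expect_error(read_ppi_edges(empty), "no records")
  bad <- withr::local_tempfile(lines = c("A\tB", "C"))
  expect_error(read_ppi_edges(bad), "line 2")
  badsif <- withr::local_tempfile(lines = "A interacts")
  expect_error(read_ppi_edges(badsif, format = "sif"), "SIF")
})

test_that("cleaning removes loops, redundant pairs and isolated nodes, idempotently", {
  f <- withr::local_tempfile(lines = c("A\tB", "B\tA", "C\tC"))
  expect_message(net <- clean_ppi(read_ppi_edges(f)),
                 "1 self-interaction\\(s\\) and 1 redundant pair")
  expect_identical(net$edges, data.frame(from = "A", to = "B"))
  expect_identical(net$nodes, c("A", "B"))

  expect_identical(clean_ppi(net)$edges, net$edges)  # idempotent

  # planted duplicates and loops: cleaned edge count drops by exactly d + s
  set.seed(17)
  base <- random_edges(40, 120, seed = 17)
  d <- 9L; s <- 5L
  dup_rows <- base[sample(nrow(base), d), ]
  loops <- data.frame(from = sample(sprintf("N%03d", 1:40), s),
                      to = NA)
  loops$to <- loops$from
  raw <- rbind(base, dup_rows[, c("from", "to")], loops)
  raw_net <- ppi_network(raw$from, raw$to)
  cleaned <- suppressMessages(clean_ppi(raw_net))
  expect_identical(nrow(raw_net$edges) - nrow(cleaned$edges), d + s)
  expect_identical(nrow(cleaned$edges), nrow(base))
})

path_network <- function() {
  suppressMessages(clean_ppi(ppi_network(c("a", "b", "c"), c("b", "c", "d"))))
}

test_that("seed + first-neighbor extraction matches manual adjacency on a path", {
  net <- path_network()  # A - B - C - D
  s1 <- extract_disease_subnetwork(net, "a")
  expect_identical(s1$seeds, "A")
  expect_identical(s1$neighbors, "B")
  expect_identical(nrow(s1$edges), 1L)

  s2 <- extract_disease_subnetwork(net, "b")
  expect_identical(s2$neighbors, c("A", "C"))
  expect_identical(nrow(s2$edges), 2L)

  s3 <- extract_disease_subnetwork(net, c("b", "c"))
  expect_identical(s3$seeds, c("B", "C"))
  expect_identical(s3$neighbors, c("A", "D"))
  expect_identical(nrow(s3$edges), 3L)

  expect_error(extract_disease_subnetwork(net, "z"), "none of the")
  expect_message(um <- extract_disease_subnetwork(net, c("a", "zz")),
                 "absent from the network")
  expect_identical(um$unmapped_seeds, "ZZ")
})

test_that("extraction agrees with an igraph oracle and is monotone in seeds", {
  skip_if_not_installed("igraph")
  for (seed in c(3, 14, 80)) {
    edges <- random_edges(60, 150, seed = seed)
    net <- suppressMessages(clean_ppi(ppi_network(edges$from, edges$to)))
    set.seed(seed + 1)
    seeds <- sample(net$nodes, 8)
    sub <- extract_disease_subnetwork(net, seeds)
    oracle <- oracle_seed_incident(net$edges, toupper(seeds))
    expect_identical(sub$seeds, oracle$seeds)
    expect_identical(sub$neighbors, oracle$neighbors)
    expect_identical(sort(paste(sub$edges$from, sub$edges$to)),
                     oracle$edge_keys)

    # every neighbor has at least one edge to a seed
    for (nb in sub$neighbors) {
      expect_true(any((sub$edges$from == nb & sub$edges$to %in% sub$seeds) |
                        (sub$edges$to == nb & sub$edges$from %in% sub$seeds)))
    }
    # adding a seed never removes nodes or edges
    extra <- setdiff(net$nodes, sub$seeds)[1]
    bigger <- extract_disease_subnetwork(net, c(sub$seeds, extra))
    expect_true(all(c(sub$seeds, sub$neighbors) %in%
                      c(bigger$seeds, bigger$neighbors)))
    expect_true(all(paste(sub$edges$from, sub$edges$to) %in%
                      paste(bigger$edges$from, bigger$edges$to)))
  }
})

test_that("induced mode keeps neighbor-neighbor edges without changing neighbors", {
  # triangle B-C-D hanging off seed A: A-B, A-C, B-C, C-D
  net <- suppressMessages(clean_ppi(
    ppi_network(c("a", "a", "b", "c"), c("b", "c", "c", "d"))))
  inc <- extract_disease_subnetwork(net, "a", mode = "seed_incident")
  ind <- extract_disease_subnetwork(net, "a", mode = "induced")
  expect_identical(inc$neighbors, ind$neighbors)
  expect_identical(nrow(inc$edges), 2L)   # A-B, A-C only
  expect_identical(nrow(ind$edges), 3L)   # plus B-C; C-D stays out
})

test_that("subnetwork intersection is symmetric and assigns roles from the gene lists", {
  net <- suppressMessages(clean_ppi(
    ppi_network(c("x", "y", "z"), c("y", "z", "w"))))
  sa <- extract_disease_subnetwork(net, c("x", "y"))
  sb <- extract_disease_subnetwork(net, c("y", "w"))
  ga <- gene_set(c("X", "Y"), "a")
  gb <- gene_set(c("Y", "W"), "b")
  sh <- intersect_subnetworks(sa, sb, ga, gb)
  expect_identical(paste(sh$edges$from, sh$edges$to), c("X Y", "Y Z"))
  expect_identical(unname(sh$roles["Y"]), "common_seed")
  expect_identical(unname(sh$roles["X"]), "seed_a_only")
  expect_identical(unname(sh$roles["Z"]), "neighbor")
  expect_identical(sum(sh$role_counts), length(sh$nodes))

  sym <- intersect_subnetworks(sb, sa, ga, gb)
  expect_identical(sym$nodes, sh$nodes)
  expect_setequal(paste(sym$edges$from, sym$edges$to),
                  paste(sh$edges$from, sh$edges$to))

  same <- intersect_subnetworks(sa, sa, ga, gb)
  expect_identical(nrow(same$edges), nrow(sa$edges))

  expect_message(
    disjoint <- intersect_subnetworks(
      extract_disease_subnetwork(net, "x"),
      extract_disease_subnetwork(net, "w"), "X", "W"),
    "no shared interactions")
  expect_identical(nrow(disjoint$edges), 0L)
})

test_that("degree to targets counts exactly the edges into the target set", {
  # star: HUB wired to T1..T5 plus bystander B1
  net <- suppressMessages(clean_ppi(
    ppi_network(rep("hub", 6), c(paste0("t", 1:5), "b1"))))
  sub <- extract_disease_subnetwork(net, paste0("t", 1:5))
  sh <- intersect_subnetworks(sub, sub, paste0("t", 1:5), paste0("t", 1:5))
  expect_identical(degree_to_targets(sh, "HUB", paste0("T", 1:5)), 5L)
  expect_identical(degree_to_targets(sh, "T1", "B1"), 0L)
  expect_error(degree_to_targets(sh, "NOPE", "T1"), "not in the shared")

  # random graph: equals a brute-force edge scan
  set.seed(23)
  edges <- random_edges(50, 140, seed = 23)
  net2 <- suppressMessages(clean_ppi(ppi_network(edges$from, edges$to)))
  seeds <- sample(net2$nodes, 12)
  sub2 <- extract_disease_subnetwork(net2, seeds)
  sh2 <- intersect_subnetworks(sub2, sub2, seeds, seeds)
  targets <- sample(net2$nodes, 15)
  for (node in sample(sh2$nodes, 8)) {
    brute <- sum(apply(sh2$edges, 1, function(e) {
      (e[["from"]] == node && e[["to"]] %in% targets) ||
        (e[["to"]] == node && e[["from"]] %in% targets)
    }))
    expect_identical(degree_to_targets(sh2, node, targets), as.integer(brute))
  }
})

test_that("candidate prediction applies the degree threshold and exclusion rule", {
  common <- sprintf("C%02d", 1:8)
  hub5 <- data.frame(from = rep("newgene", 5), to = common[1:5])
  hub4 <- data.frame(from = rep("weakgene", 4), to = common[1:4])
  known_hub <- data.frame(from = rep("knowngene", 6), to = common[1:6])
  edges <- rbind(hub5, hub4, known_hub)
  net <- suppressMessages(clean_ppi(ppi_network(edges$from, edges$to)))
  seeds_a <- c(common, "KNOWNGENE")
  seeds_b <- c(common, "KNOWNGENE")
  sa <- extract_disease_subnetwork(net, seeds_a)
  sh <- intersect_subnetworks(sa, extract_disease_subnetwork(net, seeds_b),
                              seeds_a, seeds_b)
  cand <- predict_candidates(sh, common, seeds_a, seeds_b, min_degree = 5)
  expect_identical(cand$gene, "NEWGENE")
  expect_identical(cand$degree_to_common, 5L)
  expect_identical(cand$common_partners,
                   paste(common[1:5], collapse = ","))

  # lowering the threshold only ever adds candidates
  cand4 <- predict_candidates(sh, common, seeds_a, seeds_b, min_degree = 4)
  expect_true(all(cand$gene %in% cand4$gene))
  expect_setequal(cand4$gene, c("NEWGENE", "WEAKGENE"))
  # ranking: degree descending, then name
  expect_identical(cand4$gene[1], "NEWGENE")
})
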