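test_that("GMT parsing builds the annotation-closure universe and flags bad lines", {
  f <- withr::local_tempfile(lines = c("t1\tfirst term\tA\tB\tC",
                                       "t2\tsecond term\tC\tD\tE\tF"))
  coll <- read_gmt(f)
  expect_length(coll$universe, 6L)
  expect_identical(coll$members$t1, c("A", "B", "C"))

  bad <- withr::local_tempfile(lines = c("t1\tfirst\tA", "t2\tonlytwo"))
  expect_error(read_gmt(bad), "malformed GMT line 2")
  dup <- withr::local_tempfile(lines = c("t1\tx\tA", "t1\ty\tB"))
  expect_error(read_gmt(dup), "duplicate term id")
})

test_that("a 50-term collection round-trips through GMT write/read", {
  universe <- generate_universe(300)
  coll <- generate_annotations(universe, 50, c(5, 20), seed = 12)
  f <- withr::local_tempfile()
  write_gmt(coll, f)
  back <- read_gmt(f, category = coll$category, universe = universe)
  expect_identical(back$term_ids, coll$term_ids)
  expect_identical(back$members, coll$members)
  expect_identical(back$universe, coll$universe)
})

test_that("hypergeometric tail matches hand-derived values", {
  expect_identical(hyper_tail_p(0, 5, 4, 10), 1)
  # all four annotated genes drawn: C(6,1)/C(10,5) = 6/252
  expect_equal(hyper_tail_p(4, 5, 4, 10), 6 / 252, tolerance = 1e-14)
  # single draw: P = K/N
  expect_equal(hyper_tail_p(1, 1, 3, 10), 0.3, tolerance = 1e-14)
  # single-point mass when the draw is the whole universe
  expect_identical(hyper_tail_p(4, 4, 4, 4), 1)

  expect_error(hyper_tail_p(5, 5, 4, 10), "invalid counts")
  expect_error(hyper_tail_p(2, 5, 4, 3), "invalid counts")
  expect_error(hyper_tail_p(-1, 5, 4, 10), "invalid counts")
  expect_error(hyper_tail_p(1.5, 5, 4, 10), "invalid counts")
})

test_that("hypergeometric tail agrees with exhaustive draw enumeration for N <= 8", {
  # the full N <= 12 sweep lives in the acceptance suite; this is a fast guard
  for (N in 2:8) {
    for (n in 1:N) {
      for (K in 0:N) {
        for (k in 0:min(n, K)) {
          expect_equal(hyper_tail_p(k, n, K, N), oracle_hyper_tail(k, n, K, N),
                       tolerance = 1e-12,
                       label = sprintf("k=%d n=%d K=%d N=%d", k, n, K, N))
        }
      }
    }
  }
})

test_that("EASE score shifts the overlap down by one and dominates the raw tail", {
  expect_identical(ease_p(1, 1, 3, 10), 1)
  expect_equal(ease_p(4, 5, 4, 10), oracle_hyper_tail(3, 5, 4, 10),
               tolerance = 1e-12)
  expect_error(ease_p(0, 5, 4, 10), "k >= 1")
  for (N in c(6, 9, 12)) {
    for (n in c(2, 4, N - 1)) {
      for (K in c(1, 3, N - 2)) {
        for (k in seq_len(min(n, K))) {
          expect_gte(ease_p(k, n, K, N), hyper_tail_p(k, n, K, N))
        }
      }
    }
  }
})

test_that("BH adjustment reproduces the step-up definition", {
  expect_identical(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(bh_adjust(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\(0, 1\\]")

  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p) && all(adj <= 1))
  }
})

test_that("enrichment ranks a fully recovered term first and is order-invariant", {
  coll <- tiny_collection()
  res <- run_enrichment(coll$members$t1, coll, alpha = 0.05)
  expect_s3_class(res, "enrichment_result")
  expect_identical(res$term_id[1], "t1")
  expect_identical(res$k[1], 4L)
  expect_true(res$significant[1])
  expect_identical(res$genes[1], paste(coll$members$t1, collapse = ","))

  # permuted term order yields identical results
  perm <- annotation_collection("pathway", rev(coll$term_ids),
                                rev(unname(coll$term_names)),
                                rev(coll$members), coll$universe)
  res_perm <- run_enrichment(coll$members$t1, perm, alpha = 0.05)
  expect_equal(res, res_perm, ignore_attr = TRUE)
})

test_that("enrichment counts only universe-mapped genes and errors when none map", {
  coll <- tiny_collection()
  expect_message(
    res <- run_enrichment(c(coll$members$t1, "NOT_IN_UNIVERSE"), coll,
                          alpha = 0.05),
    "outside the pathway universe")
  expect_identical(unique(res$n), 4L)
  expect_identical(attr(res, "n_unmapped"), 1L)
  expect_error(run_enrichment(c("X1", "X2"), coll), "annotation universe")
})

test_that("significant-term count is monotone in alpha and raw p ignores other terms", {
  universe <- generate_universe(400)
  coll <- generate_annotations(universe, 30, c(8, 25), seed = 5)
  set.seed(6)
  genes <- sample(universe, 40)
  res <- run_enrichment(genes, coll, alpha = 0.5, min_overlap = 1L)
  n_sig <- vapply(c(0.5, 0.1, 0.05, 0.01), function(a) sum(res$p_bh < a),
                  integer(1))
  expect_true(all(diff(n_sig) <= 0))

  # dropping a term with no overlap leaves every other raw p unchanged
  # (explicit shared universe keeps N fixed)
  overlap_per_term <- vapply(coll$term_ids, function(id) {
    length(intersect(genes, coll$members[[id]]))
  }, integer(1))
  zero_terms <- coll$term_ids[overlap_per_term == 0L]
  expect_gt(length(zero_terms), 0L)
  keep <- setdiff(coll$term_ids, zero_terms[1])
  smaller <- annotation_collection("pathway", keep,
                                   unname(coll$term_names[keep]),
                                   coll$members[keep], universe)
  res2 <- run_enrichment(genes, smaller, alpha = 0.5, min_overlap = 1L)
  common <- intersect(res$term_id, res2$term_id)
  expect_equal(res2$p[match(common, res2$term_id)],
               res$p[match(common, res$term_id)], tolerance = 1e-14)
})

test_that("enrichment comparison partitions significant terms of two analyses", {
  a <- data.frame(term_id = c("x", "y", "z"), term_name = c("X", "Y", "Z"),
                  p = c(1e-5, 1e-4, 0.2), p_bh = c(3e-5, 2e-4, 0.2))
  b <- data.frame(term_id = c("y", "w"), term_name = c("Y", "W"),
                  p = c(1e-3, 1e-3), p_bh = c(2e-3, 2e-3))
  cmp <- compare_enrichments(a, b, alpha = 0.01)
  expect_identical(unname(cmp$counts), c(1L, 1L, 1L))
  expect_identical(cmp$shared$term_id, "y")
  expect_identical(cmp$a_specific$term_id, "x")
  expect_identical(cmp$b_specific$term_id, "w")
  # A-side statistics travel into the shared table
  expect_equal(cmp$shared$p_bh_a, 2e-4)

  same <- compare_enrichments(a, a, alpha = 0.01)
  expect_identical(unname(same$counts), c(2L, 0L, 0L))
  disj <- compare_enrichments(a, data.frame(term_id = "q", p_bh = 1e-6),
                              alpha = 0.01)
  expect_identical(unname(disj$counts["shared"]), 0L)
})

test_that("term gene breakdown partitions a term's members by disease", {
  coll <- annotation_collection("pathway", "t", "term",
                                list(c("G1", "G2", "G3", "G4", "G5")))
  a <- gene_set(c("G1", "G2", "G3"), "a")
  b <- gene_set(c("G3", "G4"), "b")
  br <- pathway_gene_breakdown("t", coll, a, b)
  expect_identical(br$a_only, c("G1", "G2"))
  expect_identical(br$b_only, "G4")
  expect_identical(br$both, "G3")
  expect_identical(br$unassigned, "G5")

  same <- pathway_gene_breakdown("t", coll, a, a)
  expect_length(same$a_only, 0L)
  expect_length(same$b_only, 0L)
  expect_error(pathway_gene_breakdown("nope", coll, a, b), "unknown term")

  # random partitions match a brute-force membership scan
  set.seed(31)
  pool <- sprintf("R%03d", 1:100)
  for (i in 1:10) {
    members <- sample(pool, 30)
    cl <- annotation_collection("pathway", "r", "rand", list(members))
    ga <- gene_set(sample(pool, 40), "ga")
    gb <- gene_set(sample(pool, 40), "gb")
    br <- pathway_gene_breakdown("r", cl, ga, gb)
    scan <- table(factor(
      ifelse(members %in% ga$members & members %in% gb$members, "both",
             ifelse(members %in% ga$members, "a_only",
                    ifelse(members %in% gb$members, "b_only", "unassigned"))),
      levels = c("a_only", "b_only", "both", "unassigned")))
    expect_identical(length(br$a_only), as.integer(scan[["a_only"]]))
    expect_identical(length(br$b_only), as.integer(scan[["b_only"]]))
    expect_identical(length(br$both), as.integer(scan[["both"]]))
    expect_identical(length(br$unassigned), as.integer(scan[["unassigned"]]))
    expect_setequal(c(br$a_only, br$b_only, br$both, br$unassigned), members)
  }
})
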