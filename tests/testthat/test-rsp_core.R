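test_that("two-hop enumeration handles star, triangle and absent targets", {
  star <- interaction_graph(rbind(c("T", "A"), c("A", "B"), c("A", "C")))
  expect_identical(enumerate_rsps("T", star),
                   data.frame(target = "T", g1 = c("A", "A"), g2 = c("B", "C"),
                              stringsAsFactors = FALSE))
  tri <- interaction_graph(rbind(c("T", "A"), c("A", "B"), c("B", "T")))
  # simple paths only: T may not recur as G2
  expect_identical(enumerate_rsps("T", tri),
                   data.frame(target = "T", g1 = c("A", "B"), g2 = c("B", "A"),
                              stringsAsFactors = FALSE))
  # relaxation flag admits the back-tracking paths
  expect_identical(nrow(enumerate_rsps("T", tri, allow_return = TRUE)), 4L)
  expect_message(out <- enumerate_rsps("Z", star), "not in PPI graph")
  expect_identical(nrow(out), 0L)
})

test_that("enumeration equals the exhaustive ordered-triple oracle on random graphs", {
  set.seed(23)
  for (rep in 1:10) {
    ed <- random_edges(sample(5:15, 1), stats::runif(1, 0.1, 0.4))
    if (nrow(ed) == 0L) next
    g <- interaction_graph(ed)
    target <- sample(g$nodes, 1)
    got <- enumerate_rsps(target, g)
    want <- brute_force_rsps(target, g$edges)
    rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("the Jaccard coefficient matches its worked value and edge cases", {
  expect_identical(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_identical(jaccard(c("x", "y"), c("x", "y")), 1)
  expect_identical(jaccard("x", "y"), 0)
  expect_identical(jaccard(character(0), character(0)), 0)
})

test_that("the Jaccard coefficient is symmetric and bounded on random set pairs", {
  set.seed(5)
  pool <- sprintf("t%02d", 1:20)
  for (rep in 1:50) {
    a <- sample(pool, sample(0:10, 1))
    b <- sample(pool, sample(0:10, 1))
    jc <- jaccard(a, b)
    expect_identical(jc, jaccard(b, a))
    expect_gte(jc, 0); expect_lte(jc, 1)
  }
})

test_that("the sub-pathway Jaccard score averages the two hop coefficients", {
  cat <- annotation_catalog(
    list(T = c("a", "b", "c"), G1 = c("b", "c", "d"), G2 = c("c", "d", "e")),
    "BP")
  s <- js_score("T", "G1", "G2", cat)
  expect_equal(s$score, 0.5)   # both hops are 2/4
  expect_true(s$viable)
  same <- annotation_catalog(list(T = "a", G1 = "a", G2 = "a"), "BP")
  expect_identical(js_score("T", "G1", "G2", same)$score, 1)
  # a zero first hop makes the path non-viable whatever the second hop
  gap <- annotation_catalog(
    list(T = c("a", "b"), G1 = c("c", "d"), G2 = c("c", "d")), "BP")
  s2 <- js_score("T", "G1", "G2", gap)
  expect_false(s2$viable)
  expect_identical(s2$jc2, 1)
})

test_that("pair p-value matches hand-enumerated cases and rejects infeasible overlaps", {
  expect_identical(pair_pvalue(4, 2, 2, 4), 1)       # first set is the universe
  expect_equal(pair_pvalue(2, 2, 2, 4), 1 / 6)        # one of C(4,2)=6 subsets
  expect_equal(pair_pvalue(3, 2, 1, 5), 0.6)          # C(3,1)C(2,1)/C(5,2)
  expect_error(pair_pvalue(3, 2, 3, 5), "infeasible")
  expect_error(pair_pvalue(3, 2, 0, 4), "infeasible") # shared < x + y - N
  expect_error(pair_pvalue(6, 2, 1, 5), "infeasible") # set larger than universe
})

test_that("pair p-value agrees with the hypergeometric distribution and its tail", {
  set.seed(31)
  for (rep in 1:50) {
    N <- sample(5:400, 1)
    x <- sample(0:N, 1); y <- sample(0:N, 1)
    lo <- max(0L, x + y - N); hi <- min(x, y)
    n <- if (lo == hi) lo else sample(lo:hi, 1)
    expect_equal(pair_pvalue(x, y, n, N), stats::dhyper(n, x, N - x, y),
                 tolerance = 1e-12)
    expect_equal(pair_pvalue(x, y, n, N, tail = TRUE),
                 stats::phyper(n - 1, x, N - x, y, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(pair_pvalue(x, y, n, N), pair_pvalue_literal(x, y, n, N),
                 tolerance = 1e-12)
  }
})

test_that("score_rsp takes the larger pair p-value and gates on the selected namespace", {
  bp <- annotation_catalog(
    list(T = c("a", "b", "c"), G1 = c("b", "c", "d"), G2 = c("d", "e")), "BP")
  mf <- annotation_catalog(
    list(T = c("m1", "m2"), G1 = c("m2", "m3"), G2 = c("m3", "m4")), "MF")
  rec <- score_rsp("T", "G1", "G2", bp, mf, "BP")
  N <- bp$universe_size
  p1 <- pair_pvalue(3, 3, 2, N)
  p2 <- pair_pvalue(3, 2, 1, N)
  expect_equal(rec$p1, p1)
  expect_equal(rec$p2, p2)
  expect_identical(rec$p_value, max(p1, p2))

  # symmetric term sets give p1 = p2 = p
  mfrec <- score_rsp("T", "G1", "G2", bp, mf, "MF")
  expect_identical(mfrec$p1, mfrec$p2)
  expect_identical(mfrec$p_value, mfrec$p1)

  # zero first-hop JC in the selected namespace discards the path,
  # even when the other namespace is viable
  bp0 <- annotation_catalog(
    list(T = c("a", "b"), G1 = c("c", "d"), G2 = c("c", "d")), "BP")
  expect_null(score_rsp("T", "G1", "G2", bp0, mf, "BP"))
  expect_false(is.null(score_rsp("T", "G1", "G2", bp0, mf, "MF")))
})

test_that("pathway tags require all three genes by default, any gene by flag", {
  pw <- annotation_catalog(
    list(T = c("P1", "P3"), G1 = c("P1", "P2"), G2 = c("P1", "P2")), "PATHWAY")
  expect_identical(assign_pathways("T", "G1", "G2", pw), "P1")
  expect_identical(assign_pathways("T", "G1", "G2", pw, rule = "any"),
                   c("P1", "P2", "P3"))
  expect_identical(assign_pathways("X", "Y", "Z", pw), character(0))
})

test_that("every retained record has a positive selected score and a p-value in [0,1]", {
  b <- fixture_bundle()
  targets <- unique(b$assoc$mirna_targets$gene)[1:5]
  for (tg in targets) {
    rec <- rspnet:::score_target_rsps(tg, b, "MF")
    if (nrow(rec) == 0L) next
    expect_true(all(rec$js_mf > 0 & rec$js_mf <= 1))
    expect_true(all(rec$p_value >= 0 & rec$p_value <= 1))
    expect_identical(rec$p_value, pmax(rec$p1, rec$p2))
  }
})
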