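test_that("contingency tables count the 2x2 partition of the universe", {
  u <- sprintf("G%02d", 1:20)
  ct <- contingency(u[1:5], u[2:6], u)
  expect_equal(c(ct$n11, ct$n10, ct$n01, ct$n00), c(4, 1, 1, 14))
  expect_equal(ct$N, 20)

  # query outside the universe contributes nothing
  ct2 <- contingency(c("X1", "X2"), u[1:5], u)
  expect_equal(ct2$n11 + ct2$n10, 0)

  # term == query
  ct3 <- contingency(u[1:5], u[1:5], u)
  expect_equal(c(ct3$n10, ct3$n01), c(0, 0))

  expect_error(contingency(u[1:5], u[1:5], character(0)), "universe")
})

test_that("kappa matches hand-derived values and conventions", {
  expect_equal(kappa_score(new_contingency(4, 1, 1, 14)), 11 / 15,
               tolerance = 1e-12)
  expect_equal(kappa_score(new_contingency(0, 5, 5, 10)), -1 / 3,
               tolerance = 1e-12)
  # identical non-trivial sets agree perfectly
  expect_equal(kappa_score(new_contingency(5, 0, 0, 15)), 1)
  # degenerate marginal (term covers the whole universe): Pe = 1 -> 0
  expect_equal(kappa_score(new_contingency(5, 0, 15, 0)), 0)
})

test_that("kappa is symmetric, bounded, and 1 only without disagreement", {
  u <- sprintf("G%03d", 1:60)
  set.seed(5)
  for (i in 1:50) {
    A <- sample(u, sample.int(40, 1))
    B <- sample(u, sample.int(40, 1))
    kab <- kappa_score(contingency(A, B, u))
    kba <- kappa_score(contingency(B, A, u))
    expect_identical(kab, kba)
    expect_true(kab >= -1 && kab <= 1)
    expect_equal(kappa_score(contingency(A, A, u)), 1)
  }
})

test_that("enrichment p is the exact hypergeometric tail", {
  ct <- new_contingency(4, 1, 1, 14)
  expect_equal(enrichment_p(ct), 76 / 15504, tolerance = 1e-12)
  # n11 = 0 -> full upper tail = 1
  expect_equal(enrichment_p(new_contingency(0, 5, 5, 10)), 1)
  # term = universe -> overlap is forced, p = 1
  expect_equal(enrichment_p(new_contingency(5, 0, 15, 0)), 1)
  # depletion tail complements: P(X<=4) + P(X>=5) covers all outcomes
  dep <- enrichment_p(ct, "depletion")
  expect_equal(dep, 1 - (1 / choose(20, 5)), tolerance = 1e-12)
})

test_that("BH adjustment matches the textbook example and stats::p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(9)
  for (i in 1:25) {
    p <- runif(sample.int(100, 1))
    q <- bh_adjust(p)
    expect_true(all(q >= 0 & q <= 1))
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("run_gsa ranks a strongly overlapping term first", {
  g <- sprintf("G%03d", 1:200)
  set.seed(21)
  terms <- c(list(annotation_term("planted", g[1:20], category = "pathway")),
             lapply(1:30, function(i) {
               annotation_term(sprintf("rnd%02d", i), sample(g, 20),
                               category = "pathway")
             }))
  store <- annotation_store(terms)
  query <- g[1:15]
  run <- run_gsa(query, store, q_threshold = NULL)
  expect_equal(run$results$term_id[1], "planted")
  expect_equal(run$n_tested, 31)
  # strict threshold: q_threshold = 0 keeps nothing
  run0 <- run_gsa(query, store, q_threshold = 0)
  expect_equal(nrow(run0$results), 0)
  # query identical to a term scores kappa = 1 for it
  run1 <- run_gsa(g[1:20], store, q_threshold = NULL)
  expect_equal(run1$results$kappa[run1$results$term_id == "planted"], 1)
})

test_that("run_gsa is invariant under gene relabeling", {
  g <- sprintf("G%03d", 1:80)
  set.seed(3)
  terms <- lapply(1:10, function(i) {
    annotation_term(sprintf("t%02d", i), sample(g, 15), category = "go")
  })
  query <- sample(g, 20)
  run <- run_gsa(query, annotation_store(terms), q_threshold = NULL)

  relabel <- stats::setNames(sprintf("H%03d", sample(80)), g)
  terms2 <- lapply(terms, function(tm) {
    annotation_term(tm$term_id, unname(relabel[tm$members]),
                    category = tm$category)
  })
  run2 <- run_gsa(unname(relabel[query]), annotation_store(terms2),
                  q_threshold = NULL)
  expect_equal(run2$results[, c("term_id", "n11", "kappa", "p_value",
                                "q_value")],
               run$results[, c("term_id", "n11", "kappa", "p_value",
                               "q_value")])
})

test_that("run_gsa validates inputs and supports per-category BH", {
  store <- tiny_store()
  expect_error(run_gsa(c("ZZZ"), store), "universe")
  g <- sprintf("G%02d", 1:20)
  pooled <- run_gsa(g[1:5], store, q_threshold = NULL)
  percat <- run_gsa(g[1:5], store, q_threshold = NULL,
                    bh_by_category = TRUE)
  expect_equal(sort(pooled$results$p_value), sort(percat$results$p_value))
  # per-category families adjust with smaller m
  for (cat in unique(percat$results$category)) {
    idx <- percat$results$category == cat
    expect_equal(percat$results$q_value[idx],
                 bh_adjust(percat$results$p_value[idx]))
  }
})

test_that("result tables are written sorted with 6 significant digits", {
  g <- sprintf("G%02d", 1:20)
  run <- run_gsa(g[1:5], tiny_store(), q_threshold = NULL)
  tf <- tempfile(fileext = ".tsv")
  write_gsa_table(run, tf)
  tab <- utils::read.delim(tf, stringsAsFactors = FALSE)
  expect_equal(names(tab),
               c("term_id", "category", "name", "n11", "term_size",
                 "query_size", "universe_size", "kappa", "p_value",
                 "q_value"))
  expect_equal(tab$term_id, run$results$term_id)
  expect_false(is.unsorted(tab$q_value))
  expect_equal(tab$kappa, as.numeric(sprintf("%.6g", run$results$kappa)))
})
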