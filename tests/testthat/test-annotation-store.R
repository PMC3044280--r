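test_that("GMT reading deduplicates members and rejects malformed input", {
  tf <- tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\tG1\tG2\tG2"), tf)
  terms <- read_gmt(tf, category = "pathway")
  expect_equal(terms$T1$members, c("G1", "G2"))
  expect_equal(terms$T1$category, "pathway")

  writeLines("T1", tf)
  expect_error(read_gmt(tf), "line 1")

  writeLines(c("T1\td\tG1", "T1\td\tG2"), tf)
  expect_error(read_gmt(tf), "T1")

  # empty-member line dropped with a warning
  writeLines(c("T1\td\tG1", "T2\td"), tf)
  expect_warning(terms <- read_gmt(tf), "T2")
  expect_equal(names(terms), "T1")
})

test_that("GMT round-trips preserve membership and are byte-stable", {
  store <- tiny_store()
  tf <- tempfile(fileext = ".gmt")
  write_gmt(store$terms, tf)
  back <- read_gmt(tf)
  expect_equal(names(back), names(store$terms))
  for (id in names(back)) {
    expect_equal(back[[id]]$members, store$terms[[id]]$members)
  }
  tf2 <- tempfile(fileext = ".gmt")
  write_gmt(back, tf2)
  expect_identical(readLines(tf), readLines(tf2))

  # empty list -> empty file
  write_gmt(list(), tf)
  expect_equal(length(readLines(tf)), 0)
})

test_that("hierarchies accept DAGs and reject cycles", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tC"), tf)
  h <- read_hierarchy(tf)
  expect_equal(nrow(h), 2)

  writeLines(c("A\tB", "B\tA"), tf)
  expect_error(read_hierarchy(tf), "cycle")

  # two parents for one child is a DAG, not an error
  writeLines(c("A\tC", "B\tC"), tf)
  expect_equal(nrow(read_hierarchy(tf)), 2)
})

test_that("network reading canonicalizes PPI and deduplicates edges", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("G1\tG2", "G2\tG1"), tf)
  nw <- read_network(tf, "ppi", "ppi")
  expect_false(nw$directed)
  expect_equal(nrow(nw$edges), 1)
  expect_equal(unlist(nw$edges[1, ], use.names = FALSE), c("G1", "G2"))

  writeLines(c("TF1\tG1", "TF1\tG1"), tf)
  nw2 <- read_network(tf, "tf_target")
  expect_true(nw2$directed)
  expect_equal(nrow(nw2$edges), 1)

  writeLines("G1\tG1", tf)
  expect_warning(nw3 <- read_network(tf, "ppi"), "self-loop")
  expect_equal(nrow(nw3$edges), 0)
})

test_that("universe is the union over selected categories and monotone", {
  store <- tiny_store()
  g <- sprintf("G%02d", 1:20)
  expect_equal(gene_universe(store, "pathway"), sort(g[1:6]))
  expect_equal(gene_universe(store, "all"), sort(g))
  # monotone in categories
  expect_true(all(gene_universe(store, "pathway") %in%
                    gene_universe(store, c("pathway", "go"))))
  expect_error(gene_universe(store, character(0)), "no annotation")
  expect_error(gene_universe(store, "nosuch"), "unknown")
  # superset of every term's members
  for (tm in store$terms) {
    expect_true(all(tm$members %in% gene_universe(store, "all")))
  }
})

test_that("term size filtering is bounded and idempotent", {
  store <- tiny_store()
  f <- filter_terms(store, min_size = 6)
  expect_false("T1" %in% names(f$terms))   # size 5 dropped
  expect_true(all(vapply(f$terms, function(tm) length(tm$members),
                         integer(1)) >= 6))
  # idempotent at fixed bounds
  f2 <- filter_terms(f, min_size = 6)
  expect_equal(names(f2$terms), names(f$terms))
  # identity bounds
  id <- filter_terms(store, min_size = 1, max_size = Inf)
  expect_equal(names(id$terms), names(store$terms))
})

test_that("filtering drops hierarchy edges touching removed terms", {
  g <- sprintf("G%02d", 1:10)
  store <- annotation_store(
    list(annotation_term("A", g[1:5], category = "go"),
         annotation_term("B", g[1:2], category = "go"),
         annotation_term("C", g[1], category = "go")),
    hierarchy = data.frame(parent = c("A", "B"), child = c("B", "C"),
                           stringsAsFactors = FALSE))
  f <- filter_terms(store, min_size = 2)
  expect_equal(names(f$terms), c("A", "B"))
  expect_equal(nrow(f$hierarchy), 1)  # (B,C) edge dropped with C
})

test_that("store construction validates hierarchy references and cycles", {
  g <- sprintf("G%02d", 1:10)
  terms <- list(annotation_term("A", g[1:3]), annotation_term("B", g[4:6]))
  expect_error(
    annotation_store(terms, hierarchy = data.frame(parent = "A",
                                                   child = "Z")),
    "unknown term")
  expect_error(
    annotation_store(terms,
                     hierarchy = data.frame(parent = c("A", "B"),
                                            child = c("B", "A"))),
    "cycle")
  expect_error(annotation_store(c(terms, terms[1])), "duplicate")
})

test_that("term search matches id and name, exact id first", {
  store <- tiny_store()
  hits <- search_terms(store, "apopt")
  expect_equal(names(hits), "T1")
  hits2 <- search_terms(store, "T3")
  expect_equal(names(hits2)[1], "T3")
  expect_equal(length(search_terms(store, "zzz")), 0)
})
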