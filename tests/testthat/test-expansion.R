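test_that("expansion follows typed edges in the requested direction", {
  path_net <- molecular_network("chain", "tf_target",
                                data.frame(source = c("A", "B"),
                                           target = c("B", "C")))
  expect_equal(expand_genes("A", path_net, "downstream", hops = 2)$expanded,
               c("A", "B", "C"))
  expect_equal(expand_genes("A", path_net, "downstream", hops = 1)$expanded,
               c("A", "B"))
  expect_equal(expand_genes("C", path_net, "upstream", hops = 2)$expanded,
               c("A", "B", "C"))
  # no outgoing edges: fixed point
  expect_equal(expand_genes("C", path_net, "downstream")$expanded, "C")
  # PPI expands both ways regardless of the direction flag
  ppi <- molecular_network("ppi", "ppi",
                           data.frame(source = "X", target = "Y"))
  expect_equal(expand_genes("Y", ppi, "downstream")$expanded, c("X", "Y"))
})

test_that("expansion steps record provenance and added IDs", {
  nw <- molecular_network("tfnet", "tf_target",
                          data.frame(source = "TF1", target = c("G1", "G2")))
  out <- expand_genes(c("TF1", "G1"), nw)
  expect_equal(out$step$added, "G2")
  expect_equal(out$step$frontier_before, c("G1", "TF1"))
  expect_equal(out$step$network_name, "tfnet")
  expect_equal(length(intersect(out$step$added, out$step$frontier_before)),
               0)
})

test_that("a miRNA seed expands through TF and PPI layers in turn", {
  # miRNA -> targets, then TF-target, then PPI interactors
  mir <- molecular_network("mirnet", "mirna_target",
                           data.frame(source = c("miR-A", "miR-B"),
                                      target = c("TF1", "G0")))
  tf <- molecular_network("tfnet", "tf_target",
                          data.frame(source = "TF1",
                                     target = c("G1", "G2", "G3")))
  ppi <- molecular_network("ppinet", "ppi",
                           data.frame(source = c("G1", "G2", "G3"),
                                      target = c("P1", "P2", "P3")))
  store <- annotation_store(list(), networks = list(mir, tf, ppi))
  res <- expand_chain(c("miR-A", "miR-B"), store,
                      "mirnet:downstream:1,tfnet:downstream:1,ppinet:both:1")
  expect_true(all(c("G1", "G2", "G3", "P1", "P2", "P3") %in% res$expanded))
  expect_equal(length(res$steps), 3)
  # chain output contains every single-step result (monotone composition)
  single <- expand_chain(c("miR-A", "miR-B"), store, "mirnet:downstream:1")
  expect_true(all(single$expanded %in% res$expanded))
  # empty chain is the identity
  ident <- expand_chain(c("miR-A"), store, list())
  expect_equal(ident$expanded, "miR-A")
  # mixed-namespace result filters down to genes
  expect_equal(restrict_to_genes(res$expanded, c("G0", "G1", "G2", "G3",
                                                 "P1", "P2", "P3", "TF1")),
               c("G0", "G1", "G2", "G3", "P1", "P2", "P3", "TF1"))
  expect_false(any(grepl("^miR", restrict_to_genes(
    res$expanded, c("G0", "G1", "G2", "G3")))))
  expect_error(expand_chain("miR-A", store, "nosuch:downstream:1"),
               "unknown network")
})

test_that("step order can change the expanded set on asymmetric networks", {
  # brute-force check on a 6-node toy under both orders
  n1 <- molecular_network("n1", "tf_target",
                          data.frame(source = "A", target = "B"))
  n2 <- molecular_network("n2", "tf_target",
                          data.frame(source = "B", target = "C"))
  store <- annotation_store(list(), networks = list(n1, n2))
  r12 <- expand_chain("A", store, "n1:downstream:1,n2:downstream:1")
  r21 <- expand_chain("A", store, "n2:downstream:1,n1:downstream:1")
  # oracle: n1 then n2 reaches C, n2 first finds nothing to follow
  expect_equal(r12$expanded, c("A", "B", "C"))
  expect_equal(r21$expanded, c("A", "B"))
})

test_that("chain specs parse network, direction and hops", {
  steps <- parse_chain_spec("tfnet:downstream:1,ppi:both:2,mir")
  expect_equal(length(steps), 3)
  expect_equal(steps[[2]],
               list(network = "ppi", direction = "both", hops = 2L))
  expect_equal(steps[[3]],
               list(network = "mir", direction = "downstream", hops = 1L))
  expect_error(parse_chain_spec(""), "non-empty|nzchar")
})

test_that("expansion is monotone in hops and has fixed points", {
  set.seed(77)
  for (i in 1:10) {
    nodes <- sprintf("N%02d", 1:20)
    ed <- data.frame(source = sample(nodes, 30, replace = TRUE),
                     target = sample(nodes, 30, replace = TRUE))
    nw <- molecular_network("w", "tf_target", ed)
    seed_ids <- sample(nodes, 3)
    prev <- character(0)
    for (h in 1:4) {
      cur <- expand_genes(seed_ids, nw, "downstream", hops = h)$expanded
      expect_true(all(seed_ids %in% cur))
      expect_true(all(prev %in% cur))
      prev <- cur
    }
    # closure: expanding the 4-hop closure (diameter < 20) again is identity
    closed <- expand_genes(seed_ids, nw, "downstream", hops = 25)$expanded
    expect_equal(expand_genes(closed, nw, "downstream", hops = 1)$expanded,
                 closed)
  }
})
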