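# Independent oracles used to cross-check the implementation, plus tiny
# in-code fixtures.  Every oracle takes a deliberately different route
# from the code it checks (per-element counting, explicit enumeration,
# brute-force scans).

# kappa by per-gene agreement counting: materialize the two binary
# membership vectors over the universe and tally concordance directly
oracle_kappa <- function(n11, n10, n01, n00) {
  x <- c(rep(1L, n11), rep(1L, n10), rep(0L, n01), rep(0L, n00))
  y <- c(rep(1L, n11), rep(0L, n10), rep(1L, n01), rep(0L, n00))
  po <- mean(x == y)
  pe <- mean(x) * mean(y) + mean(1 - x) * mean(1 - y)
  if (pe >= 1) return(0)
  (po - pe) / (1 - pe)
}

# upper-tail hypergeometric by explicit summation of point masses
oracle_hyper_p <- function(n11, n10, n01, n00) {
  N <- n11 + n10 + n01 + n00
  K <- n11 + n01
  n <- n11 + n10
  ks <- n11:min(K, n)
  if (length(ks) == 0 || n11 > min(K, n)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# BH by the literal min-over-suffix step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- vapply(seq_len(m), function(i) {
    min(pmin(1, ps[i:m] * m / (i:m)))
  }, numeric(1))
  q <- numeric(m)
  q[o] <- qs
  q
}

# all 2x2 tables (n11, n10, n01, n00) with total exactly N
enumerate_tables <- function(N) {
  out <- list()
  for (a in 0:N) for (b in 0:(N - a)) for (c in 0:(N - a - b)) {
    out[[length(out) + 1]] <- c(a, b, c, N - a - b - c)
  }
  out
}

# brute-force bounded reachability by repeated full edge scans
oracle_reach <- function(edges, seed, direction, hops, undirected) {
  visited <- unique(seed)
  frontier <- visited
  for (h in seq_len(hops)) {
    nxt <- character(0)
    for (v in frontier) {
      if (undirected || direction %in% c("downstream", "both")) {
        nxt <- c(nxt, edges$target[edges$source == v])
      }
      if (undirected || direction %in% c("upstream", "both")) {
        nxt <- c(nxt, edges$source[edges$target == v])
      }
    }
    nxt <- setdiff(unique(nxt), visited)
    if (length(nxt) == 0) break
    visited <- c(visited, nxt)
    frontier <- nxt
  }
  sort(visited)
}

# --- tiny fixtures -------------------------------------------------------

# the 3-row mapping table: one RefSeq alias, one ambiguous symbol
tiny_mapping <- function() {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("id_type\tsource_id\tcanonical_id",
               "refseq\tNM_130786\t1457",
               "symbol\tA1BG\t1",
               "symbol\tA1BG\t9999"), tf)
  read_id_mapping(tf)
}

# identity mapping table over a gene pool
identity_mapping <- function(genes) {
  df <- data.frame(id_type = "symbol", source_id = genes,
                   canonical_id = genes, stringsAsFactors = FALSE)
  class(df) <- c("id_mapping_table", "data.frame")
  df
}

# small hand-built store: 5 terms over a 20-gene universe
tiny_store <- function() {
  g <- sprintf("G%02d", 1:20)
  annotation_store(list(
    annotation_term("T1", g[1:5], name = "Apoptosis pathway",
                    category = "pathway"),
    annotation_term("T2", c(g[1:4], g[6]), name = "Cell cycle",
                    category = "pathway"),
    annotation_term("T3", g[6:15], name = "Signal transduction",
                    category = "go"),
    annotation_term("T4", g[11:20], name = "Metabolic process",
                    category = "go"),
    annotation_term("T5", g[1:20], name = "Everything", category = "go")))
}

random_gene_sets <- function(pool, n_sets, max_size) {
  lapply(seq_len(n_sets), function(i) {
    sample(pool, sample.int(max_size, 1))
  })
}
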