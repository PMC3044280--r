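# Deterministic synthetic-fixture generator with planted enrichment:
# produces a full annotation store (terms, hierarchy, typed networks), a
# mapping table and a query list, entirely from one seed, so the whole
# pipeline is testable without external data.

# run code under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic fixture generator
#'
#' The defaults define the reference simulation conditions used
#' throughout the test suite: 2,000 genes, two annotation categories of
#' 100 terms each (200 terms total, sizes 10-40), three planted terms, a
#' 40-gene query drawing fraction 0.6 of its size from the planted terms,
#' and one network of each supported kind.  The seed fully determines the
#' output.
#'
#' Planted terms share a common "core" of
#' `round(planted_overlap_fraction * query_size)` genes that is also
#' placed in the query, so each planted term individually overlaps the
#' query by that amount — a known ground truth for recovery tests.
#'
#' @param n_genes Size of the gene pool.
#' @param categories Annotation category labels.
#' @param n_terms_per_category Terms generated per category.
#' @param term_size_range Inclusive `(min, max)` term sizes.
#' @param n_planted_terms Number of planted (truly enriched) terms; they
#'   are placed in the first category.  0 gives a pure null fixture.
#' @param planted_overlap_fraction Fraction of the query drawn from each
#'   planted term, in (0, 1].
#' @param query_size Number of genes in the query list.
#' @param networks Named list `kind = n_edges` for the molecular
#'   networks to generate (names must be valid network kinds).
#' @param n_hierarchy_edges Parent-child edges generated within the last
#'   category (GO-like DAG).
#' @param seed Integer seed; same seed, same fixture, byte for byte.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(n_genes = 2000,
                           categories = c("pathway", "go"),
                           n_terms_per_category = 100,
                           term_size_range = c(10, 40),
                           n_planted_terms = 3,
                           planted_overlap_fraction = 0.6,
                           query_size = 40,
                           networks = list(ppi = 300, tf_target = 120,
                                           mirna_target = 60,
                                           drug_target = 30),
                           n_hierarchy_edges = 40,
                           seed = 1) {
  stopifnot(n_genes >= 10, length(categories) >= 1,
            n_terms_per_category >= 1,
            length(term_size_range) == 2,
            term_size_range[1] >= 2,
            term_size_range[1] <= term_size_range[2],
            term_size_range[2] <= n_genes,
            n_planted_terms >= 0,
            n_planted_terms <= n_terms_per_category,
            planted_overlap_fraction > 0, planted_overlap_fraction <= 1,
            query_size >= 1, query_size <= n_genes)
  if (length(networks) > 0) {
    stopifnot(all(names(networks) %in% .network_kinds))
  }
  structure(list(n_genes = n_genes, categories = categories,
                 n_terms_per_category = n_terms_per_category,
                 term_size_range = term_size_range,
                 n_planted_terms = n_planted_terms,
                 planted_overlap_fraction = planted_overlap_fraction,
                 query_size = query_size, networks = networks,
                 n_hierarchy_edges = n_hierarchy_edges,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

#' Simulate a fixture in memory
#'
#' Generates the full synthetic dataset described by a [fixture_config]
#' without touching the filesystem: an [annotation_store] (terms,
#' hierarchy, networks), an ID mapping table (identity rows plus a few
#' aliases and two deliberately ambiguous symbols), the query token list
#' and the planted term IDs.
#'
#' @param config A [fixture_config].
#' @return List with elements `config`, `genes`, `store`, `mapping`
#'   (an `id_mapping_table`), `query_tokens` and `planted_terms`.
#' @export
simulate_fixture <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  .with_seed(config$seed, {
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    core_size <- round(config$planted_overlap_fraction * config$query_size)
    core_size <- min(core_size, config$query_size)
    core <- if (config$n_planted_terms > 0) {
      sample(genes, core_size)
    } else {
      character(0)
    }
    query <- c(core, sample(setdiff(genes, core),
                            config$query_size - length(core)))

    sizes <- config$term_size_range
    planted_ids <- character(0)
    terms <- list()
    for (ci in seq_along(config$categories)) {
      cat_label <- config$categories[ci]
      for (j in seq_len(config$n_terms_per_category)) {
        id <- sprintf("%s_T%03d", cat_label, j)
        size <- sample(sizes[1]:sizes[2], 1)
        planted <- ci == 1 && j <= config$n_planted_terms
        members <- if (planted) {
          size <- max(size, length(core))
          c(core, sample(setdiff(genes, core), size - length(core)))
        } else {
          sample(genes, size)
        }
        if (planted) planted_ids <- c(planted_ids, id)
        terms[[id]] <- annotation_term(
          id, members,
          name = sprintf("Synthetic %s set %d", cat_label, j),
          category = cat_label)
      }
    }

    # GO-like DAG in the last category: parents always have smaller index
    hier_cat <- config$categories[length(config$categories)]
    k <- config$n_terms_per_category
    n_edges <- min(config$n_hierarchy_edges, max(k - 1, 0))
    hierarchy <- if (n_edges > 0 && k >= 2) {
      children <- sample(2:k, n_edges, replace = (n_edges > k - 1))
      parents <- vapply(children, function(j) sample.int(j - 1, 1),
                        integer(1))
      unique(data.frame(
        parent = sprintf("%s_T%03d", hier_cat, parents),
        child = sprintf("%s_T%03d", hier_cat, children),
        stringsAsFactors = FALSE))
    } else {
      data.frame(parent = character(0), child = character(0),
                 stringsAsFactors = FALSE)
    }

    networks <- list()
    for (kind in names(config$networks)) {
      n_e <- config$networks[[kind]]
      sources <- switch(kind,
        ppi = genes,
        tf_target = sample(genes, min(50, config$n_genes)),
        mirna_target = sprintf("miR-%02d", 1:15),
        drug_target = sprintf("DRUG%02d", 1:10))
      ed <- data.frame(source = sample(sources, n_e, replace = TRUE),
                       target = sample(genes, n_e, replace = TRUE),
                       stringsAsFactors = FALSE)
      if (kind == "ppi") ed <- ed[ed$source != ed$target, , drop = FALSE]
      networks[[kind]] <- molecular_network(kind, kind, ed)
    }

    # mapping: identity symbols for every gene, RefSeq-style aliases for
    # the first 25, and two deliberately ambiguous symbols
    n_alias <- min(25, config$n_genes)
    mapping <- rbind(
      data.frame(id_type = "symbol", source_id = genes,
                 canonical_id = genes, stringsAsFactors = FALSE),
      data.frame(id_type = "refseq",
                 source_id = sprintf("NM_%06d", seq_len(n_alias)),
                 canonical_id = genes[seq_len(n_alias)],
                 stringsAsFactors = FALSE),
      data.frame(id_type = "symbol",
                 source_id = rep(c("AMB1", "AMB2"), each = 2),
                 canonical_id = genes[1:4], stringsAsFactors = FALSE))
    class(mapping) <- c("id_mapping_table", "data.frame")

    list(config = config, genes = genes,
         store = annotation_store(terms, hierarchy = hierarchy,
                                  networks = networks),
         mapping = mapping,
         query_tokens = query,
         planted_terms = planted_ids)
  })
}

#' Write a simulated fixture to a directory
#'
#' Materializes [simulate_fixture()] output as the plain-text files the
#' CLI and readers consume: `mapping.tsv`, one `<category>.gmt` per
#' category, `hierarchy.tsv`, `network_<kind>.tsv`, `query.txt`,
#' `planted_terms.txt` and a `fixture_manifest.txt` recording the
#' configuration.  Output is byte-identical across runs at a fixed seed.
#'
#' @param config A [fixture_config].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly; the simulated fixture is attached as
#'   attribute `"fixture"`.
#' @export
generate_fixture <- function(config, outdir) {
  fx <- simulate_fixture(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, ...)

  m <- fx$mapping
  writeLines(c("id_type\tsource_id\tcanonical_id",
               sprintf("%s\t%s\t%s", m$id_type, m$source_id,
                       m$canonical_id)), fp("mapping.tsv"))

  for (cat_label in config$categories) {
    keep <- vapply(fx$store$terms, function(tm) tm$category == cat_label,
                   logical(1))
    write_gmt(fx$store$terms[keep], fp(paste0(cat_label, ".gmt")))
  }

  h <- fx$store$hierarchy
  writeLines(c("parent_id\tchild_id",
               if (nrow(h) > 0) sprintf("%s\t%s", h$parent, h$child)),
             fp("hierarchy.tsv"))

  for (nm in names(fx$store$networks)) {
    e <- fx$store$networks[[nm]]$edges
    writeLines(c("source\ttarget",
                 if (nrow(e) > 0) sprintf("%s\t%s", e$source, e$target)),
               fp(paste0("network_", nm, ".tsv")))
  }

  writeLines(fx$query_tokens, fp("query.txt"))
  writeLines(fx$planted_terms, fp("planted_terms.txt"))

  writeLines(c(sprintf("seed: %d", config$seed),
               sprintf("n_genes: %d", config$n_genes),
               sprintf("categories: %s",
                       paste(config$categories, collapse = ",")),
               sprintf("n_terms_per_category: %d",
                       config$n_terms_per_category),
               sprintf("term_size_range: %d-%d", config$term_size_range[1],
                       config$term_size_range[2]),
               sprintf("n_planted_terms: %d", config$n_planted_terms),
               sprintf("planted_overlap_fraction: %g",
                       config$planted_overlap_fraction),
               sprintf("query_size: %d", config$query_size)),
             fp("fixture_manifest.txt"))

  out <- outdir
  attr(out, "fixture") <- fx
  invisible(out)
}
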