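# Annotation-relationship network: pairwise kappa among enriched terms,
# thresholded into an undirected weighted graph, exported in standard
# graph formats (Cytoscape SIF, GraphML, MCL ABC, TSV).

#' Pairwise kappa between annotation terms
#'
#' Computes Cohen's kappa for every unordered pair of terms over a common
#' background universe — the same contingency + kappa machinery used for
#' enrichment scoring, so an edge weight can be reproduced exactly from
#' the term memberships.  Cross-category pairs are included; kappa is
#' symmetric in its arguments.
#'
#' @param terms List of [annotation_term] objects (at least 2).
#' @param universe Character vector: the background universe (the same
#'   one used for the GSA run, for consistency).
#' @return Data frame with columns `term_a`, `term_b`
#'   (`term_a < term_b` lexicographically) and `kappa`; `choose(k, 2)`
#'   rows for `k` terms.
#' @export
pairwise_kappa <- function(terms, universe) {
  if (length(terms) < 2) stop("need at least 2 terms for pairwise kappa")
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("universe must be non-empty")
  ids <- vapply(terms, function(tm) tm$term_id, character(1))
  o <- order(ids, method = "radix")
  terms <- terms[o]
  ids <- ids[o]
  k <- length(terms)
  pairs <- utils::combn(k, 2)
  kap <- vapply(seq_len(ncol(pairs)), function(j) {
    a <- terms[[pairs[1, j]]]
    b <- terms[[pairs[2, j]]]
    kappa_score(contingency(a$members, b$members, universe))
  }, numeric(1))
  data.frame(term_a = ids[pairs[1, ]], term_b = ids[pairs[2, ]],
             kappa = kap, stringsAsFactors = FALSE)
}

#' Build the annotation-relationship network from a GSA run
#'
#' Nodes are all terms passing the run's q-value threshold (isolated
#' nodes included); edges connect term pairs whose pairwise kappa over
#' the run's universe reaches `kappa_threshold`.  Edges may cross
#' annotation categories, which is how relations between heterogeneous
#' annotations (e.g. a miRNA target set and a disease signature) surface.
#' The default threshold 0.35 follows the DAVID functional-annotation-
#' clustering convention for kappa agreement.
#'
#' @param run A `gsa_run` from [run_gsa()].
#' @param store The [annotation_store] the run was made against (supplies
#'   term memberships).
#' @param kappa_threshold Minimum kappa for an edge (inclusive).
#' @return An object of class `term_network`: list with `nodes` (data
#'   frame `term_id`, `category`, `kappa`, `q_value`) and `edges` (data
#'   frame `term_a`, `term_b`, `kappa`, with `term_a < term_b`).
#' @export
build_term_network <- function(run, store, kappa_threshold = 0.35) {
  stopifnot(inherits(run, "gsa_run"), inherits(store, "annotation_store"))
  res <- run$results
  if (nrow(res) == 0) stop("GSA run has no passing results")
  nodes <- res[order(res$term_id, method = "radix"),
               c("term_id", "category", "kappa", "q_value"), drop = FALSE]
  rownames(nodes) <- NULL
  missing <- setdiff(nodes$term_id, names(store$terms))
  if (length(missing) > 0) {
    stop("store lacks term(s) from the run: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  if (nrow(nodes) >= 2) {
    pk <- pairwise_kappa(store$terms[nodes$term_id], run$universe)
    edges <- pk[pk$kappa >= kappa_threshold, , drop = FALSE]
    edges <- edges[order(edges$term_a, edges$term_b, method = "radix"), ,
                   drop = FALSE]
  } else {
    edges <- data.frame(term_a = character(0), term_b = character(0),
                        kappa = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 kappa_threshold = kappa_threshold),
            class = "term_network")
}

#' @export
print.term_network <- function(x, ...) {
  cat("term_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (kappa >=", x$kappa_threshold, ")\n")
  invisible(x)
}

#' Export a term network in a standard graph format
#'
#' Supported formats:
#' \describe{
#'   \item{`sif`}{Cytoscape simple interaction format: one
#'     `term_a TAB kappa TAB term_b` line per edge (interaction label
#'     literally `kappa`), plus one single-token line per isolated node.}
#'   \item{`abc`}{MCL input: `term_a TAB term_b TAB weight`, weight with
#'     6 decimals.}
#'   \item{`graphml`}{GraphML via igraph; nodes carry `category`,
#'     `kappa`, `q_value` attributes, edges carry `weight`.}
#'   \item{`tsv`}{Edge table with header `term_a`, `term_b`, `kappa`.}
#' }
#' All outputs are sorted, hence byte-stable for a given network.
#'
#' @param net A `term_network`.
#' @param path Output path.
#' @param format One of `"sif"`, `"graphml"`, `"abc"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(net, path, format = c("sif", "graphml", "abc",
                                               "tsv")) {
  stopifnot(inherits(net, "term_network"))
  format <- match.arg(format)
  e <- net$edges
  switch(format,
    sif = {
      isolated <- setdiff(net$nodes$term_id, c(e$term_a, e$term_b))
      writeLines(c(sprintf("%s\tkappa\t%s", e$term_a, e$term_b),
                   sort(isolated, method = "radix")), path)
    },
    abc = {
      writeLines(sprintf("%s\t%s\t%.6f", e$term_a, e$term_b, e$kappa), path)
    },
    tsv = {
      out <- data.frame(term_a = e$term_a, term_b = e$term_b,
                        kappa = sprintf("%.6f", e$kappa),
                        stringsAsFactors = FALSE)
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    },
    graphml = {
      g <- igraph::graph_from_data_frame(
        d = data.frame(from = e$term_a, to = e$term_b, weight = e$kappa,
                       stringsAsFactors = FALSE),
        directed = FALSE,
        vertices = data.frame(name = net$nodes$term_id,
                              category = net$nodes$category,
                              kappa = net$nodes$kappa,
                              q_value = net$nodes$q_value,
                              stringsAsFactors = FALSE))
      igraph::write_graph(g, path, format = "graphml")
    })
  invisible(path)
}
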