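# Gene-set expansion along typed molecular networks: augment a seed set
# with its neighbors (miRNA->target, TF->target, PPI, drug->target),
# composably and with per-step provenance.

#' Expand a gene set along one molecular network
#'
#' Adds every node reachable from the seed within `hops` steps along the
#' permitted direction.  `downstream` follows edges source -> target
#' (the default: the typical question is the downstream effect of the
#' seed genes), `upstream` follows them in reverse, `both` ignores
#' orientation.  PPI networks are undirected and always expand both
#' ways.  For miRNA- and drug-target networks, seed IDs that occur in
#' the source namespace act as sources; the expanded set may then mix
#' namespaces — use [restrict_to_genes()] before running GSA on it.
#'
#' @param seed Character vector of IDs.
#' @param network A [molecular_network].
#' @param direction One of `"downstream"`, `"upstream"`, `"both"`.
#' @param hops Maximum number of steps (>= 1).
#' @return List with `expanded` (sorted character vector, a superset of
#'   `seed`) and `step` (an `expansion_step` recording the network,
#'   direction, hops, frontier and added IDs).
#' @examples
#' nw <- molecular_network("toy", "tf_target",
#'   data.frame(source = c("A", "B"), target = c("B", "C")))
#' expand_genes("A", nw, hops = 2)$expanded  # A B C
#' @export
expand_genes <- function(seed, network,
                         direction = c("downstream", "upstream", "both"),
                         hops = 1) {
  stopifnot(inherits(network, "molecular_network"), hops >= 1)
  direction <- match.arg(direction)
  seed <- sort(unique(as.character(seed)), method = "radix")
  e <- network$edges
  fwd <- split(e$target, e$source)
  bwd <- split(e$source, e$target)
  eff_dir <- if (!network$directed) "both" else direction
  neighbors <- function(ids) {
    out <- character(0)
    if (eff_dir %in% c("downstream", "both")) {
      out <- c(out, unlist(fwd[intersect(ids, names(fwd))],
                           use.names = FALSE))
    }
    if (eff_dir %in% c("upstream", "both")) {
      out <- c(out, unlist(bwd[intersect(ids, names(bwd))],
                           use.names = FALSE))
    }
    unique(out)
  }
  visited <- seed
  frontier <- seed
  for (h in seq_len(hops)) {
    new <- setdiff(neighbors(frontier), visited)
    if (length(new) == 0) break
    visited <- c(visited, new)
    frontier <- new
  }
  expanded <- sort(visited, method = "radix")
  step <- structure(list(network_name = network$name, kind = network$kind,
                         direction = direction, hops = hops,
                         frontier_before = seed,
                         added = setdiff(expanded, seed)),
                    class = "expansion_step")
  list(expanded = expanded, step = step)
}

#' Apply a chain of network expansions
#'
#' Sequentially expands the seed along several networks, e.g. miRNA
#' targets first grown through a TF-target network and then through PPI.
#' Step order matters on asymmetric networks.  The result combines
#' naturally with [combine_sets()] afterwards.
#'
#' @param seed Character vector of IDs.
#' @param store An [annotation_store] whose `networks` hold every named
#'   network.
#' @param steps List of steps, each a list/vector
#'   `(network, direction, hops)`, or a chain spec string such as
#'   `"tfnet:downstream:1,ppi:both:1"` (see [parse_chain_spec()]).
#' @return List with `expanded` (sorted character vector) and `steps`
#'   (list of `expansion_step` records, one per applied step).
#' @export
expand_chain <- function(seed, store, steps) {
  stopifnot(inherits(store, "annotation_store"))
  if (is.character(steps) && length(steps) == 1) {
    steps <- parse_chain_spec(steps)
  }
  current <- sort(unique(as.character(seed)), method = "radix")
  log <- list()
  for (st in steps) {
    nm <- st[["network"]]
    if (is.null(store$networks[[nm]])) {
      stop("unknown network '", nm, "'; available: ",
           paste(names(store$networks), collapse = ", "))
    }
    dir <- if (is.null(st[["direction"]])) "downstream" else st[["direction"]]
    hops <- if (is.null(st[["hops"]])) 1L else as.integer(st[["hops"]])
    out <- expand_genes(current, store$networks[[nm]], dir, hops)
    current <- out$expanded
    log[[length(log) + 1]] <- out$step
  }
  list(expanded = current, steps = log)
}

#' Parse an expansion chain specification string
#'
#' Comma-separated steps of the form `network[:direction[:hops]]`,
#' e.g. `"tfnet:downstream:1,ppi:both:1"`.
#'
#' @param spec Chain specification string.
#' @return List of steps suitable for [expand_chain()].
#' @export
parse_chain_spec <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1, nzchar(spec))
  lapply(strsplit(spec, ",", fixed = TRUE)[[1]], function(part) {
    f <- strsplit(trimws(part), ":", fixed = TRUE)[[1]]
    if (length(f) < 1 || !nzchar(f[1])) {
      stop("malformed chain step: '", part, "'")
    }
    list(network = f[1],
         direction = if (length(f) >= 2) f[2] else "downstream",
         hops = if (length(f) >= 3) as.integer(f[3]) else 1L)
  })
}

#' Restrict a mixed-namespace ID set to gene IDs
#'
#' Expansion through miRNA- or drug-target networks can introduce
#' non-gene IDs (the regulator/drug namespaces); this filters the set to
#' a gene universe before enrichment analysis.
#'
#' @param ids Character vector of IDs.
#' @param gene_universe Character vector of known gene IDs.
#' @return Sorted character vector `ids` intersected with the universe.
#' @export
restrict_to_genes <- function(ids, gene_universe) {
  sort(intersect(unique(as.character(ids)), gene_universe),
       method = "radix")
}
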