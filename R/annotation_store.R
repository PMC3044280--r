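# Annotation store: terms grouped by category, term hierarchies, and typed
# molecular networks.  Defines the background universe for enrichment.

.network_kinds <- c("ppi", "tf_target", "mirna_target", "drug_target")

#' Construct an annotation term
#'
#' @param term_id Unique term identifier.
#' @param name Human-readable name (defaults to `term_id`).
#' @param category Annotation category label, e.g. `"pathway"`, `"go"`,
#'   `"domain"`, `"disease"`, `"drug"`, or `"custom"`.
#' @param members Character vector of canonical gene IDs (deduplicated;
#'   must be non-empty).
#' @return An object of class `annotation_term`.
#' @export
annotation_term <- function(term_id, members, name = term_id,
                            category = "custom") {
  stopifnot(is.character(term_id), length(term_id) == 1, nzchar(term_id))
  members <- sort(unique(as.character(members)), method = "radix")
  members <- members[nzchar(members)]
  if (length(members) == 0) {
    stop("annotation term '", term_id, "' has no members")
  }
  structure(list(term_id = term_id, name = name, category = category,
                 members = members),
            class = "annotation_term")
}

# strip comment/blank lines, keeping original line numbers for diagnostics
.read_content_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Read gene sets from a GMT file
#'
#' One term per line: `term_id TAB description TAB gene TAB gene ...`
#' (Broad dialect).  `#` comments and blank lines are skipped.  Duplicate
#' member genes within a line are collapsed; lines whose member list is
#' empty are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @param category Category label attached to every term read.
#' @return List of [annotation_term] objects, named by `term_id`.
#' @export
read_gmt <- function(path, category = "custom") {
  cl <- .read_content_lines(path)
  terms <- list()
  for (i in seq_along(cl$lines)) {
    fields <- strsplit(cl$lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2) {
      stop("malformed GMT line ", cl$lineno[i], " in ", path,
           ": expected at least 2 tab-separated fields")
    }
    id <- fields[1]
    if (id %in% names(terms)) {
      stop("duplicate term_id '", id, "' at GMT line ", cl$lineno[i],
           " in ", path)
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      warning("GMT line ", cl$lineno[i], " (term '", id,
              "') has no member genes; dropped")
      next
    }
    terms[[id]] <- annotation_term(id, members, name = fields[2],
                                   category = category)
  }
  terms
}

#' Write gene sets to a GMT file
#'
#' Members are written in sorted order so output is byte-stable;
#' `read_gmt(write_gmt(x))` reproduces term IDs and member sets exactly.
#'
#' @param terms List of [annotation_term] objects (may be empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(terms, function(tm) {
    paste(c(tm$term_id,
            if (nzchar(tm$name)) tm$name else tm$term_id,
            sort(tm$members, method = "radix")),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# split whitespace-delimited two-column lines, tolerating an optional header
.read_pair_file <- function(path, header_names) {
  cl <- .read_content_lines(path)
  if (length(cl$lines) == 0) return(NULL)
  rows <- strsplit(cl$lines, "[\t ]+", perl = TRUE)
  first <- tolower(rows[[1]])
  if (length(first) >= 2 && all(first[1:2] == header_names)) {
    rows <- rows[-1]
    cl$lineno <- cl$lineno[-1]
  }
  if (length(rows) == 0) return(NULL)
  nf <- vapply(rows, length, integer(1))
  if (any(nf < 2)) {
    stop("malformed line ", cl$lineno[which(nf < 2)[1]], " in ", path,
         ": expected 2 whitespace-separated fields")
  }
  data.frame(a = vapply(rows, `[`, character(1), 1),
             b = vapply(rows, `[`, character(1), 2),
             stringsAsFactors = FALSE)
}

#' Read a term hierarchy (parent-child pairs)
#'
#' Tab- or space-separated `parent_id child_id` pairs, optionally headed by
#' a `parent_id`/`child_id` line.  The relation must be acyclic (GO-style
#' DAGs with multiple parents per child are fine); a cycle aborts the load
#' and names the terms involved.
#'
#' @param path Path to the hierarchy file.
#' @return Data frame with columns `parent` and `child`, one row per
#'   distinct edge.
#' @export
read_hierarchy <- function(path) {
  df <- .read_pair_file(path, c("parent_id", "child_id"))
  if (is.null(df)) {
    return(data.frame(parent = character(0), child = character(0),
                      stringsAsFactors = FALSE))
  }
  names(df) <- c("parent", "child")
  df <- unique(df)
  rownames(df) <- NULL
  cyc <- .find_cycle_nodes(df$parent, df$child)
  if (length(cyc) > 0) {
    stop("hierarchy contains a cycle involving: ",
         paste(cyc, collapse = " -> "))
  }
  df
}

# Kahn-style elimination: nodes left after repeatedly removing
# zero-indegree nodes lie on (or downstream of) a cycle.
.find_cycle_nodes <- function(parent, child) {
  nodes <- unique(c(parent, child))
  edges <- data.frame(parent = parent, child = child,
                      stringsAsFactors = FALSE)
  repeat {
    indeg0 <- setdiff(nodes, edges$child)
    if (length(indeg0) == 0) break
    nodes <- setdiff(nodes, indeg0)
    edges <- edges[!(edges$parent %in% indeg0), , drop = FALSE]
    if (nrow(edges) == 0 && length(nodes) == 0) break
  }
  sort(nodes, method = "radix")
}

#' Construct a typed molecular network
#'
#' @param name Network name (used to address it in an [annotation_store]).
#' @param kind One of `"ppi"`, `"tf_target"`, `"mirna_target"`,
#'   `"drug_target"`.  PPI networks are undirected: edges are stored in
#'   canonical (min, max) order and self-loops are dropped.  The other
#'   kinds are directed source -> target; for miRNA and drug networks the
#'   sources live in their own namespace and the targets are gene IDs.
#' @param edges Data frame with columns `source` and `target`.
#' @return An object of class `molecular_network`.
#' @export
molecular_network <- function(name, kind, edges) {
  kind <- match.arg(kind, .network_kinds)
  stopifnot(is.data.frame(edges), all(c("source", "target") %in% names(edges)))
  edges <- data.frame(source = as.character(edges$source),
                      target = as.character(edges$target),
                      stringsAsFactors = FALSE)
  directed <- kind != "ppi"
  if (!directed) {
    loops <- edges$source == edges$target
    if (any(loops)) {
      warning(sum(loops), " self-loop(s) dropped from PPI network '",
              name, "'")
      edges <- edges[!loops, , drop = FALSE]
    }
    src <- pmin(edges$source, edges$target)
    tgt <- pmax(edges$source, edges$target)
    edges <- data.frame(source = src, target = tgt, stringsAsFactors = FALSE)
  }
  edges <- unique(edges)
  edges <- edges[order(edges$source, edges$target, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(name = name, kind = kind, directed = directed,
                 edges = edges),
            class = "molecular_network")
}

#' Read a typed molecular network from an edge-list file
#'
#' Whitespace-separated `source target` lines with optional
#' `source`/`target` header; `#` comments and blanks skipped.  Undirected
#' (PPI) edges are canonicalized and deduplicated, self-loops dropped with
#' a warning; directed edges are deduplicated as written.
#'
#' @inheritParams molecular_network
#' @param path Path to the edge-list file.
#' @return A [molecular_network].
#' @export
read_network <- function(path, kind, name = basename(path)) {
  df <- .read_pair_file(path, c("source", "target"))
  if (is.null(df)) {
    df <- data.frame(a = character(0), b = character(0),
                     stringsAsFactors = FALSE)
  }
  molecular_network(name, kind, data.frame(source = df$a, target = df$b,
                                           stringsAsFactors = FALSE))
}

#' Assemble an annotation store
#'
#' Bundles annotation terms, an optional term hierarchy and any number of
#' molecular networks into the single object the analysis functions
#' consume.  Validates term-ID uniqueness, that hierarchy edges reference
#' known terms, and acyclicity.
#'
#' @param terms List of [annotation_term] objects (possibly from several
#'   [read_gmt()] calls concatenated with `c()`).
#' @param hierarchy Data frame with `parent`/`child` columns (see
#'   [read_hierarchy()]), or `NULL`.
#' @param networks List of [molecular_network] objects; addressed by their
#'   `name` field.
#' @return An object of class `annotation_store`.
#' @export
annotation_store <- function(terms, hierarchy = NULL, networks = list()) {
  stopifnot(is.list(terms))
  ids <- vapply(terms, function(tm) tm$term_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate term_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(terms) <- ids
  if (!is.null(hierarchy) && nrow(hierarchy) > 0) {
    unknown <- setdiff(unique(c(hierarchy$parent, hierarchy$child)), ids)
    if (length(unknown) > 0) {
      stop("hierarchy references unknown term_id(s): ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    cyc <- .find_cycle_nodes(hierarchy$parent, hierarchy$child)
    if (length(cyc) > 0) {
      stop("hierarchy contains a cycle involving: ",
           paste(cyc, collapse = " -> "))
    }
  } else {
    hierarchy <- data.frame(parent = character(0), child = character(0),
                            stringsAsFactors = FALSE)
  }
  if (length(networks) > 0) {
    stopifnot(all(vapply(networks, inherits, logical(1),
                         "molecular_network")))
    names(networks) <- vapply(networks, function(nw) nw$name, character(1))
  }
  structure(list(terms = terms, hierarchy = hierarchy, networks = networks),
            class = "annotation_store")
}

#' @export
print.annotation_store <- function(x, ...) {
  cats <- table(vapply(x$terms, function(tm) tm$category, character(1)))
  cat("annotation_store:", length(x$terms), "terms in", length(cats),
      "categories\n")
  for (nm in names(cats)) cat("  ", nm, ": ", cats[[nm]], " terms\n", sep = "")
  cat("  hierarchy edges: ", nrow(x$hierarchy), "\n")
  cat("  networks: ", paste(names(x$networks), collapse = ", "), "\n")
  invisible(x)
}

.store_categories <- function(store) {
  unique(vapply(store$terms, function(tm) tm$category, character(1)))
}

.select_terms <- function(store, categories) {
  known <- .store_categories(store)
  if (identical(categories, "all")) {
    categories <- known
  }
  if (length(categories) == 0) stop("no annotation categories selected")
  unknown <- setdiff(categories, known)
  if (length(unknown) > 0) {
    stop("unknown annotation categor",
         if (length(unknown) > 1) "ies: " else "y: ",
         paste(unknown, collapse = ", "))
  }
  keep <- vapply(store$terms, function(tm) tm$category %in% categories,
                 logical(1))
  store$terms[keep]
}

#' Background gene universe of an annotation store
#'
#' The default analysis background is the union of all member genes over
#' the terms in the selected categories.  Adding categories can only grow
#' the universe (monotone).
#'
#' @param store An [annotation_store].
#' @param categories Character vector of category labels, or `"all"`.
#' @return Sorted character vector of gene IDs.
#' @export
gene_universe <- function(store, categories = "all") {
  terms <- .select_terms(store, categories)
  sort(unique(unlist(lapply(terms, function(tm) tm$members),
                     use.names = FALSE)), method = "radix")
}

#' Filter annotation terms by set size
#'
#' Keeps terms whose member count lies in `[min_size, max_size]`.
#' Hierarchy edges touching a removed term are dropped (no grandparent
#' reconnection).  Idempotent at fixed bounds.  Singleton terms make both
#' kappa and the hypergeometric test degenerate, hence the default
#' `min_size = 2`.
#'
#' @param store An [annotation_store].
#' @param min_size,max_size Inclusive bounds on term size.
#' @return A filtered [annotation_store].
#' @export
filter_terms <- function(store, min_size = 2, max_size = Inf) {
  stopifnot(min_size >= 1, min_size <= max_size)
  sizes <- vapply(store$terms, function(tm) length(tm$members), integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  terms <- store$terms[keep]
  ids <- names(terms)
  h <- store$hierarchy
  h <- h[h$parent %in% ids & h$child %in% ids, , drop = FALSE]
  rownames(h) <- NULL
  annotation_store(terms, hierarchy = h, networks = store$networks)
}

#' Search annotation terms by keyword or ID
#'
#' Case-insensitive substring match against `term_id` and `name`.  An
#' exact `term_id` hit is returned first; remaining matches are sorted by
#' `term_id`.
#'
#' @param store An [annotation_store].
#' @param query Non-empty search string.
#' @return List of matching [annotation_term] objects (possibly empty).
#' @export
search_terms <- function(store, query) {
  stopifnot(is.character(query), length(query) == 1, nzchar(query))
  q <- tolower(query)
  hit <- vapply(store$terms, function(tm) {
    grepl(q, tolower(tm$term_id), fixed = TRUE) ||
      grepl(q, tolower(tm$name), fixed = TRUE)
  }, logical(1))
  res <- store$terms[hit]
  ids <- names(res)
  exact <- tolower(ids) == q
  res[order(!exact, ids, method = "radix")]
}
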