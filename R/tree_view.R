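# Hierarchical (tree) grouping of enrichment results for DAG-structured
# annotation categories (GO-style: a child may have several parents).

#' Group enrichment results along a term hierarchy
#'
#' Nests each passing term under its parent chain(s).  Ancestors that are
#' not themselves enriched appear as unscored scaffold nodes so the chain
#' to the root stays visible.  A child with several parents appears under
#' each of them (DAG semantics).  Terms absent from the hierarchy are
#' listed flat at the top level.
#'
#' @param run A `gsa_run` from [run_gsa()].
#' @param hierarchy Data frame with `parent`/`child` columns (see
#'   [read_hierarchy()]); may be empty.
#' @return An object of class `gsa_tree`: a list of root nodes, each node
#'   a list with `term_id`, `enriched` (logical), `q_value` (NA for
#'   scaffold nodes) and `children` (list of nodes).  Serializable with
#'   [tree_text()] or `jsonlite::toJSON()`.
#' @export
tree_group <- function(run, hierarchy) {
  stopifnot(inherits(run, "gsa_run"))
  passing <- run$results$term_id
  qmap <- stats::setNames(run$results$q_value, passing)
  if (is.null(hierarchy) || nrow(hierarchy) == 0) {
    nodes <- lapply(sort(passing, method = "radix"), function(id) {
      list(term_id = id, enriched = TRUE, q_value = unname(qmap[[id]]),
           children = list())
    })
    return(structure(nodes, class = "gsa_tree"))
  }

  parents_of <- split(hierarchy$parent, hierarchy$child)
  children_of <- split(hierarchy$child, hierarchy$parent)
  in_hier <- unique(c(hierarchy$parent, hierarchy$child))

  # include every passing term plus all its ancestors (scaffold)
  include <- character(0)
  frontier <- intersect(passing, in_hier)
  while (length(frontier) > 0) {
    include <- union(include, frontier)
    up <- unique(unlist(parents_of[intersect(frontier, names(parents_of))],
                        use.names = FALSE))
    frontier <- setdiff(up, include)
  }

  build <- function(id) {
    kids <- intersect(as.character(children_of[[id]]), include)
    kids <- sort(kids, method = "radix")
    list(term_id = id,
         enriched = id %in% passing,
         q_value = if (id %in% passing) unname(qmap[[id]]) else NA_real_,
         children = lapply(kids, build))
  }
  roots <- sort(include[!vapply(include, function(id) {
    any(parents_of[[id]] %in% include)
  }, logical(1))], method = "radix")
  flat <- sort(setdiff(passing, in_hier), method = "radix")
  nodes <- c(lapply(roots, build),
             lapply(flat, function(id) {
               list(term_id = id, enriched = TRUE,
                    q_value = unname(qmap[[id]]), children = list())
             }))
  structure(nodes, class = "gsa_tree")
}

#' Render a result tree as indented text
#'
#' Enriched terms print with their q-value; scaffold ancestors print in
#' parentheses.
#'
#' @param tree A `gsa_tree` from [tree_group()].
#' @param indent Indentation unit.
#' @return Character vector of lines.
#' @export
tree_text <- function(tree, indent = "  ") {
  render <- function(node, depth) {
    pad <- strrep(indent, depth)
    line <- if (node$enriched) {
      sprintf("%s%s [q=%.6g]", pad, node$term_id, node$q_value)
    } else {
      sprintf("%s(%s)", pad, node$term_id)
    }
    c(line, unlist(lapply(node$children, render, depth + 1),
                   use.names = FALSE))
  }
  unlist(lapply(tree, render, 0), use.names = FALSE)
}

#' @export
print.gsa_tree <- function(x, ...) {
  cat(tree_text(x), sep = "\n")
  invisible(x)
}
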