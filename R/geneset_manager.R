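# Named user gene sets with provenance, and set algebra over them.

#' Construct a gene set
#'
#' Low-level constructor from already-canonical gene IDs.  Most users will
#' instead call [create_gene_set()], which converts raw identifier tokens
#' through a mapping table first.
#'
#' @param name Set name.
#' @param members Character vector of canonical gene IDs.
#' @param provenance Character vector describing how the set was made;
#'   grows append-only as operations are applied.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, members, provenance = character(0)) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  members <- sort(unique(as.character(members)), method = "radix")
  members <- members[nzchar(members)]
  structure(list(name = name, members = members, provenance = provenance),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "': ", length(x$members), " genes\n", sep = "")
  if (length(x$provenance) > 0) {
    cat("  provenance:\n")
    for (p in x$provenance) cat("    -", p, "\n")
  }
  invisible(x)
}

#' Open a gene-set session
#'
#' A lightweight registry enforcing name uniqueness across
#' [create_gene_set()] / [combine_sets()] calls that share it.  Purely
#' optional: without a session, name uniqueness is the caller's concern.
#'
#' @return An environment usable as the `session` argument.
#' @export
new_geneset_session <- function() {
  new.env(parent = emptyenv())
}

.register_set <- function(session, set) {
  if (!is.null(session)) {
    if (exists(set$name, envir = session, inherits = FALSE)) {
      stop("a gene set named '", set$name, "' already exists")
    }
    assign(set$name, set, envir = session)
  }
  set
}

#' Create a named gene set from identifier tokens
#'
#' Converts the tokens to canonical gene IDs via [convert_ids()] and
#' records the conversion outcome in the set's provenance.  Ambiguous
#' tokens contribute all their canonical IDs.
#'
#' @param name Set name (must be unused in `session`, if one is given).
#' @param tokens Character vector of input identifiers.
#' @param table An `id_mapping_table` from [read_id_mapping()].
#' @param session Optional registry from [new_geneset_session()].
#' @return List with elements `set` (a [gene_set]) and `report` (the
#'   `conversion_report`).
#' @export
create_gene_set <- function(name, tokens, table, session = NULL) {
  report <- convert_ids(tokens, table)
  if (length(report$canonical_set) == 0) {
    stop("none of the input identifiers could be mapped; ",
         "check that the ID types match the mapping table")
  }
  prov <- sprintf(
    "created from %d tokens (%d mapped, %d unmapped, %d ambiguous)",
    length(report$mapped) + length(report$unmapped),
    length(report$mapped), length(report$unmapped), length(report$ambiguous))
  set <- gene_set(name, report$canonical_set, provenance = prov)
  .register_set(session, set)
  list(set = set, report = report)
}

#' Combine two gene sets
#'
#' @param a,b [gene_set] objects.
#' @param op One of `"union"`, `"intersection"`, `"subtraction"`
#'   (`a` minus `b`).
#' @param new_name Name for the result set.
#' @param session Optional registry from [new_geneset_session()].
#' @return A [gene_set] whose provenance records the operation.
#' @export
combine_sets <- function(a, b, op = c("union", "intersection", "subtraction"),
                         new_name, session = NULL) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  op <- match.arg(op)
  members <- switch(op,
                    union = union(a$members, b$members),
                    intersection = intersect(a$members, b$members),
                    subtraction = setdiff(a$members, b$members))
  set <- gene_set(new_name, members,
                  provenance = c(a$provenance, b$provenance,
                                 sprintf("%s(%s, %s)", op, a$name, b$name)))
  .register_set(session, set)
  set
}

#' Export a gene set to file
#'
#' `txt` writes one ID per line, sorted; `gmt` writes a single GMT line.
#' Re-import through [read_gene_list()] or [read_gmt()] reproduces the
#' member set.
#'
#' @param set A [gene_set].
#' @param path Output path.
#' @param format `"txt"` or `"gmt"`.
#' @return `path`, invisibly.
#' @export
export_gene_set <- function(set, path, format = c("txt", "gmt")) {
  stopifnot(inherits(set, "gene_set"))
  format <- match.arg(format)
  if (length(set$members) == 0) {
    warning("gene set '", set$name, "' is empty; exporting an empty file")
  }
  if (format == "txt") {
    writeLines(set$members, path)
  } else {
    if (length(set$members) == 0) {
      writeLines(character(0), path)
    } else {
      write_gmt(list(annotation_term(set$name, set$members,
                                     name = set$name, category = "custom")),
                path)
    }
  }
  invisible(path)
}
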