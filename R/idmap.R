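# Gene identifier normalization: map heterogeneous input IDs onto one
# canonical gene ID space (Entrez-like in real use; opaque strings here).

#' Read a gene ID mapping table
#'
#' Loads a tab-separated mapping table with columns `id_type`, `source_id`
#' and `canonical_id`.  Lines starting with `#` and blank lines are ignored.
#' A `(id_type, source_id)` pair may map to several canonical IDs
#' (one-to-many mappings are legal and flagged as ambiguous at conversion
#' time).  Duplicate rows are collapsed.
#'
#' @param path Path to a TSV file with header columns `id_type`,
#'   `source_id`, `canonical_id`.
#' @return An object of class `id_mapping_table`: a data frame with the
#'   three columns above, one row per distinct mapping.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id_type\tsource_id\tcanonical_id",
#'              "refseq\tNM_130786\tG1457",
#'              "symbol\tA1BG\tG1"), tf)
#' m <- read_id_mapping(tf)
#' nrow(m)
#' @export
read_id_mapping <- function(path) {
  if (!file.exists(path)) {
    stop("mapping file not found: ", path)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character", blank.lines.skip = TRUE)
  required <- c("id_type", "source_id", "canonical_id")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("mapping table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[, required]
  if (nrow(df) == 0) {
    stop("mapping table is empty: ", path)
  }
  bad <- !nzchar(df$canonical_id)
  if (any(bad)) {
    stop("mapping table has ", sum(bad), " row(s) with empty canonical_id")
  }
  df <- unique(df)
  rownames(df) <- NULL
  class(df) <- c("id_mapping_table", "data.frame")
  df
}

#' Supported ID type labels
#' @keywords internal
.id_types <- c("entrez", "ensembl_gene", "ensembl_transcript",
               "genbank_accession", "refseq", "unigene", "symbol",
               "uniprot_acc", "uniprot_id", "affy_probe", "illumina_probe")

#' Guess the ID type of a gene identifier token
#'
#' Pattern-based classification of a single identifier into one of the
#' supported ID namespaces.  Rules are ordered most-specific-first:
#' all-digit tokens are treated as Entrez-style numeric gene IDs, `ENSG`/
#' `ENST` prefixes as Ensembl gene/transcript, `NM_`/`NR_`/`XM_`/`XR_` as
#' RefSeq, `Hs.` as UniGene, a trailing `_at` as an Affymetrix probe,
#' UniProt accession and `_HUMAN` entry-name shapes as UniProt, a short
#' letters-then-digits shape as a GenBank accession, and anything else
#' falls back to `symbol`.  Detection only narrows the mapping lookup;
#' conversion falls back to an all-type search, so a wrong guess cannot
#' lose a mapping.
#'
#' @param token Character vector of identifier tokens (each non-empty).
#' @return Character vector of type labels, one of `entrez`,
#'   `ensembl_gene`, `ensembl_transcript`, `genbank_accession`, `refseq`,
#'   `unigene`, `symbol`, `uniprot_acc`, `uniprot_id`, `affy_probe`,
#'   `illumina_probe` or `unknown`.
#' @examples
#' detect_id_type(c("ENSG00000101266", "NM_130786", "212073_at", "1457"))
#' @export
detect_id_type <- function(token) {
  if (length(token) == 0) stop("token must be a non-empty string")
  if (!is.character(token) || any(is.na(token)) || any(!nzchar(token))) {
    stop("token must be a non-empty string")
  }
  one <- function(tk) {
    if (grepl("^[0-9]+$", tk)) return("entrez")
    if (grepl("^ENSG[0-9]+$", tk)) return("ensembl_gene")
    if (grepl("^ENST[0-9]+$", tk)) return("ensembl_transcript")
    if (grepl("^(NM_|NR_|XM_|XR_)[0-9]+", tk)) return("refseq")
    if (grepl("^Hs\\.[0-9]+$", tk)) return("unigene")
    if (grepl("_at$", tk)) return("affy_probe")
    if (grepl("^[OPQ][0-9][A-Z0-9]{3}[0-9]$", tk)) return("uniprot_acc")
    if (grepl("_HUMAN$", tk)) return("uniprot_id")
    if (grepl("^[A-Z]{1,2}[0-9]{5,8}$", tk)) return("genbank_accession")
    if (grepl("^[A-Za-z][A-Za-z0-9._-]*$", tk)) return("symbol")
    "unknown"
  }
  vapply(token, one, character(1), USE.NAMES = FALSE)
}

#' Convert identifier tokens to canonical gene IDs
#'
#' Looks every distinct input token up in the mapping table and reports the
#' outcome.  Tokens are first matched exactly against `source_id`; tokens
#' that miss are retried case-insensitively against rows of type `symbol`
#' (gene symbols are conventionally case-insensitive, accessions are not).
#' A token mapping to more than one canonical ID is kept with *all* its
#' canonical IDs and flagged as ambiguous, so nothing is silently lost.
#' Downstream analysis consumes `canonical_set`, the union of all mapped
#' IDs; everything after conversion happens at the gene level.
#'
#' @param tokens Character vector of input identifiers (duplicates are
#'   collapsed; order does not matter).
#' @param table An `id_mapping_table` from [read_id_mapping()].
#' @return An object of class `conversion_report`: a list with elements
#'   `mapped` (named list token -> character vector of canonical IDs),
#'   `unmapped` (character vector), `ambiguous` (character vector, subset
#'   of `names(mapped)`) and `canonical_set` (sorted character vector).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id_type\tsource_id\tcanonical_id",
#'              "refseq\tNM_130786\tG1457",
#'              "symbol\tA1BG\tG1",
#'              "symbol\tA1BG\tG9999"), tf)
#' rep <- convert_ids(c("NM_130786", "A1BG", "XXXX"), read_id_mapping(tf))
#' rep$ambiguous
#' rep$canonical_set
#' @export
convert_ids <- function(tokens, table) {
  stopifnot(inherits(table, "id_mapping_table"))
  if (length(tokens) == 0) stop("tokens must be a non-empty list of strings")
  tokens <- unique(as.character(tokens))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) stop("tokens must be a non-empty list of strings")

  mapped <- list()
  unmapped <- character(0)
  sym_rows <- table$id_type == "symbol"
  for (tk in tokens) {
    hits <- table$canonical_id[table$source_id == tk]
    if (length(hits) == 0) {
      hits <- table$canonical_id[sym_rows &
                                   toupper(table$source_id) == toupper(tk)]
    }
    hits <- sort(unique(hits), method = "radix")
    if (length(hits) == 0) {
      unmapped <- c(unmapped, tk)
    } else {
      mapped[[tk]] <- hits
    }
  }
  ambiguous <- names(mapped)[vapply(mapped, length, integer(1)) > 1]
  if (is.null(ambiguous)) ambiguous <- character(0)
  canonical_set <- unlist(mapped, use.names = FALSE)
  if (is.null(canonical_set)) canonical_set <- character(0)
  canonical_set <- sort(unique(canonical_set), method = "radix")
  structure(list(mapped = mapped,
                 unmapped = unmapped,
                 ambiguous = ambiguous,
                 canonical_set = canonical_set),
            class = "conversion_report")
}

#' @export
print.conversion_report <- function(x, ...) {
  cat("ID conversion report\n")
  cat("  mapped tokens:    ", length(x$mapped), "\n")
  cat("  unmapped tokens:  ", length(x$unmapped), "\n")
  cat("  ambiguous tokens: ", length(x$ambiguous), "\n")
  cat("  canonical genes:  ", length(x$canonical_set), "\n")
  invisible(x)
}

#' Read a gene list from file or free text
#'
#' Accepts one token per line, or a single line of comma/whitespace
#' separated tokens.  `#` comment lines and blanks are skipped.
#'
#' @param path Path to a plain-text gene list.
#' @return Character vector of tokens in file order (duplicates retained).
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  parse_gene_tokens(paste(lines, collapse = "\n"))
}

#' Split free text into gene identifier tokens
#'
#' @param text A character scalar (possibly multi-line) of identifiers
#'   separated by newlines, commas and/or whitespace.
#' @return Character vector of non-empty tokens.
#' @export
parse_gene_tokens <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("^\\s*#", lines)]
  toks <- unlist(strsplit(lines, "[,\\s]+", perl = TRUE), use.names = FALSE)
  toks[nzchar(toks)]
}
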