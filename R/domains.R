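#' Parse domain hits from a plain list or HMMER tblout table
#'
#' Accepts either a plain text file with one domain identifier per line, or
#' an HMMER `--tblout` table (comment lines start with `#`; the identifier
#' is taken from the target accession column, falling back to the target
#' name when the accession is `-`). Returns unique identifiers in
#' first-appearance order.
#'
#' @param path Path to the hits file.
#' @return Character vector of unique domain identifiers (possibly empty).
#' @export
parse_domain_hits <- function(path) {
  if (!file.exists(path)) stop("domain hits file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_comment <- startsWith(trimws(lines), "#")
  data <- trimws(lines[!is_comment])
  if (length(data) == 0L) return(character())
  toks <- strsplit(data, "[[:space:]]+")
  nfields <- vapply(toks, length, integer(1))
  tblout <- any(is_comment) || any(nfields >= 10L)
  ids <- if (tblout) {
    vapply(toks, function(tk) {
      acc <- if (length(tk) >= 2L) tk[2] else "-"
      if (acc == "-") tk[1] else acc
    }, "")
  } else {
    vapply(toks, `[`, "", 1L)
  }
  unique(ids)
}

#' Encode domain hits as a binary presence vector
#'
#' Position j of the result is 1 iff `vocabulary[j]` occurs in `hits`.
#' The encoding is invariant to the order and multiplicity of hits. Hits
#' absent from the vocabulary are not an error: they are counted and
#' reported through a warning so novel domains seen at prediction time do
#' not abort a run.
#'
#' @param hits Character vector of domain identifiers (possibly empty).
#' @param vocabulary Ordered character vector of D distinct identifiers;
#'   its ordering is fixed and persisted with any trained model.
#' @return Numeric 0/1 vector of length `length(vocabulary)`, names set to
#'   the vocabulary.
#' @export
domain_encode <- function(hits, vocabulary) {
  stopifnot(is.character(vocabulary), length(vocabulary) >= 1L)
  if (anyDuplicated(vocabulary))
    stop("duplicate identifiers in domain vocabulary: ",
         paste(unique(vocabulary[duplicated(vocabulary)]), collapse = ", "))
  hits <- unique(as.character(hits))
  unknown <- setdiff(hits, vocabulary)
  if (length(unknown) > 0L)
    warning(length(unknown), " domain hit(s) outside the vocabulary ignored: ",
            paste(utils::head(unknown, 5L), collapse = ", "),
            call. = FALSE)
  stats::setNames(as.numeric(vocabulary %in% hits), vocabulary)
}

#' @rdname domain_vocabulary_io
#' @param vocabulary Ordered character vector of domain identifiers.
#' @param path File path.
#' @export
write_domain_vocabulary <- function(vocabulary, path) {
  writeLines(vocabulary, path)
  invisible(path)
}

#' Read or write a domain vocabulary
#'
#' The vocabulary is persisted as plain text, one identifier per line, in
#' its frozen order.
#'
#' @name domain_vocabulary_io
#' @return `read_domain_vocabulary` returns a character vector.
#' @export
read_domain_vocabulary <- function(path) {
  v <- readLines(path, warn = FALSE)
  v[nzchar(v)]
}

# Vocabulary construction rule used at training time: lexicographically
# sorted union of all hits observed in the training set.
build_domain_vocabulary <- function(hits_list) {
  sort(unique(unlist(hits_list, use.names = FALSE)))
}
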