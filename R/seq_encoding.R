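#' Read protein sequences from a FASTA file
#'
#' Reads all entries of a FASTA file into validated [protein_record]
#' objects. The record id is the header token up to the first whitespace.
#' Sequences are upper-cased; characters outside the 20 standard amino-acid
#' letters raise an error naming the record and the character (see
#' [protein_record] for the `map_nonstandard` escape hatch).
#'
#' @param path Path to a FASTA file.
#' @param map_nonstandard Passed to [protein_record].
#' @return List of `protein_record`, in file order.
#' @export
read_fasta <- function(path, map_nonstandard = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, "", 1L)
  seqs <- as.character(set)
  mapply(protein_record, ids, seqs,
         MoreArgs = list(map_nonstandard = map_nonstandard),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' One-hot encode a protein sequence
#'
#' Returns the L x 20 binary matrix in which row i has a single 1 at the
#' column of residue i under the fixed ordering [AA_ALPHABET]: 'A' maps to
#' the unit vector at column 1, 'C' at column 2, and so on.
#'
#' @param record A [protein_record].
#' @return L x 20 numeric matrix with one 1 per row; columns named by
#'   residue.
#' @export
one_hot_encode <- function(record) {
  stopifnot(inherits(record, "protein_record"))
  chars <- seq_chars(record)
  idx <- match(chars, AA_ALPHABET)
  m <- matrix(0, nrow = length(chars), ncol = 20L,
              dimnames = list(NULL, AA_ALPHABET))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Degenerate sequence profile for use when no PSSM is available
#'
#' Reinterprets the one-hot encoding as a position-specific profile whose
#' frequency mass sits entirely on the observed residue. This lets the full
#' model run when no iterative-search profile has been computed; the matrix
#' is tagged `source = "fallback"` so downstream consumers can audit which
#' inputs carried real evolutionary information.
#'
#' @param record A [protein_record].
#' @return L x 20 matrix, attribute `source = "fallback"`.
#' @export
fallback_pssm <- function(record) {
  m <- one_hot_encode(record)
  attr(m, "source") <- "fallback"
  m
}

#' Bundle the three raw encodings of one protein
#'
#' @param one_hot L x 20 one-hot matrix.
#' @param pssm L x 20 profile matrix (entries in \[0,1\]); must have the same
#'   number of rows as `one_hot`.
#' @param domains Binary domain-presence vector (see [domain_encode]).
#' @param id Optional sequence identifier carried for reporting.
#' @return Object of class `encoded_protein`.
#' @export
encoded_protein <- function(one_hot, pssm, domains, id = NA_character_) {
  stopifnot(is.matrix(one_hot), ncol(one_hot) == 20L,
            is.matrix(pssm), ncol(pssm) == 20L,
            is.numeric(domains))
  if (nrow(one_hot) != nrow(pssm))
    stop("one-hot and PSSM matrices must have identical row counts (",
         nrow(one_hot), " vs ", nrow(pssm), ")")
  structure(list(one_hot = one_hot, pssm = pssm,
                 domains = as.numeric(domains), id = id),
            class = "encoded_protein")
}

#' Encode one protein record end to end
#'
#' Convenience wrapper producing an [encoded_protein] from a record, an
#' optional parsed PSSM (fallback profile used when `NULL`), and a set of
#' domain hits against a fixed vocabulary.
#'
#' @param record A [protein_record].
#' @param vocabulary Ordered domain vocabulary (character).
#' @param pssm Optional L x 20 profile from [parse_pssm].
#' @param hits Character vector of domain identifiers hit in this sequence.
#' @return An [encoded_protein].
#' @export
encode_record <- function(record, vocabulary, pssm = NULL, hits = character()) {
  if (is.null(pssm)) pssm <- fallback_pssm(record)
  encoded_protein(one_hot_encode(record), pssm,
                  domain_encode(hits, vocabulary), id = record$id)
}
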