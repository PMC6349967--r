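#' The canonical amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes in fixed alphabetical order.
#' This ordering defines the column layout of every L x 20 encoding produced
#' by the package ('A' is column 1, 'C' is column 2, ..., 'Y' is column 20)
#' and is persisted with trained models.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Canonical substitutes for ambiguity/rare codes; 'X' has no unambiguous
# substitute and is always rejected.
NONSTANDARD_MAP <- c(B = "D", Z = "E", U = "C", O = "K", J = "L")

#' Construct a validated protein record
#'
#' A protein record pairs a sequence identifier with an amino-acid sequence
#' over the 20 standard letters. Sequences are upper-cased on construction.
#' Non-standard letters are rejected unless `map_nonstandard = TRUE`, in
#' which case B, Z, U, O, J are mapped to their canonical substitutes
#' (D, E, C, K, L); 'X' is always an error because it carries no residue
#' identity.
#'
#' @param id Single string identifier.
#' @param sequence Single string of amino-acid letters, length >= 1.
#' @param map_nonstandard Map B/Z/U/O/J to canonical residues instead of
#'   rejecting them.
#' @return An object of class `protein_record` with fields `id` and
#'   `sequence`.
#' @examples
#' protein_record("P1", "acdef")$sequence  # "ACDEF"
#' @export
protein_record <- function(id, sequence, map_nonstandard = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  seq <- toupper(sequence)
  if (nchar(seq) < 1L)
    stop("record '", id, "': sequence must have length >= 1")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% AA_ALPHABET)
  if (any(bad)) {
    if (map_nonstandard) {
      mappable <- bad & chars %in% names(NONSTANDARD_MAP)
      chars[mappable] <- NONSTANDARD_MAP[chars[mappable]]
      bad <- !(chars %in% AA_ALPHABET)
    }
    if (any(bad)) {
      offender <- chars[which(bad)[1]]
      stop("record '", id, "': invalid amino-acid character '", offender,
           "' at position ", which(bad)[1])
    }
    seq <- paste(chars, collapse = "")
  }
  structure(list(id = id, sequence = seq), class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, " (L=", nchar(x$sequence), ")\n", sep = "")
  invisible(x)
}

seq_chars <- function(record) strsplit(record$sequence, "", fixed = TRUE)[[1]]
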