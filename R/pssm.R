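# Column order used by PSI-BLAST ASCII PSSM files (differs from the
# alphabetical order used internally; files are re-ordered on read).
PSSM_FILE_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                     "L", "K", "M", "F", "P", "S", "T", "W", "V", "Y")

#' Parse a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Reads the ASCII PSSM dialect produced by `psiblast -out_ascii_pssm`
#' (header lines, then one row per residue carrying the position, the
#' residue letter, 20 integer log-odds columns and 20 percentage columns).
#' By default the 20 percentage columns are returned divided by 100, giving
#' a per-position residue frequency profile in \[0,1\]. With
#' `columns = "logodds"` the log-odds columns are returned instead, squashed
#' to \[0,1\] by the logistic function `1/(1+exp(-x))`.
#'
#' Columns are re-ordered from the file's own residue ordering (taken from
#' the header letter line) to the package's alphabetical ordering
#' [AA_ALPHABET]. The row residue letters must match `record$sequence`
#' position by position and the row count must equal the sequence length.
#'
#' @param path Path to the ASCII PSSM file.
#' @param record The [protein_record] this profile belongs to.
#' @param columns `"percent"` (default) or `"logodds"`.
#' @return L x 20 numeric matrix with entries in \[0,1\] and attribute
#'   `source = "parsed"`.
#' @export
parse_pssm <- function(path, record, columns = c("percent", "logodds")) {
  columns <- match.arg(columns)
  stopifnot(inherits(record, "protein_record"))
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  toks <- strsplit(trimws(lines), "[[:space:]]+")
  # header letter line: 20 or 40 single-letter tokens
  is_letters <- vapply(toks, function(tk)
    length(tk) %in% c(20L, 40L) && all(grepl("^[A-Z]$", tk)), logical(1))
  file_order <- PSSM_FILE_ORDER
  if (any(is_letters)) {
    hdr <- toks[[which(is_letters)[1]]]
    file_order <- hdr[seq_len(20L)]
    if (!setequal(file_order, AA_ALPHABET))
      stop("PSSM header letter line does not cover the 20 standard residues")
  }

  is_data <- vapply(toks, function(tk)
    length(tk) >= 2L && grepl("^[0-9]+$", tk[1]) && grepl("^[A-Za-z]$", tk[2]),
    logical(1))
  rows <- which(is_data)
  L <- nchar(record$sequence)
  if (length(rows) != L)
    stop("PSSM for record '", record$id, "' has ", length(rows),
         " data rows but the sequence has length ", L)

  chars <- seq_chars(record)
  out <- matrix(NA_real_, nrow = L, ncol = 20L,
                dimnames = list(NULL, AA_ALPHABET))
  for (i in seq_len(L)) {
    tk <- toks[[rows[i]]]
    letter <- toupper(tk[2])
    if (letter != chars[i])
      stop("PSSM residue mismatch for record '", record$id, "' at position ",
           i, ": file has '", letter, "', sequence has '", chars[i], "'")
    nums <- suppressWarnings(as.numeric(tk[-(1:2)]))
    if (length(nums) < 40L || anyNA(nums[seq_len(40L)]))
      stop("malformed PSSM row at line ", rows[i], " of ", path)
    vals <- if (columns == "percent") nums[21:40] / 100 else
      stats::plogis(nums[1:20])
    out[i, file_order] <- vals
  }
  attr(out, "source") <- "parsed"
  out
}

# Writes the ASCII PSSM dialect that parse_pssm consumes, with percentage
# columns given by `percent` (an L x 20 matrix in [0,1], alphabetical column
# order) and log-odds columns derived as round(logit)-style integers.
# Used by write_dataset() to emit parseable profile fixtures.
write_ascii_pssm <- function(record, percent, path) {
  stopifnot(nrow(percent) == nchar(record$sequence), ncol(percent) == 20L)
  if (is.null(colnames(percent))) colnames(percent) <- AA_ALPHABET
  p_file <- percent[, PSSM_FILE_ORDER, drop = FALSE]
  lodds <- round(2 * (p_file * 20 - 1))  # crude integer profile scores
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed"), con)
  writeLines(paste0("            ",
                    paste(sprintf("%3s", c(PSSM_FILE_ORDER, PSSM_FILE_ORDER)),
                          collapse = "")), con)
  chars <- seq_chars(record)
  for (i in seq_len(nrow(percent))) {
    writeLines(paste0(sprintf("%5d %s ", i, chars[i]),
                      paste(sprintf("%3d", lodds[i, ]), collapse = ""),
                      " ",
                      paste(sprintf("%4d", round(p_file[i, ] * 100)),
                            collapse = ""),
                      sprintf("  %5.2f %8.2f", 0, 0)), con)
  }
  writeLines(c("", "                      K         Lambda"), con)
  invisible(path)
}
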