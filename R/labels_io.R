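#' Read / write label files
#'
#' Label files are two-column TSV: sequence id, then the comma-separated
#' list of EC main classes (e.g. `"1,3"`). `read_labels` returns a named
#' list of sorted integer vectors keyed by id; empty or full label sets are
#' rejected with the offending id because the ranking loss is undefined for
#' them.
#'
#' @param path Labels TSV path.
#' @param Q Number of classes used for validation.
#' @param allow_degenerate Accept empty/full sets (used for the binary
#'   level, where the label column may be empty).
#' @return Named list of integer vectors.
#' @name labels_io
#' @export
read_labels <- function(path, Q = 6L, allow_degenerate = FALSE) {
  if (!file.exists(path)) stop("labels file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", comment.char = "")
  if (ncol(df) < 2L) stop("labels file must have two tab-separated columns")
  out <- lapply(df[[2]], function(s) {
    if (!nzchar(trimws(s))) integer(0)
    else sort(unique(as.integer(strsplit(trimws(s), ",")[[1]])))
  })
  names(out) <- df[[1]]
  for (id in names(out)) {
    y <- out[[id]]
    if (length(y) > 0L && (min(y) < 1L || max(y) > Q))
      stop("labels for '", id, "' outside 1..", Q)
    if (!allow_degenerate && (length(y) == 0L || length(y) == Q))
      stop("instance '", id, "': empty or full label set is not allowed")
  }
  out
}

#' @rdname labels_io
#' @param ids Character vector of sequence ids.
#' @param labels_list List of integer label sets, same length as `ids`.
#' @export
write_labels <- function(ids, labels_list, path) {
  stopifnot(length(ids) == length(labels_list))
  df <- data.frame(
    id = ids,
    classes = vapply(labels_list, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
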