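as_members <- function(x, Q) {
  if (inherits(x, "predicted_label_set")) x <- x$members
  validate_label_set(x, Q)
}

#' Per-class confusion counts for multi-label predictions
#'
#' For every class j counts the instances where j was predicted and true
#' (TP), predicted only (FP), true only (FN), or neither (TN). The four
#' counts partition the N instances for every class.
#'
#' @param preds List of predicted label sets ([apply_threshold] results or
#'   integer vectors).
#' @param truths List of true label sets (integer vectors).
#' @param Q Number of classes.
#' @return Object of class `confusion_counts`: list of integer vectors
#'   `tp`, `fp`, `tn`, `fn` (length Q) plus `n` and `q`.
#' @export
confusion_counts <- function(preds, truths, Q) {
  if (length(preds) != length(truths))
    stop("prediction and truth lists have different lengths (",
         length(preds), " vs ", length(truths), ")")
  if (length(preds) == 0L) stop("cannot evaluate an empty prediction set")
  n <- length(preds)
  tp <- fp <- tn <- fn <- integer(Q)
  for (i in seq_len(n)) {
    p <- as_members(preds[[i]], Q)
    y <- as_members(truths[[i]], Q)
    pv <- yv <- logical(Q)
    pv[p] <- TRUE; yv[y] <- TRUE
    tp <- tp + (pv & yv)
    fp <- fp + (pv & !yv)
    fn <- fn + (!pv & yv)
    tn <- tn + (!pv & !yv)
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, n = n, q = Q),
            class = "confusion_counts")
}

safe_div <- function(num, den) ifelse(den == 0, 0, num / den)

#' Binary classification metrics for a single class
#'
#' Accuracy, precision, recall and F1 from one class's confusion counts.
#' A zero denominator (class never predicted, never present, etc.) yields 0
#' for the affected metric and is flagged in the `degenerate` attribute
#' rather than propagating NaN; this is conservative and never inflates an
#' average.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`
#'   with logical attribute `degenerate` marking zero-denominator metrics.
#' @export
binary_metrics <- function(tp, fp, tn, fn) {
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  out <- c(accuracy = safe_div(tp + tn, tp + fp + tn + fn),
           precision = prec, recall = rec, f1 = f1)
  attr(out, "degenerate") <- c(accuracy = tp + fp + tn + fn == 0,
                               precision = tp + fp == 0,
                               recall = tp + fn == 0,
                               f1 = prec + rec == 0)
  out
}

#' Hamming loss
#'
#' Mean fraction of instance-label pairs predicted incorrectly: the size of
#' the symmetric difference between predicted and true label sets, divided
#' by Q and averaged over instances. 0 is perfect; smaller is better.
#'
#' @inheritParams confusion_counts
#' @return Number in \[0,1\].
#' @export
hamming_loss <- function(preds, truths, Q) {
  if (length(preds) != length(truths))
    stop("prediction and truth lists have different lengths")
  if (length(preds) == 0L) stop("cannot evaluate an empty prediction set")
  mean(vapply(seq_along(preds), function(i) {
    p <- as_members(preds[[i]], Q)
    y <- as_members(truths[[i]], Q)
    length(union(setdiff(p, y), setdiff(y, p))) / Q
  }, numeric(1)))
}

#' Subset accuracy (exact-match ratio)
#'
#' Fraction of instances whose predicted label set equals the true set
#' exactly; supersets and subsets both count as 0. The strictest
#' multi-label criterion.
#'
#' @inheritParams confusion_counts
#' @return Number in \[0,1\].
#' @export
subset_accuracy <- function(preds, truths) {
  if (length(preds) != length(truths))
    stop("prediction and truth lists have different lengths")
  if (length(preds) == 0L) stop("cannot evaluate an empty prediction set")
  members_of <- function(x) {
    if (inherits(x, "predicted_label_set")) x <- x$members
    sort(unique(as.integer(x)))
  }
  mean(vapply(seq_along(preds), function(i)
    as.numeric(identical(members_of(preds[[i]]), members_of(truths[[i]]))),
    numeric(1)))
}

#' Macro-averaged precision, recall and F1
#'
#' Per-class precision and recall are computed from each class's own
#' confusion counts and averaged with equal class weight. Macro-F1 is the
#' mean of the per-class harmonic means `2 P_j R_j / (P_j + R_j)` (not the
#' harmonic mean of the macro averages).
#'
#' @param counts A [confusion_counts] object.
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
macro_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  p <- safe_div(counts$tp, counts$tp + counts$fp)
  r <- safe_div(counts$tp, counts$tp + counts$fn)
  f1 <- safe_div(2 * p * r, p + r)
  c(precision = mean(p), recall = mean(r), f1 = mean(f1))
}

#' Micro-averaged precision, recall and F1
#'
#' Counts are pooled over classes before computing the metrics:
#' `P = sum TP / (sum TP + sum FP)`, `R = sum TP / (sum TP + sum FN)`, and
#' F1 is their harmonic mean. Micro averages weight every instance-label
#' decision equally regardless of class size.
#'
#' @param counts A [confusion_counts] object.
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
micro_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- sum(counts$tp); fp <- sum(counts$fp); fn <- sum(counts$fn)
  p <- safe_div(tp, tp + fp)
  r <- safe_div(tp, tp + fn)
  c(precision = p, recall = r, f1 = safe_div(2 * p * r, p + r))
}

#' Full multi-label evaluation report
#'
#' Computes every example-based and label-based quantity for a prediction
#' set: hamming loss, subset accuracy, macro and micro precision/recall/F1,
#' and the underlying per-class confusion counts.
#'
#' @inheritParams confusion_counts
#' @return Object of class `metrics_report` (a list of the named
#'   quantities, plus `counts` and `n_instances`).
#' @export
metrics_report <- function(preds, truths, Q) {
  counts <- confusion_counts(preds, truths, Q)
  mac <- macro_metrics(counts)
  mic <- micro_metrics(counts)
  structure(list(
    hamming_loss = hamming_loss(preds, truths, Q),
    subset_accuracy = subset_accuracy(preds, truths),
    macro_precision = unname(mac["precision"]),
    macro_recall = unname(mac["recall"]),
    macro_f1 = unname(mac["f1"]),
    micro_precision = unname(mic["precision"]),
    micro_recall = unname(mic["recall"]),
    micro_f1 = unname(mic["f1"]),
    counts = counts, n_instances = counts$n
  ), class = "metrics_report")
}

metric_names <- c("hamming_loss", "subset_accuracy", "macro_precision",
                  "macro_recall", "macro_f1", "micro_precision",
                  "micro_recall", "micro_f1")

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> N=", x$n_instances, ", Q=", x$counts$q, "\n", sep = "")
  for (m in metric_names)
    cat(sprintf("  %-16s %.4f\n", m, x[[m]]))
  invisible(x)
}

#' Write one or more metric reports as a TSV table
#'
#' One row per report, one column per metric, preceded by a `run` column.
#'
#' @param reports A single [metrics_report] or a (possibly named) list of
#'   them.
#' @param path Output file path.
#' @export
write_metrics_tsv <- function(reports, path) {
  if (inherits(reports, "metrics_report")) reports <- list(reports)
  rows <- lapply(reports, function(r)
    as.data.frame(r[metric_names], check.names = FALSE))
  df <- do.call(rbind, rows)
  nm <- names(reports)
  df <- cbind(run = if (is.null(nm)) seq_along(reports) else nm, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
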