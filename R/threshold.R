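#' Linear threshold model
#'
#' Holds the parameters of the adaptive label-assignment threshold
#' `t(x) = w . l(x) + b`, a linear function of the per-class score vector.
#'
#' @param w Numeric weight vector of length Q.
#' @param b Numeric scalar intercept.
#' @param residual_rms Root-mean-square residual of the least-squares fit
#'   (0 for hand-built models).
#' @return Object of class `threshold_model`.
#' @export
threshold_model <- function(w, b, residual_rms = 0) {
  stopifnot(is.numeric(w), all(is.finite(w)),
            is.numeric(b), length(b) == 1L, is.finite(b))
  structure(list(w = as.numeric(w), b = as.numeric(b),
                 residual_rms = residual_rms),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat("<threshold_model> Q=", length(x$w), " b=", signif(x$b, 4),
      " residual_rms=", signif(x$residual_rms, 4), "\n", sep = "")
  invisible(x)
}

#' Misclassified-label count at a candidate threshold
#'
#' The count objective minimized when choosing a per-instance threshold:
#' the number of true labels whose score is `<= t` plus the number of
#' absent labels whose score is `>= t` (both comparisons inclusive).
#'
#' @param t Candidate threshold (numeric, may be a vector).
#' @param scores Per-class score vector.
#' @param labels Integer vector of true classes.
#' @return Integer count (vectorized over `t`).
#' @export
label_cut_objective <- function(t, scores, labels) {
  Q <- length(scores)
  L <- validate_label_set(labels, Q)
  cmp <- setdiff(seq_len(Q), L)
  vapply(t, function(tt)
    sum(scores[L] <= tt) + sum(scores[cmp] >= tt), numeric(1))
}

#' Optimal per-instance label-assignment threshold
#'
#' Finds the threshold minimizing [label_cut_objective] for one instance.
#' The objective is piecewise constant, so it is evaluated exhaustively on
#' the open intervals between consecutive distinct sorted scores (plus the
#' two unbounded outer intervals); minima never occur exactly at a score
#' value, where both inclusive comparisons count it. When the minimizing
#' set is a segment, its middle value is returned: for the printed example
#' scores (0.9, 0.8, 0.3, 0.1, 0.1, 0.1) with true classes \{1,2\} the
#' objective is 0 on (0.3, 0.8) and the threshold is 0.55.
#'
#' Unbounded minimizing intervals (including the degenerate empty and full
#' label sets, which are tolerated here) are closed off at a fixed offset of
#' half the mean adjacent-score gap beyond the extreme score (0.5 when all
#' scores tie). Among multiple disjoint minimizing segments the widest is
#' chosen, ties broken by the lower midpoint, so the result is
#' deterministic.
#'
#' @inheritParams label_cut_objective
#' @return Single numeric threshold.
#' @export
optimal_instance_threshold <- function(scores, labels) {
  Q <- length(scores)
  labels <- validate_label_set(labels, Q)
  s <- sort(unique(as.numeric(scores)))
  k <- length(s)
  g <- if (k >= 2L) (s[k] - s[1]) / (k - 1L) / 2 else 0.5
  # interval endpoints: virtual outer bounds at +/- 2g beyond the extremes,
  # so outer-interval midpoints sit at the half-mean-gap offset g
  ends <- c(s[1] - 2 * g, s, s[k] + 2 * g)
  lo <- ends[-length(ends)]
  hi <- ends[-1]
  mids <- (lo + hi) / 2
  obj <- label_cut_objective(mids, scores, labels)
  best <- min(obj)
  is_min <- obj == best

  # merge adjacent minimizing intervals when the separating score value also
  # attains the minimum (then the solution segment is contiguous through it)
  seg_lo <- numeric(0); seg_hi <- numeric(0)
  i <- 1L
  while (i <= length(is_min)) {
    if (is_min[i]) {
      j <- i
      while (j < length(is_min) && is_min[j + 1L] &&
             label_cut_objective(hi[j], scores, labels) == best) j <- j + 1L
      seg_lo <- c(seg_lo, lo[i]); seg_hi <- c(seg_hi, hi[j])
      i <- j + 1L
    } else i <- i + 1L
  }
  width <- seg_hi - seg_lo
  pick <- which(width == max(width))
  if (length(pick) > 1L) {
    mid <- (seg_lo[pick] + seg_hi[pick]) / 2
    pick <- pick[which.min(mid)]
  }
  (seg_lo[pick] + seg_hi[pick]) / 2
}

#' Fit the linear threshold function by least squares
#'
#' Computes the per-instance optimal threshold `t_i` for every row of the
#' score matrix, then solves `min_{w,b} sum_i (w . l_i + b - t_i)^2`. The
#' system is solved through the singular value decomposition, which returns
#' the minimum-norm solution when the design is rank deficient (e.g. fewer
#' instances than classes).
#'
#' @param score_matrix m x Q matrix of per-class scores, one row per
#'   instance.
#' @param labels_list List of m integer label sets.
#' @param targets Optional numeric vector of per-instance threshold targets
#'   overriding the [optimal_instance_threshold] computation (mainly for
#'   calibration experiments and testing the solver in isolation).
#' @return A [threshold_model]; its `residual_rms` field reports the
#'   root-mean-square fit residual.
#' @export
fit_threshold_function <- function(score_matrix, labels_list = NULL,
                                   targets = NULL) {
  score_matrix <- as.matrix(score_matrix)
  m <- nrow(score_matrix)
  if (m == 0L) stop("cannot fit a threshold function on 0 instances")
  if (is.null(targets)) {
    stopifnot(length(labels_list) == m)
    targets <- vapply(seq_len(m), function(i)
      optimal_instance_threshold(score_matrix[i, ], labels_list[[i]]),
      numeric(1))
  }
  stopifnot(length(targets) == m)
  X <- cbind(score_matrix, 1)
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(sv$d)
  pos <- sv$d > tol
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], targets)) / sv$d[pos])
  resid <- drop(X %*% beta) - targets
  threshold_model(w = beta[seq_len(ncol(score_matrix))],
                  b = beta[ncol(score_matrix) + 1L],
                  residual_rms = sqrt(mean(resid^2)))
}

#' Assign labels with the adaptive threshold
#'
#' Computes `t(x) = w . l(x) + b` and returns the classes whose score is
#' strictly greater than the threshold. An enzyme always carries at least
#' one main class at this level, so when the strict cut leaves no class the
#' single highest-scoring class (lowest index on ties) is returned and the
#' result is flagged `fallback_used = TRUE` for auditability.
#'
#' @param scores Per-class score vector.
#' @param model A [threshold_model].
#' @return Object of class `predicted_label_set` with fields `members`
#'   (sorted integer vector) and `fallback_used`.
#' @export
apply_threshold <- function(scores, model) {
  stopifnot(inherits(model, "threshold_model"),
            length(scores) == length(model$w))
  t_x <- sum(model$w * scores) + model$b
  members <- which(scores > t_x)
  fallback <- length(members) == 0L
  if (fallback) members <- which.max(scores)
  structure(list(members = as.integer(members), fallback_used = fallback,
                 threshold = t_x),
            class = "predicted_label_set")
}

#' @export
print.predicted_label_set <- function(x, ...) {
  cat("<predicted_label_set> {", paste(x$members, collapse = ","), "}",
      if (x$fallback_used) " [fallback]", "\n", sep = "")
  invisible(x)
}
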