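validate_label_set <- function(labels, Q) {
  labels <- as.integer(labels)
  if (anyDuplicated(labels)) labels <- unique(labels)
  if (length(labels) > 0L && (min(labels) < 1L || max(labels) > Q))
    stop("label set must be a subset of {1..", Q, "}, got: ",
         paste(labels, collapse = ","))
  sort(labels)
}

check_rankable <- function(labels, Q) {
  if (length(labels) == 0L || length(labels) == Q)
    stop("pairwise ranking loss undefined: empty label set or empty complement")
  labels
}

#' BP-MLL pairwise ranking loss for one instance
#'
#' The per-instance training error of backpropagation for multi-label
#' learning: every (true label k, absent label q) pair contributes
#' `exp(-(l_k - l_q))`, and the sum is normalized by `|L| * |L-bar|`, the
#' product of the label-set and complement cardinalities. Minimizing it
#' pushes the network scores of true labels above those of absent labels,
#' with exponentially severe penalties for inverted pairs. Both the label
#' set and its complement must be non-empty or the normalization is
#' undefined.
#'
#' @param scores Numeric vector of per-class network outputs in (0,1).
#' @param labels Integer vector: the classes this instance has (subset of
#'   `1:length(scores)`).
#' @return Single positive number.
#' @examples
#' bpmll_loss(rep(0.5, 6), 1)  # exactly 1: every pair contributes exp(0)
#' @export
bpmll_loss <- function(scores, labels) {
  Q <- length(scores)
  L <- check_rankable(validate_label_set(labels, Q), Q)
  cmp <- setdiff(seq_len(Q), L)
  # sum_{k,q} e^{-(l_k - l_q)} factorizes as (sum_k e^{-l_k})(sum_q e^{l_q})
  sum(exp(-scores[L])) * sum(exp(scores[cmp])) / (length(L) * length(cmp))
}

#' Gradient of the BP-MLL loss with respect to the score vector
#'
#' Analytic partial derivatives of [bpmll_loss]: for a true label j the
#' component is `-(1/(|L||L-bar|)) * sum_q exp(-(l_j - l_q))`, and for an
#' absent label j it is `+(1/(|L||L-bar|)) * sum_k exp(-(l_k - l_j))`.
#' True-label components are always negative (raising the score lowers the
#' loss) and the components sum to zero over each (k,q) pair's antisymmetry.
#'
#' @inheritParams bpmll_loss
#' @return Numeric vector of length `length(scores)`.
#' @export
bpmll_gradient <- function(scores, labels) {
  Q <- length(scores)
  L <- check_rankable(validate_label_set(labels, Q), Q)
  cmp <- setdiff(seq_len(Q), L)
  norm <- length(L) * length(cmp)
  g <- numeric(Q)
  s_cmp <- sum(exp(scores[cmp]))
  s_lab <- sum(exp(-scores[L]))
  g[L] <- -exp(-scores[L]) * s_cmp / norm
  g[cmp] <- exp(scores[cmp]) * s_lab / norm
  g
}

#' Total ranking loss over a set of instances
#'
#' The training objective sums the per-instance [bpmll_loss] over the
#' dataset; an empty list has loss 0. Invalid instances (empty or full
#' label sets) raise an error naming the offending index.
#'
#' @param scores_list List of score vectors.
#' @param labels_list List of label sets, same length.
#' @return Single non-negative number (the sum; divide by the list length
#'   for the mean reported in training histories).
#' @export
bpmll_batch_loss <- function(scores_list, labels_list) {
  stopifnot(length(scores_list) == length(labels_list))
  total <- 0
  for (i in seq_along(scores_list)) {
    total <- total + tryCatch(
      bpmll_loss(scores_list[[i]], labels_list[[i]]),
      error = function(e) stop("instance ", i, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  total
}

#' Independent-label squared loss
#'
#' The baseline multi-label error `sum_j (l_j - d_j)^2` with `d` the 0/1
#' label indicator. It treats classes as independent and ignores ranking
#' relationships between them; provided as the contrast to [bpmll_loss].
#'
#' @inheritParams bpmll_loss
#' @return Single non-negative number.
#' @export
squared_loss <- function(scores, labels) {
  Q <- length(scores)
  L <- validate_label_set(labels, Q)
  d <- numeric(Q)
  d[L] <- 1
  sum((scores - d)^2)
}
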