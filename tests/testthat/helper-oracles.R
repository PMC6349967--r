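# Independent brute-force reference implementations used to cross-check the
# package's vectorized code. These deliberately use naive double loops and
# dense grids, never the functions they verify.

# Pairwise ranking loss by explicit two-loop summation.
oracle_bpmll <- function(scores, labels) {
  Q <- length(scores)
  cmp <- setdiff(seq_len(Q), labels)
  total <- 0
  for (k in labels) for (q in cmp)
    total <- total + exp(-(scores[k] - scores[q]))
  total / (length(labels) * length(cmp))
}

# Central finite differences of the ranking loss.
oracle_bpmll_grad_fd <- function(scores, labels, h = 1e-6) {
  vapply(seq_along(scores), function(j) {
    up <- scores; up[j] <- up[j] + h
    dn <- scores; dn[j] <- dn[j] - h
    (oracle_bpmll(up, labels) - oracle_bpmll(dn, labels)) / (2 * h)
  }, numeric(1))
}

# Misclassified-label count objective, written independently.
oracle_cut_count <- function(t, scores, labels) {
  cmp <- setdiff(seq_along(scores), labels)
  sum(scores[labels] <= t) + sum(scores[cmp] >= t)
}

# Global minimum of the count objective over a dense grid plus all data
# points and the midpoints between consecutive sorted scores (the objective
# is piecewise constant with breakpoints at the scores, so this candidate
# set sees every attained value even when two scores are closer than the
# grid spacing).
oracle_min_cut <- function(scores, labels, grid_n = 2001) {
  lo <- min(scores) - 1; hi <- max(scores) + 1
  s <- sort(unique(scores))
  mids <- if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else numeric(0)
  cand <- c(seq(lo, hi, length.out = grid_n), scores, mids)
  min(vapply(cand, oracle_cut_count, numeric(1),
             scores = scores, labels = labels))
}

# Naive per-instance / per-class reference for every evaluation metric.
oracle_metrics <- function(preds, truths, Q) {
  n <- length(preds)
  tp <- fp <- tn <- fn <- integer(Q)
  ham <- 0; exact <- 0
  for (i in seq_len(n)) {
    p <- preds[[i]]; y <- truths[[i]]
    sym <- 0
    for (j in seq_len(Q)) {
      inp <- j %in% p; iny <- j %in% y
      if (inp && iny) tp[j] <- tp[j] + 1L
      if (inp && !iny) { fp[j] <- fp[j] + 1L; sym <- sym + 1 }
      if (!inp && iny) { fn[j] <- fn[j] + 1L; sym <- sym + 1 }
      if (!inp && !iny) tn[j] <- tn[j] + 1L
    }
    ham <- ham + sym / Q
    if (setequal(p, y)) exact <- exact + 1
  }
  div0 <- function(a, b) if (b == 0) 0 else a / b
  pj <- rj <- fj <- numeric(Q)
  for (j in seq_len(Q)) {
    pj[j] <- div0(tp[j], tp[j] + fp[j])
    rj[j] <- div0(tp[j], tp[j] + fn[j])
    fj[j] <- div0(2 * pj[j] * rj[j], pj[j] + rj[j])
  }
  mip <- div0(sum(tp), sum(tp) + sum(fp))
  mir <- div0(sum(tp), sum(tp) + sum(fn))
  list(hamming = ham / n, subset = exact / n,
       macro_p = mean(pj), macro_r = mean(rj), macro_f1 = mean(fj),
       micro_p = mip, micro_r = mir,
       micro_f1 = div0(2 * mip * mir, mip + mir),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

# Random valid (scores, labels) draw: label-set size 1..Q-1.
random_instance <- function(Q) {
  size <- sample.int(Q - 1L, 1L)
  list(scores = runif(Q, 0.001, 0.999),
       labels = sort(sample.int(Q, size)))
}

# Bag-of-motifs oracle classifier: the class set whose motifs occur in the
# sequence (exact on noiseless synthetic data).
motif_oracle_predict <- function(records, motifs) {
  lapply(records, function(rec)
    unname(which(vapply(motifs, grepl, logical(1), x = rec$sequence,
                        fixed = TRUE))))
}

tiny_sim <- function(n = 40, seed = 7, ...) {
  generate_dataset(sim_spec(n = n, seed = seed, ...))
}
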