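# Internal numerical plumbing for the branched network: im2col convolution,
# global pooling, and the Adam optimizer. All functions are pure R over
# BLAS-backed dense matrices; shapes are small enough that this is fast at
# desk scale.

# Sliding-window expansion: row i of the result is the concatenation of
# input rows i..i+w-1. Inputs shorter than the window are zero-padded so at
# least one output position exists.
im2col <- function(A, w) {
  P0 <- nrow(A); C <- ncol(A)
  if (P0 < w) A <- rbind(A, matrix(0, w - P0, C))
  n_out <- nrow(A) - w + 1L
  X <- matrix(0, n_out, w * C)
  for (k in seq_len(w))
    X[, ((k - 1L) * C + 1L):(k * C)] <- A[k:(k + n_out - 1L), , drop = FALSE]
  X
}

# Adjoint of im2col: scatter-adds window-gradient blocks back onto input
# rows. `P0` is the unpadded input row count.
col2im <- function(dX, P0, w, C) {
  n_out <- nrow(dX)
  P <- n_out + w - 1L
  dA <- matrix(0, P, C)
  for (k in seq_len(w)) {
    rows <- k:(k + n_out - 1L)
    dA[rows, ] <- dA[rows, ] + dX[, ((k - 1L) * C + 1L):(k * C), drop = FALSE]
  }
  dA[seq_len(P0), , drop = FALSE]
}

add_row_vec <- function(Z, b) Z + matrix(b, nrow(Z), ncol(Z), byrow = TRUE)

# Global pooling over positions; returns the pooled vector and what backward
# needs (argmax rows for max pooling, row count for average).
pool_forward <- function(A, kind) {
  if (kind == "global-max") {
    amax <- max.col(t(A), ties.method = "first")
    list(pooled = A[cbind(amax, seq_len(ncol(A)))], amax = amax, P = nrow(A))
  } else {
    list(pooled = colMeans(A), amax = NULL, P = nrow(A))
  }
}

pool_backward <- function(dpooled, cache, kind, C) {
  if (kind == "global-max") {
    dA <- matrix(0, cache$P, C)
    dA[cbind(cache$amax, seq_len(C))] <- dpooled
    dA
  } else {
    matrix(dpooled / cache$P, cache$P, C, byrow = TRUE)
  }
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
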