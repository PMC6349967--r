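#' Model configuration
#'
#' Collects every tunable of the branched network and its training loop.
#' The published architecture fixes only the topology (two convolutional
#' branches over the L x 20 encodings, a fully-connected branch over the
#' domain vector, concatenation, fully-connected classifier) and the epoch
#' count; the remaining defaults here are this package's own desk-scale
#' choices and all of them can be overridden.
#'
#' @param q_classes Number of output classes Q (6 for the main-class level,
#'   1 for the mono/multi binary level).
#' @param conv_filters List of `c(window, channels)` pairs, one per
#'   convolutional layer, applied in order to both sequence branches.
#' @param pool `"global-max"` or `"global-average"` pooling over positions
#'   (this is what makes the network length-independent).
#' @param fc_widths Two hidden widths: domain-branch layer and classifier
#'   head.
#' @param dropout Dropout rate on the concatenated feature vector during
#'   training, in \[0,1).
#' @param max_len Optional cap on sequence length (rows beyond it are
#'   truncated); `NULL` for no cap.
#' @param seed Integer seed for weight initialization and training-time
#'   randomness.
#' @param epochs Training epochs (the published runs use 40).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam learning rate, > 0.
#' @param class_weights Optional positive per-class weights for the
#'   weighted binary cross-entropy loss; `NULL` derives them from training
#'   label frequencies.
#' @return Object of class `model_config`.
#' @export
model_config <- function(q_classes = 6L,
                         conv_filters = list(c(4L, 32L), c(8L, 32L)),
                         pool = c("global-max", "global-average"),
                         fc_widths = c(64L, 128L),
                         dropout = 0.3,
                         max_len = NULL,
                         seed = 1L,
                         epochs = 40L,
                         batch_size = 32L,
                         learning_rate = 1e-3,
                         class_weights = NULL) {
  pool <- match.arg(pool)
  bad <- character()
  if (!(is.numeric(q_classes) && length(q_classes) == 1L && q_classes >= 1))
    bad <- c(bad, "q_classes (must be an integer >= 1)")
  if (!(is.list(conv_filters) && length(conv_filters) >= 1L &&
        all(vapply(conv_filters, function(f)
          length(f) == 2L && all(f >= 1), logical(1)))))
    bad <- c(bad, "conv_filters (list of c(window, channels), all >= 1)")
  if (!(length(fc_widths) == 2L && all(fc_widths >= 1)))
    bad <- c(bad, "fc_widths (two widths >= 1)")
  if (!(is.numeric(dropout) && dropout >= 0 && dropout < 1))
    bad <- c(bad, "dropout (must be in [0,1))")
  if (!is.null(max_len) && (!is.numeric(max_len) || max_len < 1))
    bad <- c(bad, "max_len (must be NULL or >= 1)")
  if (!(is.numeric(epochs) && epochs >= 1)) bad <- c(bad, "epochs (>= 1)")
  if (!(is.numeric(batch_size) && batch_size >= 1))
    bad <- c(bad, "batch_size (>= 1)")
  if (!(is.numeric(learning_rate) && learning_rate > 0))
    bad <- c(bad, "learning_rate (must be > 0)")
  if (!is.null(class_weights) && any(class_weights <= 0))
    bad <- c(bad, "class_weights (must be positive)")
  if (length(bad) > 0L)
    stop("invalid model configuration: ", paste(bad, collapse = "; "))
  structure(list(
    q_classes = as.integer(q_classes),
    conv_filters = lapply(conv_filters, as.integer),
    pool = pool,
    fc_widths = as.integer(fc_widths),
    dropout = dropout,
    max_len = if (is.null(max_len)) NULL else as.integer(max_len),
    seed = as.integer(seed),
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    learning_rate = learning_rate,
    class_weights = class_weights
  ), class = "model_config")
}

init_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

#' Build the branched network
#'
#' Instantiates the two-branch convolutional + fully-connected architecture:
#' a convolutional stack (shared topology, separate weights) over the
#' one-hot and profile matrices with global pooling, a fully-connected layer
#' over the domain vector, concatenation, a fully-connected classifier head,
#' and Q logistic outputs so every per-class score lies in (0,1). Weights
#' are drawn deterministically from `config$seed` (He-scaled normal for the
#' hidden layers).
#'
#' @param config A [model_config].
#' @param domain_dim Length D of the domain-presence vector, >= 1.
#' @return Object of class `trained_model` (untrained: empty history).
#' @export
build_model <- function(config, domain_dim) {
  stopifnot(inherits(config, "model_config"))
  if (!(is.numeric(domain_dim) && domain_dim >= 1))
    stop("invalid model configuration: domain_dim (must be >= 1)")
  domain_dim <- as.integer(domain_dim)
  set.seed(config$seed)
  params <- list()
  for (branch in c("oh", "ps")) {
    in_ch <- 20L
    for (l in seq_along(config$conv_filters)) {
      w <- config$conv_filters[[l]][1]
      out_ch <- config$conv_filters[[l]][2]
      fan_in <- w * in_ch
      params[[paste0(branch, ".conv", l, ".W")]] <-
        init_mat(fan_in, out_ch, sqrt(2 / fan_in))
      params[[paste0(branch, ".conv", l, ".b")]] <- numeric(out_ch)
      in_ch <- out_ch
    }
  }
  conv_out <- config$conv_filters[[length(config$conv_filters)]][2]
  dom_w <- config$fc_widths[1]
  head_w <- config$fc_widths[2]
  params[["dom.W"]] <- init_mat(domain_dim, dom_w, sqrt(2 / domain_dim))
  params[["dom.b"]] <- numeric(dom_w)
  concat <- 2L * conv_out + dom_w
  params[["head.W"]] <- init_mat(concat, head_w, sqrt(2 / concat))
  params[["head.b"]] <- numeric(head_w)
  params[["out.W"]] <- init_mat(head_w, config$q_classes, sqrt(1 / head_w))
  params[["out.b"]] <- numeric(config$q_classes)
  structure(list(params = params, config = config,
                 domain_dim = domain_dim,
                 domain_vocabulary = NULL,
                 threshold = NULL,
                 history = numeric(0)),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat("<trained_model> Q=", x$config$q_classes,
      " domain_dim=", x$domain_dim,
      " epochs_trained=", length(x$history),
      if (!is.null(x$threshold)) " [+threshold]", "\n", sep = "")
  invisible(x)
}

conv_branch_forward <- function(params, prefix, X, filters) {
  A <- X
  layers <- vector("list", length(filters))
  for (l in seq_along(filters)) {
    w <- filters[[l]][1]
    Xc <- im2col(A, w)
    Z <- add_row_vec(Xc %*% params[[paste0(prefix, ".conv", l, ".W")]],
                     params[[paste0(prefix, ".conv", l, ".b")]])
    layers[[l]] <- list(P_in = nrow(A), Xc = Xc, Z = Z)
    A <- pmax(Z, 0)
  }
  list(A = A, layers = layers)
}

conv_branch_backward <- function(params, prefix, dA, fw, filters, grads) {
  for (l in rev(seq_along(filters))) {
    w <- filters[[l]][1]
    cache <- fw$layers[[l]]
    dZ <- dA * (cache$Z > 0)
    grads[[paste0(prefix, ".conv", l, ".W")]] <-
      grads[[paste0(prefix, ".conv", l, ".W")]] + crossprod(cache$Xc, dZ)
    grads[[paste0(prefix, ".conv", l, ".b")]] <-
      grads[[paste0(prefix, ".conv", l, ".b")]] + colSums(dZ)
    if (l > 1L) {
      W <- params[[paste0(prefix, ".conv", l, ".W")]]
      dXc <- tcrossprod(dZ, W)
      in_ch <- filters[[l - 1L]][2]
      dA <- col2im(dXc, cache$P_in, w, in_ch)
    }
  }
  grads
}

nn_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  stopifnot(inherits(x, "encoded_protein"))
  if (length(x$domains) != model$domain_dim)
    stop("domain vector length ", length(x$domains),
         " does not match model domain_dim ", model$domain_dim)
  oh <- x$one_hot; ps <- x$pssm
  if (!is.null(cfg$max_len) && nrow(oh) > cfg$max_len) {
    oh <- oh[seq_len(cfg$max_len), , drop = FALSE]
    ps <- ps[seq_len(cfg$max_len), , drop = FALSE]
  }
  fw_oh <- conv_branch_forward(model$params, "oh", oh, cfg$conv_filters)
  fw_ps <- conv_branch_forward(model$params, "ps", ps, cfg$conv_filters)
  pool_oh <- pool_forward(fw_oh$A, cfg$pool)
  pool_ps <- pool_forward(fw_ps$A, cfg$pool)

  d <- as.numeric(x$domains)
  z_dom <- drop(crossprod(model$params[["dom.W"]], d)) +
    model$params[["dom.b"]]
  h_dom <- pmax(z_dom, 0)

  v <- c(pool_oh$pooled, pool_ps$pooled, h_dom)
  mask <- NULL
  if (training && cfg$dropout > 0) {
    mask <- (stats::runif(length(v)) >= cfg$dropout) / (1 - cfg$dropout)
    v <- v * mask
  }
  z_head <- drop(v %*% model$params[["head.W"]]) + model$params[["head.b"]]
  h_head <- pmax(z_head, 0)
  z_out <- drop(h_head %*% model$params[["out.W"]]) + model$params[["out.b"]]
  scores <- stats::plogis(z_out)
  scores <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  list(scores = scores,
       cache = list(fw_oh = fw_oh, fw_ps = fw_ps,
                    pool_oh = pool_oh, pool_ps = pool_ps,
                    d = d, z_dom = z_dom, h_dom = h_dom,
                    v = v, mask = mask,
                    z_head = z_head, h_head = h_head, scores = scores))
}

# Accumulates gradients of one instance (given dE/dz on the pre-logistic
# outputs) into `grads`.
nn_backward <- function(model, cache, dz_out, grads) {
  cfg <- model$config
  grads[["out.W"]] <- grads[["out.W"]] + outer(cache$h_head, dz_out)
  grads[["out.b"]] <- grads[["out.b"]] + dz_out
  dh_head <- drop(model$params[["out.W"]] %*% dz_out)
  dz_head <- dh_head * (cache$z_head > 0)
  grads[["head.W"]] <- grads[["head.W"]] + outer(cache$v, dz_head)
  grads[["head.b"]] <- grads[["head.b"]] + dz_head
  dv <- drop(model$params[["head.W"]] %*% dz_head)
  if (!is.null(cache$mask)) dv <- dv * cache$mask

  conv_out <- ncol(cache$fw_oh$A)
  i1 <- seq_len(conv_out)
  i2 <- conv_out + seq_len(conv_out)
  i3 <- (2L * conv_out) + seq_along(cache$h_dom)

  dz_dom <- dv[i3] * (cache$z_dom > 0)
  grads[["dom.W"]] <- grads[["dom.W"]] + outer(cache$d, dz_dom)
  grads[["dom.b"]] <- grads[["dom.b"]] + dz_dom

  dA_oh <- pool_backward(dv[i1], cache$pool_oh, cfg$pool, conv_out)
  dA_ps <- pool_backward(dv[i2], cache$pool_ps, cfg$pool, conv_out)
  grads <- conv_branch_backward(model$params, "oh", dA_oh, cache$fw_oh,
                                cfg$conv_filters, grads)
  conv_branch_backward(model$params, "ps", dA_ps, cache$fw_ps,
                       cfg$conv_filters, grads)
}

#' Score one encoded protein
#'
#' Pure forward pass through the network: returns the length-Q vector of
#' per-class scores, each in (0,1). The output depends only on the model
#' and the input (no dropout, no batch effects), so scoring an instance
#' alone or within any batch gives identical results.
#'
#' @param model A [trained_model].
#' @param x An [encoded_protein] whose domain vector length matches the
#'   model.
#' @return Numeric vector of length `model$config$q_classes`.
#' @export
forward <- function(model, x) {
  stopifnot(inherits(model, "trained_model"))
  nn_forward(model, x, training = FALSE)$scores
}

#' Score matrix for a list of encoded proteins
#'
#' @param model A [trained_model].
#' @param xs List of [encoded_protein] objects.
#' @return m x Q numeric matrix, one row per input.
#' @export
score_matrix <- function(model, xs) {
  Q <- model$config$q_classes
  t(vapply(xs, function(x) forward(model, x), numeric(Q)))
}

default_class_weights <- function(labels_list, Q) {
  n <- length(labels_list)
  pos <- integer(Q)
  for (y in labels_list) pos[y] <- pos[y] + 1L
  pmax((n - pos) / pmax(pos, 1L), 1)
}

loss_grad_z <- function(scores, y, loss, cw) {
  Q <- length(scores)
  if (loss == "bpmll") {
    g <- bpmll_gradient(scores, y)
    list(loss = bpmll_loss(scores, y), dz = g * scores * (1 - scores))
  } else {
    d <- numeric(Q); d[y] <- 1
    c_j <- ifelse(d == 1, cw, 1)
    val <- -sum(ifelse(d == 1, cw * log(scores), log(1 - scores)))
    dz <- ifelse(d == 1, -c_j * (1 - scores), scores)
    list(loss = val, dz = dz)
  }
}

#' Train the network
#'
#' End-to-end mini-batch training with the Adam optimizer. The optimized
#' objective is the sum of per-instance losses over the training set; the
#' recorded history holds the per-epoch mean per-instance loss, which is
#' comparable across batch sizes (rescaling a loss by a positive constant
#' does not move its optimum). Two per-instance losses are available:
#'
#' * `"bpmll"` — the pairwise ranking loss [bpmll_loss]; every training
#'   label set must be non-empty and must not contain all Q classes.
#' * `"weighted-binary"` — class-weighted binary cross-entropy, used at the
#'   mono/multi level where the classes are heavily imbalanced; positive
#'   examples of class j are up-weighted by `class_weights[j]` (derived
#'   from inverse label frequency when not supplied).
#'
#' Training is deterministic given the data, configuration and
#' `config$seed` (shuffling and dropout draw from the seeded stream).
#'
#' @param model A [trained_model] from [build_model].
#' @param data List of instances, each a list with fields `x` (an
#'   [encoded_protein]) and `y` (integer label set).
#' @param loss `"bpmll"` or `"weighted-binary"`.
#' @param config Optional [model_config] overriding the one stored in the
#'   model (e.g. to continue training with a different epoch count).
#' @param log_file Optional path; per-epoch lines `epoch<TAB>mean_loss` are
#'   appended.
#' @param verbose Print per-epoch mean loss.
#' @return The trained model, with `history` extended by one mean-loss
#'   entry per epoch.
#' @export
train_model <- function(model, data, loss = c("bpmll", "weighted-binary"),
                        config = NULL, log_file = NULL, verbose = FALSE) {
  loss <- match.arg(loss)
  stopifnot(inherits(model, "trained_model"))
  if (length(data) == 0L) stop("training data is empty")
  cfg <- if (is.null(config)) model$config else config
  Q <- model$config$q_classes
  labels_list <- lapply(data, function(inst) validate_label_set(inst$y, Q))
  if (loss == "bpmll") {
    sizes <- lengths(labels_list)
    bad <- which(sizes == 0L | sizes == Q)
    if (length(bad) > 0L) {
      id <- data[[bad[1]]]$x$id
      stop("instance ", bad[1],
           if (!is.na(id)) paste0(" ('", id, "')"),
           ": pairwise ranking loss undefined: empty label set or empty complement")
    }
  }
  cw <- cfg$class_weights
  if (loss == "weighted-binary" && is.null(cw))
    cw <- default_class_weights(labels_list, Q)
  if (!is.null(cw) && length(cw) == 1L) cw <- rep(cw, Q)

  set.seed(cfg$seed)
  state <- adam_init(model$params)
  zero_grads <- lapply(model$params, function(p) p * 0)
  n <- length(data)
  if (!is.null(log_file)) cat("epoch\tmean_loss\n", file = log_file)
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    epoch_loss <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
      grads <- zero_grads
      for (i in idx) {
        fw <- nn_forward(model, data[[i]]$x, training = TRUE)
        lg <- loss_grad_z(fw$scores, labels_list[[i]], loss, cw)
        epoch_loss <- epoch_loss + lg$loss
        grads <- nn_backward(model, fw$cache, lg$dz, grads)
      }
      grads <- lapply(grads, function(g) g / length(idx))
      upd <- adam_step(model$params, grads, state, cfg$learning_rate)
      model$params <- upd$params
      state <- upd$state
    }
    mean_loss <- epoch_loss / n
    model$history <- c(model$history, mean_loss)
    if (!is.null(log_file))
      cat(sprintf("%d\t%.6g\n", epoch, mean_loss), file = log_file,
          append = TRUE)
    if (verbose)
      message(sprintf("epoch %d/%d: mean loss %.5f", epoch, cfg$epochs,
                      mean_loss))
  }
  model
}

#' Fit and attach the adaptive threshold to a trained model
#'
#' Scores every training instance, computes its optimal per-instance
#' threshold, fits the linear threshold function by least squares
#' ([fit_threshold_function]) and stores the result in the model's
#' `threshold` slot, so the checkpoint carries everything needed for
#' prediction.
#'
#' @param model A trained [trained_model] with Q >= 2.
#' @param data Training instances as in [train_model].
#' @return The model with its `threshold` slot set.
#' @export
calibrate_threshold <- function(model, data) {
  sm <- score_matrix(model, lapply(data, `[[`, "x"))
  model$threshold <- fit_threshold_function(sm, lapply(data, `[[`, "y"))
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single self-describing file holding the weights, the
#' [model_config], the frozen domain vocabulary, the alphabet ordering, the
#' optional threshold model and the training history. Serialization uses
#' R's native format and round-trips bit-exactly.
#'
#' @param model A [trained_model].
#' @param path Checkpoint file path.
#' @name model_checkpoint
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  payload <- unclass(model)
  payload$alphabet <- AA_ALPHABET
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname model_checkpoint
#' @return `load_model` returns the restored [trained_model].
#' @export
load_model <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$alphabet, AA_ALPHABET))
    stop("checkpoint alphabet ordering does not match this package")
  payload$alphabet <- NULL
  payload$config <- structure(payload$config, class = "model_config")
  if (!is.null(payload$threshold))
    payload$threshold <- structure(payload$threshold,
                                   class = "threshold_model")
  structure(payload, class = "trained_model")
}
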