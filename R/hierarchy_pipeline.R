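#' Pipeline configuration
#'
#' Settings for the two-level annotation pipeline: where the binary
#' (mono/multi) and multi-label (main classes) checkpoints live, how to
#' obtain the profile and domain encodings, and the evaluation split.
#'
#' @param binary_model_path Path to the mono/multi model checkpoint
#'   (`q_classes = 1`).
#' @param multilabel_model_path Path to the main-class model checkpoint
#'   (`q_classes = 6`, threshold attached).
#' @param pssm `"fallback"` (degenerate one-hot profile) or `"parsed"`
#'   (read `<id>.pssm` ASCII files from `pssm_dir`).
#' @param pssm_dir Directory of per-record ASCII PSSM files.
#' @param domains `"file"` (read `<id>.hits` from `domains_dir`) or
#'   `"none"` (all-zero domain vector).
#' @param domains_dir Directory of per-record domain hit files.
#' @param split Training fraction for evaluation splits, in (0,1);
#'   default 0.70 (70% train / 30% test).
#' @param cutoff Decision cutoff on the multi-functional probability.
#' @param seed Integer seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(binary_model_path = NULL,
                            multilabel_model_path = NULL,
                            pssm = c("fallback", "parsed"),
                            pssm_dir = NULL,
                            domains = c("file", "none"),
                            domains_dir = NULL,
                            split = 0.70,
                            cutoff = 0.5,
                            seed = 1L) {
  pssm <- match.arg(pssm)
  domains <- match.arg(domains)
  if (!(split > 0 && split < 1)) stop("split must be in (0,1)")
  structure(list(binary_model_path = binary_model_path,
                 multilabel_model_path = multilabel_model_path,
                 pssm = pssm, pssm_dir = pssm_dir,
                 domains = domains, domains_dir = domains_dir,
                 split = split, cutoff = cutoff, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Predict whether an enzyme is multi-functional
#'
#' First level of the hierarchy: a single-logistic-output model scores the
#' probability that the enzyme carries more than one main-class annotation.
#' The decision is `score > cutoff` (strict), with the score returned for
#' auditability.
#'
#' @param x An [encoded_protein].
#' @param model A [trained_model] with `q_classes = 1`.
#' @param cutoff Decision cutoff, default 0.5.
#' @return List with `is_multifunctional` (logical) and `score`.
#' @export
predict_is_multifunctional <- function(x, model, cutoff = 0.5) {
  if (model$config$q_classes != 1L)
    stop("binary level requires a model with q_classes = 1, got ",
         model$config$q_classes)
  s <- forward(model, x)[1]
  list(is_multifunctional = s > cutoff, score = s)
}

#' Predict the main classes of a multi-functional enzyme
#'
#' Second level of the hierarchy: the six-output model scores the instance
#' and the adaptive threshold converts the score vector into a label set.
#'
#' @param x An [encoded_protein].
#' @param model A [trained_model] with `q_classes = 6` (or general Q).
#' @param tmodel A [threshold_model]; defaults to the one stored in the
#'   checkpoint.
#' @return A `predicted_label_set` (see [apply_threshold]).
#' @export
predict_main_classes <- function(x, model, tmodel = model$threshold) {
  if (is.null(tmodel))
    stop("no threshold model supplied and none stored in the checkpoint")
  apply_threshold(forward(model, x), tmodel)
}

encode_for_pipeline <- function(record, config, vocabulary) {
  pssm <- NULL
  if (config$pssm == "parsed") {
    pfile <- file.path(config$pssm_dir, paste0(record$id, ".pssm"))
    pssm <- parse_pssm(pfile, record)
  }
  hits <- character()
  if (config$domains == "file") {
    hfile <- file.path(config$domains_dir, paste0(record$id, ".hits"))
    if (file.exists(hfile)) hits <- parse_domain_hits(hfile)
  }
  encode_record(record, vocabulary, pssm = pssm, hits = hits)
}

#' Annotate a FASTA file with the two-level hierarchy
#'
#' For every record: encode, run the binary mono/multi model, and for
#' multi-functional predictions run the main-class model with its adaptive
#' threshold. Mono-functional records are emitted with a note that
#' finer-grained (digit-level) annotation is delegated to an external
#' mono-functional predictor. Per-record encoding failures do not abort the
#' run: the failing records carry the error message in their `note` column
#' and the number of failures is reported in the `n_failed` attribute (a
#' nonzero value signals partial failure to callers such as the CLI).
#'
#' @param fasta Path to the input FASTA.
#' @param config A [pipeline_config] with both checkpoint paths set.
#' @return `data.frame` with one row per record: `id`,
#'   `is_multifunctional`, `score`, `main_classes` (comma-separated, empty
#'   for mono), `fallback` (logical), `note`. Attributes: `n_failed`,
#'   `fallback_rate`.
#' @export
run_pipeline <- function(fasta, config) {
  stopifnot(inherits(config, "pipeline_config"))
  bin_model <- load_model(config$binary_model_path)
  ml_model <- load_model(config$multilabel_model_path)
  vocabulary <- ml_model$domain_vocabulary
  if (is.null(vocabulary))
    vocabulary <- sprintf("PF%05d", seq_len(ml_model$domain_dim))
  records <- read_fasta(fasta)
  rows <- lapply(records, function(rec) {
    tryCatch({
      x <- encode_for_pipeline(rec, config, vocabulary)
      bin <- predict_is_multifunctional(x, bin_model, config$cutoff)
      if (bin$is_multifunctional) {
        pred <- predict_main_classes(x, ml_model)
        data.frame(id = rec$id, is_multifunctional = TRUE,
                   score = bin$score,
                   main_classes = paste(pred$members, collapse = ","),
                   fallback = pred$fallback_used,
                   note = "", stringsAsFactors = FALSE)
      } else {
        data.frame(id = rec$id, is_multifunctional = FALSE,
                   score = bin$score, main_classes = "",
                   fallback = FALSE,
                   note = "mono-functional: digit-level annotation delegated",
                   stringsAsFactors = FALSE)
      }
    }, error = function(e) {
      data.frame(id = rec$id, is_multifunctional = NA,
                 score = NA_real_, main_classes = "", fallback = FALSE,
                 note = paste0("ERROR: ", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  failed <- startsWith(out$note, "ERROR:")
  attr(out, "n_failed") <- sum(failed)
  multi <- !failed & !is.na(out$is_multifunctional) & out$is_multifunctional
  attr(out, "fallback_rate") <-
    if (any(multi)) mean(out$fallback[multi]) else 0
  out
}

split_indices <- function(ids, train_fraction, seed, run) {
  # pure function of (seed, run index, dataset ids): ids are ranked by a
  # seeded permutation so the same inputs always give the same split
  set.seed(seed + run * 10007L)
  n <- length(ids)
  perm <- sample.int(n)
  n_train <- max(1L, min(n - 1L, round(train_fraction * n)))
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[(n_train + 1L):n]))
}

#' Repeated-split evaluation of the multi-label level
#'
#' Runs `R` independent random train/test splits (70/30 by default). In
#' each split a fresh model is trained with the ranking loss, the adaptive
#' threshold is fitted on the training scores, the held-out instances are
#' predicted, and the full metric suite is computed. Reported are the mean
#' and standard deviation of every metric across splits.
#'
#' For testing the evaluation machinery independently of training,
#' `predict_fun` can replace the model: it receives the train and test
#' instance lists and must return the predicted label sets for the test
#' instances.
#'
#' @param ds A [sim_dataset] (or any list with `records`, `labels`,
#'   `domain_hits`, `vocabulary`).
#' @param config [model_config] for the per-split models.
#' @param R Number of repeated splits.
#' @param split Training fraction.
#' @param seed Base seed; split r uses a seed derived from `(seed, r)`.
#' @param predict_fun Optional `function(train, test)` returning a list of
#'   predicted label sets for `test`.
#' @return List with `summary` (data.frame: metric, mean, sd) and
#'   `reports` (per-split [metrics_report]s).
#' @export
evaluate_splits <- function(ds, config = model_config(), R = 30L,
                            split = 0.70, seed = 1L, predict_fun = NULL) {
  data <- encode_sim_dataset(ds)
  if (length(data) < 10L)
    stop("dataset too small for split evaluation (need >= 10 instances)")
  Q <- config$q_classes
  reports <- vector("list", R)
  for (r in seq_len(R)) {
    idx <- split_indices(vapply(ds$records, `[[`, "", "id"), split, seed, r)
    train <- data[idx$train]
    test <- data[idx$test]
    truths <- lapply(test, `[[`, "y")
    preds <- if (is.null(predict_fun)) {
      cfg <- config
      cfg$seed <- as.integer(config$seed + r)
      model <- build_model(cfg, domain_dim = length(ds$vocabulary))
      model <- train_model(model, train, loss = "bpmll", config = cfg)
      model <- calibrate_threshold(model, train)
      lapply(test, function(inst) predict_main_classes(inst$x, model))
    } else {
      predict_fun(train, test)
    }
    reports[[r]] <- metrics_report(preds, truths, Q)
  }
  vals <- sapply(metric_names, function(m)
    vapply(reports, `[[`, numeric(1), m))
  vals <- matrix(vals, nrow = R, dimnames = list(NULL, metric_names))
  list(summary = data.frame(metric = metric_names,
                            mean = colMeans(vals),
                            sd = apply(vals, 2, stats::sd),
                            row.names = NULL),
       reports = reports)
}
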