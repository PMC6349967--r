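fixture_dir <- pipeline_fixture()

fixture_config <- function(...) {
  pipeline_config(binary_model_path = file.path(fixture_dir, "bin.rds"),
                  multilabel_model_path = file.path(fixture_dir, "ml.rds"),
                  domains = "none", ...)
}

test_that("the binary level applies a strict decision cutoff", {
  bin <- load_model(file.path(fixture_dir, "bin.rds"))
  ds <- readRDS(file.path(fixture_dir, "ds.rds"))
  x <- encode_sim_dataset(ds)[[1]]$x
  out <- predict_is_multifunctional(x, bin)
  expect_type(out$is_multifunctional, "logical")
  expect_true(out$score > 0 && out$score < 1)
  expect_identical(out$is_multifunctional, out$score > 0.5)
  # boundary: a cutoff equal to the score decides mono (strict '>')
  out2 <- predict_is_multifunctional(x, bin, cutoff = out$score)
  expect_false(out2$is_multifunctional)
  ml <- load_model(file.path(fixture_dir, "ml.rds"))
  expect_error(predict_is_multifunctional(x, ml), "q_classes = 1")
})

test_that("main-class prediction composes scoring and thresholding", {
  ml <- load_model(file.path(fixture_dir, "ml.rds"))
  ds <- readRDS(file.path(fixture_dir, "ds.rds"))
  x <- encode_sim_dataset(ds)[[2]]$x
  p1 <- predict_main_classes(x, ml)
  p2 <- apply_threshold(forward(ml, x), ml$threshold)
  expect_identical(p1$members, p2$members)
  expect_identical(p1$members, predict_main_classes(x, ml)$members)
  expect_gte(length(p1$members), 1)  # fallback guarantees non-empty
  # the published worked example under a hand-built constant threshold
  s <- c(0.9, 0.8, 0.3, 0.1, 0.1, 0.1)
  expect_equal(apply_threshold(s, threshold_model(rep(0, 6), 0.55))$members,
               c(1L, 2L))
})

test_that("run_pipeline annotates every record exactly once", {
  out <- run_pipeline(file.path(fixture_dir, "data", "sequences.fasta"),
                      fixture_config())
  ds <- readRDS(file.path(fixture_dir, "ds.rds"))
  expect_equal(nrow(out), length(ds$records))
  expect_equal(out$id, vapply(ds$records, `[[`, "", "id"))
  expect_equal(attr(out, "n_failed"), 0)
  # routing exhaustiveness: each record is mono xor multi
  expect_true(all(out$is_multifunctional %in% c(TRUE, FALSE)))
  multi <- out$is_multifunctional
  expect_true(all(nzchar(out$main_classes[multi])))
  expect_true(all(out$main_classes[!multi] == ""))
  expect_true(all(grepl("delegated", out$note[!multi])))
  # determinism: identical rerun
  out2 <- run_pipeline(file.path(fixture_dir, "data", "sequences.fasta"),
                       fixture_config())
  expect_identical(out$main_classes, out2$main_classes)
  expect_identical(out$score, out2$score)
})

test_that("per-record failures are collected without aborting the run", {
  cfg <- fixture_config(pssm = "parsed",
                        pssm_dir = file.path(fixture_dir, "data", "pssm"))
  # corrupt one record's PSSM
  ds <- readRDS(file.path(fixture_dir, "ds.rds"))
  victim <- ds$records[[3]]$id
  pfile <- file.path(fixture_dir, "data", "pssm", paste0(victim, ".pssm"))
  orig <- readLines(pfile)
  writeLines(orig[1:5], pfile)
  withr::defer(writeLines(orig, pfile))
  out <- run_pipeline(file.path(fixture_dir, "data", "sequences.fasta"), cfg)
  expect_equal(attr(out, "n_failed"), 1)
  expect_match(out$note[out$id == victim], "ERROR")
  expect_true(all(!startsWith(out$note[out$id != victim], "ERROR")))
})

test_that("split evaluation is reproducible and validates its inputs", {
  ds <- readRDS(file.path(fixture_dir, "ds.rds"))
  oracle <- function(train, test)
    motif_oracle_predict(lapply(test, function(i)
      list(sequence = paste(AA_ALPHABET[max.col(i$x$one_hot)],
                            collapse = ""))),
      ds$truth$motifs)
  r1 <- evaluate_splits(ds, R = 2, seed = 3, predict_fun = oracle)
  r2 <- evaluate_splits(ds, R = 2, seed = 3, predict_fun = oracle)
  expect_identical(r1$summary, r2$summary)
  # the motif oracle is perfect on noiseless data: zero hamming, sd 0
  expect_equal(r1$summary$mean[r1$summary$metric == "hamming_loss"], 0)
  expect_equal(r1$summary$sd[r1$summary$metric == "subset_accuracy"], 0)
  expect_equal(r1$summary$mean[r1$summary$metric == "subset_accuracy"], 1)
  tiny <- generate_dataset(sim_spec(n = 5, seed = 1, length_range = c(30L, 40L)))
  expect_error(evaluate_splits(tiny, R = 1), "too small")
})

test_that("trained split evaluation returns a mean/sd table per metric", {
  ds <- readRDS(file.path(fixture_dir, "ds.rds"))
  cfg <- model_config(conv_filters = list(c(4L, 8L)), fc_widths = c(8L, 16L),
                      dropout = 0, epochs = 4L, seed = 11)
  res <- evaluate_splits(ds, config = cfg, R = 2, seed = 4)
  expect_equal(nrow(res$summary), 8)
  expect_true(all(res$summary$mean >= 0 & res$summary$mean <= 1))
  expect_length(res$reports, 2)
})

test_that("splits are pure functions of seed, run index and ids", {
  ids <- sprintf("S%03d", 1:40)
  a <- mlenz:::split_indices(ids, 0.7, 5L, 1L)
  b <- mlenz:::split_indices(ids, 0.7, 5L, 1L)
  expect_identical(a, b)
  c <- mlenz:::split_indices(ids, 0.7, 5L, 2L)
  expect_false(identical(a$train, c$train))
  expect_equal(length(a$train), 28)
  expect_equal(sort(c(a$train, a$test)), 1:40)
})
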