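small_cfg <- function(..., epochs = 3L, batch_size = 16L) {
  model_config(conv_filters = list(c(4L, 8L), c(6L, 8L)),
               fc_widths = c(16L, 32L), dropout = 0.2, epochs = epochs,
               batch_size = batch_size, ...)
}

random_encoded <- function(L, D, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seq <- paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
  r <- protein_record("x", seq)
  encode_record(r, vocabulary = sprintf("PF%05d", 1:D),
                hits = sprintf("PF%05d", sample(D, 2)))
}

test_that("config validation lists every violated field", {
  expect_error(model_config(q_classes = 0, learning_rate = -1),
               "q_classes.*learning_rate")
  expect_error(model_config(dropout = 1), "dropout")
  expect_s3_class(model_config(), "model_config")
})

test_that("the built network outputs Q scores in (0,1) for any input", {
  cfg <- small_cfg(q_classes = 6L)
  m <- build_model(cfg, domain_dim = 10)
  for (L in c(1, 5, 40, 500)) {
    s <- forward(m, random_encoded(L, 10, seed = L))
    expect_length(s, 6)
    expect_true(all(s > 0 & s < 1))
  }
})

test_that("initialization is deterministic in the seed", {
  x <- random_encoded(30, 10, seed = 99)
  m1 <- build_model(small_cfg(seed = 3), domain_dim = 10)
  m2 <- build_model(small_cfg(seed = 3), domain_dim = 10)
  expect_identical(forward(m1, x), forward(m2, x))
  m3 <- build_model(small_cfg(seed = 4), domain_dim = 10)
  expect_false(identical(forward(m1, x), forward(m3, x)))
})

test_that("forward is pure and invariant to batch composition", {
  m <- build_model(small_cfg(), domain_dim = 8)
  x <- random_encoded(25, 8, seed = 1)
  expect_identical(forward(m, x), forward(m, x))
  xs <- lapply(1:4, function(i) random_encoded(20 + i, 8, seed = i))
  sm <- score_matrix(m, xs)
  expect_equal(sm[2, ], forward(m, xs[[2]]))
})

test_that("dimension mismatches are rejected", {
  m <- build_model(small_cfg(), domain_dim = 8)
  x <- random_encoded(20, 12, seed = 2)
  expect_error(forward(m, x), "domain vector length")
})

test_that("training reduces the ranking loss on learnable synthetic data", {
  ds <- tiny_sim(n = 120, seed = 21, label_noise = 0,
                 length_range = c(30L, 60L))
  data <- encode_sim_dataset(ds)
  cfg <- small_cfg(seed = 7, epochs = 6L)
  m <- build_model(cfg, domain_dim = length(ds$vocabulary))
  m <- train_model(m, data, loss = "bpmll", config = cfg)
  expect_length(m$history, 6)
  expect_lt(m$history[6], m$history[1])
})

test_that("training is bit-reproducible under a fixed seed", {
  ds <- tiny_sim(n = 30, seed = 22, length_range = c(30L, 50L))
  data <- encode_sim_dataset(ds)
  cfg <- small_cfg(seed = 9, epochs = 2L)
  m1 <- train_model(build_model(cfg, 24), data, "bpmll", config = cfg)
  m2 <- train_model(build_model(cfg, 24), data, "bpmll", config = cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("ranking-loss training rejects degenerate label sets by index", {
  ds <- tiny_sim(n = 12, seed = 23, length_range = c(30L, 50L))
  data <- encode_sim_dataset(ds)
  data[[4]]$y <- 1:6
  cfg <- small_cfg(epochs = 1L)
  m <- build_model(cfg, 24)
  expect_error(train_model(m, data, "bpmll", config = cfg), "instance 4")
  # all-singleton label sets are fine when Q > 1
  data2 <- lapply(encode_sim_dataset(ds), function(i) { i$y <- 1L; i })
  expect_no_error(train_model(m, data2, "bpmll", config = cfg))
})

test_that("weighted binary cross-entropy trains the one-output level", {
  ds <- tiny_sim(n = 60, seed = 24, multi_fraction = 0.3,
                 length_range = c(30L, 50L))
  data <- encode_sim_dataset(ds, binary = TRUE)
  cfg <- small_cfg(q_classes = 1L, seed = 2, epochs = 4L)
  m <- build_model(cfg, 24)
  m <- train_model(m, data, loss = "weighted-binary", config = cfg)
  expect_lt(m$history[4], m$history[1])
  s <- forward(m, data[[1]]$x)
  expect_length(s, 1)
})

test_that("checkpoints round-trip bit-exactly with vocabulary and threshold", {
  ds <- tiny_sim(n = 25, seed = 25, length_range = c(30L, 50L))
  data <- encode_sim_dataset(ds)
  cfg <- small_cfg(seed = 6, epochs = 1L)
  m <- train_model(build_model(cfg, 24), data, "bpmll", config = cfg)
  m$domain_vocabulary <- ds$vocabulary
  m <- calibrate_threshold(m, data)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$params, m$params)
  expect_identical(m2$domain_vocabulary, ds$vocabulary)
  expect_equal(m2$threshold$w, m$threshold$w)
  x <- data[[1]]$x
  expect_identical(forward(m2, x), forward(m, x))
})

test_that("global-average pooling is an accepted alternative", {
  cfg <- small_cfg(pool = "global-average")
  m <- build_model(cfg, 8)
  s <- forward(m, random_encoded(30, 8, seed = 31))
  expect_true(all(s > 0 & s < 1))
})

test_that("max_len truncation caps the convolved length", {
  cfg <- small_cfg(max_len = 10L)
  m <- build_model(cfg, 8)
  long <- random_encoded(200, 8, seed = 32)
  short <- long
  short$one_hot <- short$one_hot[1:10, ]
  short$pssm <- short$pssm[1:10, ]
  expect_identical(forward(m, long), forward(m, short))
})
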