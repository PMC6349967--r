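# Lazily-built shared fixture for the pipeline tests: a small noiseless
# synthetic dataset written to disk plus trained binary and multi-label
# checkpoints. Built once per test session under tempdir().
pipeline_fixture <- local({
  dir <- NULL
  function() {
    if (!is.null(dir)) return(dir)
    d <- file.path(tempdir(), "mlenz-pipeline-fixture")
    if (!dir.exists(d)) {
      dir.create(d)
      spec <- sim_spec(n = 80, label_noise = 0, seed = 31,
                       length_range = c(30L, 60L), multi_fraction = 0.4)
      ds <- generate_dataset(spec)
      write_dataset(ds, file.path(d, "data"), pssm = TRUE)
      cfg <- model_config(conv_filters = list(c(4L, 8L), c(6L, 8L)),
                          fc_widths = c(16L, 32L), dropout = 0.1,
                          epochs = 10L, seed = 5)
      train <- encode_sim_dataset(ds)
      ml <- build_model(cfg, domain_dim = length(ds$vocabulary))
      ml <- train_model(ml, train, "bpmll", config = cfg)
      ml$domain_vocabulary <- ds$vocabulary
      ml <- calibrate_threshold(ml, train)
      save_model(ml, file.path(d, "ml.rds"))
      bcfg <- cfg; bcfg$q_classes <- 1L
      bin <- build_model(bcfg, domain_dim = length(ds$vocabulary))
      bin <- train_model(bin, encode_sim_dataset(ds, binary = TRUE),
                         "weighted-binary", config = bcfg)
      bin$domain_vocabulary <- ds$vocabulary
      save_model(bin, file.path(d, "bin.rds"))
      saveRDS(ds, file.path(d, "ds.rds"))
    }
    dir <<- d
    d
  }
})
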