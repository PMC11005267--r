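tiny_experiment <- function(seed = 1, out_dir = NULL,
                            models = default_model_registry()) {
  # two short records, small model, few epochs: a shape/determinism probe,
  # not a performance run
  recs <- list(synth_config(duration = 2, heart_rate = 70,
                            noise = list(noise_component("white", 0.05)),
                            seed = 11),
               synth_config(duration = 2, heart_rate = 90,
                            noise = list(noise_component("white", 0.05)),
                            seed = 12))
  experiment_config(recs, models = models,
                    embedding = embedding_config(m = 10),
                    training = train_config(epochs = 2, hidden_size = 4,
                                            learning_rate = 5e-3,
                                            batch_size = 128, seed = seed),
                    denoise_signal = FALSE, seed = seed, out_dir = out_dir)
}

test_that("experiment emits correctly shaped tables with exact averages", {
  out <- withr::local_tempdir()
  res <- suppressMessages(run_experiment(tiny_experiment(out_dir = out)))
  for (tab in list(res$rmse, res$mae, res$rmse_norm, res$mae_norm)) {
    expect_equal(dim(tab), c(3L, 3L))       # 2 records + average row
    expect_equal(tab$record_id[3], "average")
    for (mod in c("nested_lstm", "lstm"))
      expect_equal(tab[[mod]][3], mean(tab[[mod]][1:2]), tolerance = 1e-12)
  }
  expect_true(file.exists(file.path(out, "rmse.csv")))
  expect_true(file.exists(file.path(out, "mae.csv")))
  expect_true(file.exists(file.path(out, "summary.json")))
  # de-normalized and normalized tables differ by the per-record sd factor
  sd1 <- res$details[[1]]$norm_stats$sd
  expect_equal(res$rmse$nested_lstm[1],
               res$rmse_norm$nested_lstm[1] * sd1, tolerance = 1e-12)
})

test_that("experiments are reproducible under the global seed", {
  r1 <- suppressMessages(run_experiment(tiny_experiment(seed = 5)))
  r2 <- suppressMessages(run_experiment(tiny_experiment(seed = 5)))
  expect_identical(r1$rmse, r2$rmse)
  expect_identical(r1$mae, r2$mae)
})

test_that("a perfect mock predictor produces a zero error column", {
  # model whose readout copies the last window sample: on a constant-free
  # one-step task with targets equal to the last input this is exact; here
  # we instead inject targets==prediction by predicting the previous sample
  # of a persistence-friendly series
  persistence <- function(input_size, hidden_size, seed) {
    p <- ecgforecast:::.map_leaves(function(x) x * 0,
                                   lstm_params(input_size, 1L, seed = seed))
    p            # all-zero parameters: predicts 0 everywhere
  }
  recs <- list(ecg_record(rep(c(1e-12, -1e-12), 300), 250, "flatline"))
  cfg <- experiment_config(recs, models = list(zero = persistence),
                           embedding = embedding_config(m = 5),
                           training = train_config(epochs = 0,
                                                   hidden_size = 1),
                           denoise_signal = FALSE, seed = 1)
  res <- suppressMessages(run_experiment(cfg))
  # targets are +-1e-12 in mV, i.e. 0 up to float formatting: the zero
  # predictor is exact at mV scale within 1e-10
  expect_lt(res$rmse$zero[1], 1e-10)
})

test_that("relative reduction reproduces the printed comparison arithmetic", {
  # published average RMSE values: nested 0.0701 vs SVM 0.1802, ESN 0.1192,
  # LSTM 0.0882, Bi-LSTM 0.0854 -> 61.1 / 41.2 / 20.5 / 17.9 percent
  expect_equal(round(relative_reduction(0.0701, 0.1802), 1), 61.1)
  expect_equal(round(relative_reduction(0.0701, 0.1192), 1), 41.2)
  expect_equal(round(relative_reduction(0.0701, 0.0882), 1), 20.5)
  expect_equal(round(relative_reduction(0.0701, 0.0854), 1), 17.9)
  expect_equal(relative_reduction(3, 3), 0)
  expect_equal(relative_reduction(0, 5), 100)
  expect_error(relative_reduction(1, 0), "nonzero")
})

test_that("config validation fails fast", {
  expect_error(experiment_config(list()), "at least one")
  expect_error(experiment_config(list("no/such/file.csv")), "not found")
  expect_error(experiment_config(list(synth_config()),
                                 models = list(function(...) NULL)),
               "named list")
})
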