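test_that("a 60 s trial at 128 Hz sampled every 0.25 s yields 240 steps", {
  fseq <- factor_sequence(matrix(rnorm(3 * 60 * 128), 3), 128,
                          trial_id = "t1")
  s <- build_sequences(fseq, list(klass = "positive"), step_seconds = 0.25)
  expect_equal(nrow(s$steps), 240)
  expect_equal(ncol(s$steps), 3)
  expect_identical(s$label, "positive")
})

test_that("a one-sample step returns the full factor sequence", {
  fseq <- factor_sequence(matrix(rnorm(2 * 100), 2), 128)
  s <- build_sequences(fseq, list(klass = "negative"), step_seconds = 1 / 128)
  expect_equal(nrow(s$steps), 100)
  expect_equal(s$steps, t(fseq$factors), tolerance = 0)
})

test_that("excluded trials and over-long steps are rejected", {
  fseq <- factor_sequence(matrix(rnorm(2 * 64), 2), 128)
  expect_error(build_sequences(fseq, list(klass = "excluded")), "excluded")
  expect_error(build_sequences(fseq, list(klass = "positive"),
                               step_seconds = 1), "step longer")
})

test_that("every emitted sequence carries its trial's label", {
  for (kl in c("positive", "negative")) {
    fseq <- factor_sequence(matrix(rnorm(2 * 256), 2), 128, trial_id = "tX")
    s <- build_sequences(fseq, list(klass = kl), 0.25)
    expect_identical(s$label, kl)
    expect_identical(s$trial_id, "tX")
  }
})

test_that("the default LSTM configuration mirrors the reference architecture", {
  cfg <- lstm_config()
  expect_equal(cfg$lstm_units, 200)
  expect_equal(cfg$dense_units, 100)
  expect_equal(cfg$batch, 50)
  expect_equal(cfg$dense_activation, "relu")
})

test_that("the LSTM memorizes a tiny separable sequence set (training F1 = 1)", {
  samples <- make_separable_sequences(n_per_class = 6, seed = 90)
  clf <- train_lstm(samples, lstm_config(lstm_units = 16, dense_units = 8,
                                         batch = 4, epochs = 60,
                                         dropout_rate = 0.2, seed = 1))
  pred <- predict(clf, samples)
  truth <- vapply(samples, function(s) s$label, character(1))
  expect_equal(f1_score(pred$labels, truth)$f1, 1.0)
  expect_lte(tail(clf$losses, 1), 0.95 * clf$losses[1])
})

test_that("softmax probabilities are normalized and inference is deterministic", {
  samples <- make_separable_sequences(n_per_class = 4, seed = 91)
  clf <- train_lstm(samples, lstm_config(lstm_units = 8, dense_units = 4,
                                         batch = 4, epochs = 10, seed = 2))
  p1 <- predict(clf, samples)
  p2 <- predict(clf, samples)
  expect_identical(p1$probs, p2$probs)
  expect_equal(dim(p1$probs), c(8L, 2L))
  expect_lt(max(abs(rowSums(p1$probs) - 1)), 1e-6)
})

test_that("single-class input and dimension mismatches are rejected", {
  samples <- make_separable_sequences(n_per_class = 3, seed = 92)
  onecls <- samples[vapply(samples, function(s) s$label, character(1)) ==
                      "positive"]
  expect_error(train_lstm(onecls), "single class")
  clf <- train_lstm(samples, lstm_config(lstm_units = 4, dense_units = 4,
                                         batch = 4, epochs = 3, seed = 1))
  wrong <- make_separable_sequences(n_per_class = 2, m = 3, seed = 93)
  expect_error(predict(clf, wrong), "does not match")
})

test_that("decoder-encoded factors of class-modulated trials are learnable", {
  # within-subject check: one subject, held-out trials, known amplitude effect
  cfg <- synthetic_config(n_subjects = 1, trials_per_subject = 60,
                          trial_seconds = 10, amplitude_ratio = 2,
                          master_seed = 21)
  ds <- make_labeled_dataset(cfg)
  recs <- zscore_by_subject(ds$recordings)
  train_idx <- 1:40; test_idx <- 41:60
  pooled <- do.call(rbind, lapply(recs[train_idx], function(r) t(r$data)))
  v <- fit_vae(pooled, 3, epochs = 10, seed = 1)
  mk <- function(i) build_sequences(encode(v, recs[[i]]),
                                    list(klass = ds$labels$klass[i]), 0.25)
  train_s <- lapply(train_idx, mk)
  test_s <- lapply(test_idx, mk)
  std <- standardize_sequences(train_s)
  test_s <- eegfactors:::standardize_sequences_apply(test_s, std$center,
                                                     std$scale)
  clf <- train_lstm(std$samples,
                    lstm_config(lstm_units = 32, dense_units = 16, batch = 10,
                                epochs = 80, seed = 3))
  pred <- predict(clf, test_s)
  truth <- ds$labels$klass[test_idx]
  expect_gte(f1_score(pred$labels, truth)$f1, 0.9)
})

test_that("sequence standardization uses training statistics only", {
  samples <- make_separable_sequences(n_per_class = 5, seed = 94)
  std <- standardize_sequences(samples)
  allsteps <- do.call(rbind, lapply(std$samples, function(s) s$steps))
  expect_lt(max(abs(colMeans(allsteps))), 1e-9)
  expect_lt(max(abs(apply(allsteps, 2, sd) - 1)), 1e-6)
  other <- make_separable_sequences(n_per_class = 2, seed = 95)
  mapped <- eegfactors:::standardize_sequences_apply(other, std$center,
                                                     std$scale)
  back <- sweep(sweep(mapped[[1]]$steps, 2, std$scale, "*"), 2, std$center,
                "+")
  expect_equal(back, other[[1]]$steps, tolerance = 1e-12)
})
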