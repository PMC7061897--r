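test_that("Pearson correlation handles the canonical cases", {
  set.seed(150)
  x <- rnorm(50)
  expect_equal(pearson_r(x, x), 1.0, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x), -1.0, tolerance = 1e-12)
  # worked 3-point example: r = 9 / sqrt(84)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), 0.9820, tolerance = 1e-4)
  expect_warning(r0 <- pearson_r(rep(1, 10), rnorm(10)), "constant")
  expect_identical(r0, 0)
  expect_error(pearson_r(1:3, 1:4), "lengths differ")
})

test_that("Pearson correlation is invariant under positive affine maps", {
  set.seed(151)
  x <- rnorm(100); y <- rnorm(100)
  r <- pearson_r(x, y)
  expect_lt(abs(pearson_r(3 * x + 7, y) - r), 1e-12)
  expect_lt(abs(pearson_r(x, 0.2 * y - 5) - r), 1e-12)
})

test_that("F1 matches direct evaluation and guards zero denominators", {
  expect_equal(f1_score(c("positive", "negative"), c("positive", "negative"))$f1, 1.0)
  expect_warning(
    z <- f1_score(rep("negative", 4), c("positive", "positive", "negative", "negative")),
    "no positive predictions")
  expect_identical(z$f1, 0)
  # TP = 3, FP = 1, FN = 1 -> precision = recall = F1 = 0.75
  pred <- c(rep("positive", 4), "negative", "negative")
  true <- c(rep("positive", 3), "negative", "positive", "negative")
  sc <- f1_score(pred, true)
  expect_equal(sc$precision, 0.75)
  expect_equal(sc$recall, 0.75)
  expect_equal(sc$f1, 0.75)
  expect_error(f1_score(c("positive", "weird"), c("positive", "negative")),
               "unknown predicted label")
})

test_that("F1 agrees with brute-force confusion counting on all length-4 patterns", {
  labs <- c("positive", "negative")
  grid <- expand.grid(p1 = labs, p2 = labs, p3 = labs, p4 = labs,
                      t1 = labs, t2 = labs, t3 = labs, t4 = labs,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    pred <- unlist(grid[i, 1:4], use.names = FALSE)
    true <- unlist(grid[i, 5:8], use.names = FALSE)
    sc <- suppressWarnings(f1_score(pred, true))
    # independent oracle: enumerate the four outcome types directly
    tp <- sum(pred == "positive" & true == "positive")
    fp <- sum(pred == "positive" & true == "negative")
    fn <- sum(pred == "negative" & true == "positive")
    f1_direct <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    expect_equal(sc$f1, f1_direct, tolerance = 1e-12)
  }
})

test_that("rating binarization follows the over/under-five rule", {
  expect_identical(label_binarize(7), "positive")
  expect_identical(label_binarize(3), "negative")
  expect_identical(label_binarize(5), "excluded")
  expect_identical(label_binarize(5, ties = "negative"), "negative")
  expect_identical(label_binarize(c(5.1, 4.9)), c("positive", "negative"))
  expect_error(label_binarize(0.5), "\\[1, 9\\]")
  expect_identical(label_binarize("positive", scheme = "predefined"),
                   "positive")
})

test_that("reconstruction reports are internally consistent", {
  fx <- make_mixture(n = 6, m = 3, t = 3000, noise_sd = 0.2, seed = 152)
  p <- fit_pca(fx$X, 6)
  rep6 <- reconstruction_report(p, list(fx$recz))
  expect_lt(abs(rep6$mean_r - 1), 1e-8)            # full-rank projection
  p3 <- fit_pca(fx$X, 3)
  rep3 <- reconstruction_report(p3, list(fx$recz))
  expect_equal(rep3$mean_r, mean(rep3$channels), tolerance = 1e-12)
  expect_named(rep3$channels, fx$recz$channel_labels)
  path <- file.path(tempdir(), "heat.json")
  write_heatmap_json(rep3, path)
  hm <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(unname(unlist(hm)), unname(rep3$channels), tolerance = 1e-12)
})

test_that("LOSO produces one fold per subject with exact mean bookkeeping", {
  cfg <- synthetic_config(n_subjects = 2, trials_per_subject = 8,
                          trial_seconds = 4, master_seed = 31)
  ds <- make_labeled_dataset(cfg)
  cv <- loso_cv(ds, decoder = "pca", m = 3, step_seconds = 0.25,
                lstm = lstm_config(lstm_units = 8, dense_units = 4,
                                   batch = 4, epochs = 8), seed = 5)
  expect_length(cv$per_subject, 2)
  expect_named(cv$per_subject, c("s01", "s02"))
  expect_equal(cv$mean_f1, mean(cv$per_subject), tolerance = 1e-12)
  expect_length(cv$confusion, 2)
})

test_that("folds whose held-out subject is single-class are skipped with a warning", {
  cfg <- synthetic_config(n_subjects = 3, trials_per_subject = 6,
                          trial_seconds = 4, master_seed = 32)
  ds <- make_labeled_dataset(cfg)
  ds$labels$klass[ds$labels$subject_id == "s03"] <- "positive"
  expect_warning(
    cv <- loso_cv(ds, decoder = "pca", m = 2, step_seconds = 0.25,
                  lstm = lstm_config(lstm_units = 8, dense_units = 4,
                                     batch = 4, epochs = 5), seed = 6),
    "single class")
  expect_identical(cv$skipped, "s03")
  expect_setequal(names(cv$per_subject), c("s01", "s02"))
})

test_that("a constant predictor's F1 matches its closed form from class counts", {
  # with n_pos positives out of n, predicting all-positive gives
  # precision = n_pos / n, recall = 1, F1 = 2 n_pos / (n + n_pos)
  true <- c(rep("positive", 3), rep("negative", 5))
  sc <- f1_score(rep("positive", 8), true)
  expect_equal(sc$f1, 2 * 3 / (8 + 3), tolerance = 1e-12)
})
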