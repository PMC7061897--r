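test_that("Hjorth activity is the plain variance and guards constants", {
  set.seed(100)
  x <- rnorm(512)
  h <- hjorth(x)
  expect_equal(unname(h["activity"]), stats::var(x), tolerance = 1e-12)
  expect_warning(hc <- hjorth(rep(3, 100)), "constant")
  expect_identical(unname(hc), c(0, 0, 0))
})

test_that("white noise is more mobile than a slow sine (10 seeds)", {
  fs <- 128
  t <- seq(0, 4, by = 1 / fs)[-1]
  sine <- sin(2 * pi * 2 * t)
  ok <- all(vapply(1:10, function(s) {
    set.seed(110 + s)
    hjorth(rnorm(length(t)))["mobility"] > hjorth(sine)["mobility"]
  }, logical(1)))
  expect_true(ok)
})

test_that("time-frequency features handle degenerate and analytic cases", {
  fs <- 128
  const <- rep(2, 512)
  tf <- suppressWarnings(tfd_features(const, fs))
  expect_equal(unname(tf["variance"]), 0)
  expect_equal(unname(tf["msv"]), 4)
  expect_equal(unname(tf["max_psd_freq"]), 0)   # power concentrated at DC
  # unit 10 Hz sine: periodogram peak within one bin of 10 Hz
  t <- seq(0, 4, by = 1 / fs)[-1]
  tf2 <- tfd_features(sin(2 * pi * 10 * t), fs)
  expect_lt(abs(tf2["max_psd_freq"] - 10), fs / length(t) + 1e-9)
  # +/-1 square wave: mean square value exactly 1
  sq <- rep(c(1, -1), each = 32, times = 8)
  expect_equal(unname(tfd_features(sq, fs)["msv"]), 1.0)
})

test_that("permutation entropy is zero for strictly monotone series", {
  expect_identical(permutation_entropy(1:100), 0)
  expect_identical(permutation_entropy(seq(5, 1, length.out = 50)), 0)
})

test_that("NDS features guard degenerate input and rank noise above tones", {
  out <- suppressWarnings(nds_features(rep(1, 300), 128))
  expect_identical(unname(out), rep(0, 9))
  expect_equal(unname(out["apen"]), 0)
  fs <- 128
  t <- seq(0, 4, by = 1 / fs)[-1]
  sine <- sin(2 * pi * 10 * t)
  ok <- all(vapply(1:10, function(s) {
    set.seed(120 + s)
    spectral_entropy(rnorm(length(t)), fs) > spectral_entropy(sine, fs)
  }, logical(1)))
  expect_true(ok)
  v <- nds_features(rnorm(512), fs)
  expect_length(v, 9)
  expect_true(all(is.finite(v)))
})

test_that("asymmetry features are zero for mirrored hemispheres", {
  set.seed(130)
  x <- matrix(rnorm(28 * 400), 28)
  reg <- default_pair_registry()
  rec <- recording(rbind(x[1:14, ], x[1:14, ]),
                   c(reg$left, reg$right), 128)
  av <- bhaa_features(rec, reg)
  expect_identical(unname(av), rep(0, 14))
  expect_identical(names(av)[1], "Fp1Fp2")
})

test_that("doubling the left amplitude yields log(4) asymmetry (power oracle)", {
  set.seed(131)
  base <- matrix(rnorm(14 * 500), 14)
  reg <- default_pair_registry()
  rec <- recording(rbind(2 * base, base), c(reg$left, reg$right), 128)
  av <- bhaa_features(rec, reg)
  expect_lt(max(abs(av - log(4))), 1e-10)
  # direct power computation on the first pair
  p1 <- mean((2 * base[1, ])^2); p2 <- mean(base[1, ]^2)
  expect_equal(unname(av[1]), log(p1 / p2), tolerance = 1e-12)
})

test_that("missing registry electrodes raise a named validation error", {
  rec <- recording(matrix(rnorm(300), 3), c("Fp1", "Fp2", "Cz"), 128)
  expect_error(bhaa_features(rec, default_pair_registry()), "AF3")
})

test_that("the registry holds the canonical 14 pairs", {
  reg <- default_pair_registry()
  expect_equal(nrow(reg), 14)
  expect_identical(reg$left[1:2], c("Fp1", "AF3"))
  expect_identical(reg$right[1:2], c("Fp2", "AF4"))
})

test_that("feature vectors have length 72 n + 56 with unique names, deterministically", {
  set.seed(132)
  rec <- recording(matrix(rnorm(32 * 512), 32), standard_montage(32), 128,
                   trial_id = "t1")
  nds_args <- list(max_points = 120)
  v1 <- feature_vector(rec, nds_args = nds_args)
  expect_length(v1, 72 * 32 + 56)
  expect_false(anyDuplicated(names(v1)) > 0)
  expect_true(all(is.finite(v1)))
  v2 <- feature_vector(rec, nds_args = nds_args)
  expect_identical(v1, v2)
})

test_that("channel permutation permutes features only up to their names", {
  set.seed(133)
  reg <- default_pair_registry()
  labs <- c(reg$left, reg$right)
  rec <- recording(matrix(rnorm(28 * 512), 28), labs, 128)
  perm <- sample(28)
  rec_p <- recording(rec$data[perm, ], labs[perm], 128)
  nds_args <- list(max_points = 100)
  v <- feature_vector(rec, nds_args = nds_args)
  vp <- feature_vector(rec_p, nds_args = nds_args)
  expect_setequal(names(v), names(vp))
  expect_equal(v[names(vp)], vp, tolerance = 1e-10)
})
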