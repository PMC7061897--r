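toy_grbm <- function(W, a, b, sigma = NULL) {
  n <- length(a); m <- length(b)
  structure(list(W = matrix(W, n, m), a = a, b = b,
                 sigma = sigma %||% rep(1, n), n = n, m = m, cd_k = 1,
                 losses = numeric(0)),
            class = "GRBMModel")
}

test_that("zero weights and biases give P(h = 1 | x) = 1/2 everywhere", {
  g <- toy_grbm(rep(0, 6), rep(0, 3), rep(0, 2))
  X <- matrix(rnorm(12), 4, 3)
  expect_true(all(grbm_hidden_prob(g, X) == 0.5))
})

test_that("hidden conditionals match exhaustive Boltzmann enumeration", {
  # 2 visible, 2 hidden toy: marginalize exp(-E(x, h)) over all 4 hidden
  # states and compare P(h_j = 1 | x) with the logistic form
  set.seed(70)
  g <- toy_grbm(c(0.3, -0.2, 0.15, 0.4), a = c(0.1, -0.3), b = c(0.2, -0.1))
  hidden_states <- as.matrix(expand.grid(h1 = 0:1, h2 = 0:1))
  for (trial in 1:5) {
    x <- rnorm(2)
    wts <- apply(hidden_states, 1, function(h) exp(-grbm_energy(g, x, h)))
    wts <- wts / sum(wts)
    p_enum <- c(sum(wts[hidden_states[, 1] == 1]),
                sum(wts[hidden_states[, 2] == 1]))
    p_formula <- drop(grbm_hidden_prob(g, matrix(x, 1)))
    expect_lt(max(abs(p_enum - p_formula)), 1e-10)
  }
})

test_that("hidden conditionals match enumeration on a 3-hidden-unit toy", {
  set.seed(71)
  g <- toy_grbm(rnorm(3) * 0.3, a = 0.2, b = rnorm(3) * 0.2)
  hs <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  x <- 0.7
  wts <- apply(hs, 1, function(h) exp(-grbm_energy(g, x, h)))
  wts <- wts / sum(wts)
  p_enum <- vapply(1:3, function(j) sum(wts[hs[, j] == 1]), numeric(1))
  expect_lt(max(abs(p_enum - drop(grbm_hidden_prob(g, matrix(x, 1))))), 1e-10)
})

test_that("CD-1 reduces reconstruction error from epoch 1 to epoch 10", {
  fx <- make_mixture(n = 8, m = 3, t = 8000, noise_sd = 0.2, seed = 72)
  ok <- sum(vapply(1:10, function(s) {
    g <- fit_grbm(fx$X, 3, epochs = 10, seed = s)
    g$losses[10] <= g$losses[1]
  }, logical(1)))
  expect_gte(ok, 9)
})

test_that("non-positive visible scales are rejected", {
  fx <- make_mixture(n = 4, m = 2, t = 500, seed = 73)
  expect_error(fit_grbm(fx$X, 2, sigma = c(1, 1, 0, 1)), "sigma")
})

test_that("zero-epoch unrolling reproduces the mean-field reconstruction exactly", {
  fx <- make_mixture(n = 6, m = 3, t = 3000, noise_sd = 0.1, seed = 74)
  g <- fit_grbm(fx$X, 3, epochs = 3, seed = 1)
  ae0 <- grbm_unroll_finetune(g, fx$X, epochs = 0)
  expect_equal(dim(ae0$W1), c(3L, 6L))
  expect_equal(dim(ae0$W2), c(6L, 3L))
  direct <- grbm_visible_mean(g, grbm_hidden_prob(g, fx$X))
  via_ae <- eegfactors:::ae_forward_out(ae0, eegfactors:::ae_forward_hidden(ae0, fx$X))
  expect_lt(max(abs(direct - via_ae)), 1e-12)
})

test_that("fine-tuning lowers training reconstruction error below the unrolled start", {
  fx <- make_mixture(n = 8, m = 3, t = 8000, noise_sd = 0.2, seed = 75)
  g <- fit_grbm(fx$X, 3, epochs = 10, seed = 1)
  ae0 <- grbm_unroll_finetune(g, fx$X, epochs = 0)
  aef <- grbm_unroll_finetune(g, fx$X, epochs = 10, seed = 1)
  mse <- function(model) {
    H <- eegfactors:::ae_forward_hidden(model, fx$X)
    mean((eegfactors:::ae_forward_out(model, H) - fx$X)^2)
  }
  expect_lte(mse(aef), mse(ae0))
})

test_that("fine-tuning improves reconstruction correlation in most seeds", {
  ok <- sum(vapply(1:10, function(s) {
    fx <- make_mixture(n = 8, m = 3, t = 8000, noise_sd = 0, seed = 500 + s)
    g <- fit_grbm(fx$X, 3, epochs = 10, seed = s)
    r0 <- mean_recon_r(grbm_unroll_finetune(g, fx$X, epochs = 0), fx$recz)
    rf <- mean_recon_r(grbm_unroll_finetune(g, fx$X, epochs = 10, lr = 0.02,
                                            seed = s), fx$recz)
    rf > r0
  }, logical(1)))
  expect_gte(ok, 8)
})

test_that("GRBM encoding returns hidden conditional means", {
  fx <- make_mixture(n = 6, m = 2, t = 1000, noise_sd = 0.1, seed = 76)
  g <- fit_grbm(fx$X, 2, epochs = 2, seed = 3)
  fs <- encode(g, fx$recz)
  expect_equal(dim(fs$factors), c(2L, 1000L))
  expect_true(all(fs$factors > 0 & fs$factors < 1))
  expect_equal(fs$factors, t(grbm_hidden_prob(g, fx$X)), tolerance = 0)
})
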