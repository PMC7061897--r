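test_that("source generation is bit-deterministic given the seed", {
  mm <- make_mixture(seed = 10)$mm
  expect_identical(generate_sources(mm, 500, seed = 3),
                   generate_sources(mm, 500, seed = 3))
})

test_that("an ar2 source peaks at its design frequency (periodogram oracle)", {
  mm <- mixing_model(diag(1),
                     list(list(kind = "ar2", freq_hz = 10,
                               pole_radius = 0.97, scale = 1)), 0, 128)
  x <- as.numeric(generate_sources(mm, 16384, seed = 7))
  pg <- stats::spec.pgram(stats::ts(x, frequency = 128), plot = FALSE,
                          taper = 0, span = 5)
  peak <- pg$freq[which.max(pg$spec)]
  expect_lt(abs(peak - 10), 1)
})

test_that("independent laplace sources are empirically uncorrelated", {
  mm <- mixing_model(diag(2),
                     rep(list(list(kind = "laplace_iid", scale = 1)), 2),
                     0, 128)
  ok <- sum(vapply(1:10, function(s) {
    S <- generate_sources(mm, 10000, seed = 100 + s)
    abs(stats::cor(S[1, ], S[2, ])) <= 0.1
  }, logical(1)))
  expect_gte(ok, 9)
})

test_that("identity mixing with zero noise returns the sources exactly", {
  mm <- mixing_model(diag(3), default_source_specs(3), 0, 128)
  S <- generate_sources(mm, 400, seed = 1)
  rec <- mix(S, mm)
  expect_equal(rec$data, S, tolerance = 0)
})

test_that("noiseless channels equal the mixing-weighted source sums", {
  fx <- make_mixture(n = 8, m = 3, t = 2000, noise_sd = 0, seed = 20)
  expect_lt(max(abs(fx$rec$data - fx$mm$M %*% fx$S)), 1e-10)
})

test_that("the empirical noise sd matches the configured level", {
  fx <- make_mixture(n = 4, m = 2, t = 50000, noise_sd = 0.5, seed = 30)
  resid <- fx$rec$data - fx$mm$M %*% fx$S
  expect_lt(abs(stats::sd(resid) - 0.5) / 0.5, 0.05)
})

test_that("noiseless recordings lie in the column space of M", {
  fx <- make_mixture(n = 8, m = 3, t = 1000, noise_sd = 0, seed = 40)
  Q <- qr.Q(qr(fx$mm$M))
  resid <- fx$rec$data - Q %*% (t(Q) %*% fx$rec$data)
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("dataset generation is balanced, complete and reproducible", {
  cfg <- synthetic_config(n_subjects = 4, trials_per_subject = 10,
                          trial_seconds = 2, master_seed = 5)
  ds <- make_labeled_dataset(cfg)
  expect_length(ds$recordings, 40)
  expect_equal(nrow(ds$labels), 40)
  expect_equal(unname(table(ds$labels$klass)["positive"]), 20,
               ignore_attr = TRUE)
  ds2 <- make_labeled_dataset(cfg)
  expect_identical(ds$recordings[[17]]$data, ds2$recordings[[17]]$data)
  expect_identical(ds$labels, ds2$labels)
})

test_that("the class effect raises modulated-source band power in positive trials", {
  cfg <- synthetic_config(n_subjects = 2, trials_per_subject = 20,
                          trial_seconds = 5, amplitude_ratio = 2,
                          master_seed = 8)
  ds <- make_labeled_dataset(cfg)
  # oracle: project each trial back through the true pseudo-inverse and
  # measure the modulated source's variance
  subj_ids <- unique(ds$labels$subject_id)
  pw <- vapply(seq_along(ds$recordings), function(i) {
    r <- ds$recordings[[i]]
    M <- ds$manifest$models[[match(r$subject_id, subj_ids)]]$M
    Shat <- pracma::pinv(M) %*% r$data
    stats::var(Shat[ds$manifest$modulated_source, ])
  }, numeric(1))
  pos <- pw[ds$labels$klass == "positive"]
  neg <- pw[ds$labels$klass == "negative"]
  expect_lt(stats::t.test(pos, neg, alternative = "greater")$p.value, 0.01)
})

test_that("an oracle classifier on the true sources recovers the labels", {
  cfg <- synthetic_config(master_seed = 11, trial_seconds = 10)
  ds <- make_labeled_dataset(cfg)
  subj_ids <- unique(ds$labels$subject_id)
  lv <- vapply(seq_along(ds$recordings), function(i) {
    r <- ds$recordings[[i]]
    M <- ds$manifest$models[[match(r$subject_id, subj_ids)]]$M
    Shat <- pracma::pinv(M) %*% r$data
    log(stats::var(Shat[ds$manifest$modulated_source, ]))
  }, numeric(1))
  kl <- ds$labels$klass
  thr <- mean(c(mean(lv[kl == "positive"]), mean(lv[kl == "negative"])))
  pred <- ifelse(lv > thr, "positive", "negative")
  expect_gte(f1_score(pred, kl)$f1, 0.95)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n = 4, m = 6), "m > n")
  expect_error(mixing_model(cbind(1:3, 2 * (1:3)), default_source_specs(2)),
               "rank")
  set.seed(1)
  mm <- mixing_model(matrix(rnorm(6), 3, 2),
                     list(list(kind = "nope"), list(kind = "nope")), 0, 128)
  expect_error(generate_sources(mm, 10), "unknown source kind")
  expect_error(mix(matrix(0, 2, 10), make_mixture(seed = 2)$mm),
               "config error")
})

test_that("written datasets carry a ground-truth manifest", {
  cfg <- synthetic_config(n_subjects = 2, trials_per_subject = 2,
                          trial_seconds = 1, master_seed = 3)
  ds <- make_labeled_dataset(cfg)
  dir <- file.path(tempdir(), "dsout")
  write_dataset(ds, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$amplitude_ratio, 2)
  expect_length(man$mixing_matrices, 2)
  M1 <- man$mixing_matrices[[1]]
  expect_equal(c(M1$nrow, M1$ncol), c(8, 3))
  expect_length(M1$values, 24)
  ds_mat <- matrix(unlist(M1$values), M1$nrow, M1$ncol)
  expect_equal(ds_mat, ds$manifest$models[[1]]$M, tolerance = 1e-12)
})
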