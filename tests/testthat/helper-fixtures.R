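# Shared fixture builders: all data generated in code at test time.

# one noisy (or noiseless) linear mixture with z-scored channels
make_mixture <- function(n = 8, m = 3, t = 8000, noise_sd = 0, seed = 1,
                         specs = NULL, fs = 128) {
  set.seed(seed)
  M <- matrix(stats::rnorm(n * m), n, m)
  mm <- mixing_model(M, specs %||% default_source_specs(m), noise_sd, fs)
  S <- generate_sources(mm, t, seed = seed + 1)
  rec <- mix(S, mm, seed = seed + 2)
  recz <- zscore_per_channel(rec)
  list(mm = mm, S = S, rec = rec, recz = recz, X = t(recz$data))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean per-channel reconstruction r for a model on one recording
mean_recon_r <- function(model, recz) {
  reconstruction_report(model, list(recz))$mean_r
}

# tiny labeled sequence fixture with a location-separated class effect,
# for classifier memorization/shape tests
make_separable_sequences <- function(n_per_class = 6, steps = 12, m = 2,
                                     shift = 2, seed = 1) {
  set.seed(seed)
  out <- list()
  k <- 0
  for (cl in c("negative", "positive")) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1
      mu <- if (cl == "positive") shift else 0
      out[[k]] <- structure(
        list(steps = matrix(stats::rnorm(steps * m, mean = mu), steps, m),
             label = cl, subject_id = sprintf("s%02d", i), trial_id = as.character(k)),
        class = "SequenceSample")
    }
  }
  out
}
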