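#' Define a ground-truth linear mixing model
#'
#' The simulator's generative assumption is the same linear model the
#' decoders try to invert: observed channels are a mixing-matrix-weighted sum
#' of independent latent sources plus i.i.d. Gaussian sensor noise,
#' `E = M S + noise`. Sources are non-Gaussian or temporally structured by
#' default so that blind source separation is identifiable.
#'
#' @param M numeric `n x m` mixing matrix (channels by sources); must have
#'   full column rank.
#' @param source_specs list of `m` specs, each a list with `kind` one of
#'   `"ar2"` (second-order autoregressive process with a spectral peak;
#'   params `freq_hz`, `pole_radius`, `scale`), `"band_sine"` (sinusoid with
#'   random phase plus small jitter; params `freq_hz`, `scale`), or
#'   `"laplace_iid"` (heavy-tailed i.i.d.; param `scale`).
#' @param noise_sd standard deviation of the additive channel noise (>= 0).
#' @param fs sampling rate in Hz.
#' @return An object of class `"MixingModel"`.
#' @examples
#' mm <- mixing_model(matrix(rnorm(8 * 3), 8), default_source_specs(3), 0.1, 128)
#' @export
mixing_model <- function(M, source_specs, noise_sd = 0, fs = 128) {
  M <- as.matrix(M)
  n <- nrow(M); m <- ncol(M)
  if (m > n) stop("config error: more sources (m) than channels (n)")
  if (length(source_specs) != m)
    stop("config error: need one source spec per column of M")
  if (noise_sd < 0) stop("config error: noise_sd must be >= 0")
  if (qr(M)$rank < m) stop("config error: M is column-rank deficient")
  structure(list(M = M, source_specs = source_specs,
                 noise_sd = as.numeric(noise_sd), fs = as.numeric(fs),
                 n = n, m = m),
            class = "MixingModel")
}

#' Default source specifications
#'
#' A conventional trio repeated to length `m`: an alpha-band AR(2) source
#' (10 Hz peak), a theta-band sinusoid (6 Hz) and a heavy-tailed
#' `laplace_iid` source.
#'
#' @param m number of sources.
#' @return A list of `m` source specs for [mixing_model()].
#' @export
default_source_specs <- function(m) {
  base <- list(
    list(kind = "ar2", freq_hz = 10, pole_radius = 0.97, scale = 1),
    list(kind = "band_sine", freq_hz = 6, scale = 1),
    list(kind = "laplace_iid", scale = 1))
  rep(base, length.out = m)
}

r_laplace <- function(t, scale) {
  u <- stats::runif(t) - 0.5
  # inverse-CDF draw; variance = 2 b^2, rescaled to sd = scale
  x <- -sign(u) * log(1 - 2 * abs(u))
  x * scale / sqrt(2)
}

gen_one_source <- function(spec, t, fs) {
  scale <- if (is.null(spec$scale)) 1 else spec$scale
  switch(spec$kind,
    ar2 = {
      # AR(2) with complex pole pair at radius r, angle 2*pi*f/fs:
      # spectral density peaks near f
      r <- if (is.null(spec$pole_radius)) 0.97 else spec$pole_radius
      th <- 2 * pi * spec$freq_hz / fs
      a1 <- 2 * r * cos(th); a2 <- -r^2
      x <- as.numeric(stats::arima.sim(list(ar = c(a1, a2)), n = t,
                                       n.start = 500))
      x / stats::sd(x) * scale
    },
    band_sine = {
      ph <- stats::runif(1, 0, 2 * pi)
      x <- sin(2 * pi * spec$freq_hz * (seq_len(t) - 1) / fs + ph) +
        0.05 * stats::rnorm(t)
      x / stats::sd(x) * scale
    },
    laplace_iid = r_laplace(t, scale),
    stop(sprintf("config error: unknown source kind '%s'", spec$kind)))
}

#' Generate latent source signals
#'
#' Draws the `m x t` source matrix `S` of the mixing model, each row
#' independently from its spec. Deterministic given `seed`.
#'
#' @param model a [mixing_model()].
#' @param t number of time samples (>= 1).
#' @param seed integer RNG seed.
#' @return `m x t` numeric matrix.
#' @export
generate_sources <- function(model, t, seed = 1) {
  stopifnot(inherits(model, "MixingModel"), t >= 1)
  set.seed(seed)
  S <- matrix(0, nrow = model$m, ncol = t)
  for (j in seq_len(model$m))
    S[j, ] <- gen_one_source(model$source_specs[[j]], t, model$fs)
  S
}

#' Mix sources into a multichannel recording
#'
#' Applies the forward model `E = M S + noise`, with channel noise drawn
#' i.i.d. Gaussian at the model's `noise_sd`.
#'
#' @param sources `m x t` source matrix (rows must match `model$m`).
#' @param model a [mixing_model()].
#' @param seed RNG seed for the noise draw.
#' @param subject_id,trial_id identity passed to the resulting recording.
#' @param channel_labels channel names; defaults to `ch1..chn`.
#' @return A [recording()] of `n` channels by `t` samples.
#' @export
mix <- function(sources, model, seed = 1, subject_id = "sim",
                trial_id = NULL, channel_labels = NULL) {
  stopifnot(inherits(model, "MixingModel"))
  sources <- as.matrix(sources)
  if (nrow(sources) != model$m)
    stop(sprintf("config error: sources have %d rows, model expects m=%d",
                 nrow(sources), model$m))
  E <- model$M %*% sources
  if (model$noise_sd > 0) {
    set.seed(seed)
    E <- E + matrix(stats::rnorm(length(E), sd = model$noise_sd),
                    nrow = nrow(E))
  }
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(model$n))
  recording(E, channel_labels, model$fs,
            subject_id = subject_id, trial_id = trial_id)
}

#' Configuration for a labeled synthetic dataset
#'
#' Describes a multi-subject, multi-trial simulated study. Each subject gets
#' a distinct mixing matrix (a shared template plus a small Gaussian
#' perturbation, so cross-subject structure exists but leave-one-subject-out
#' evaluation is nontrivial). Positive-class trials multiply the amplitude of
#' one designated source by `amplitude_ratio`; classes are balanced.
#'
#' @param n_subjects,trials_per_subject,trial_seconds study dimensions.
#' @param n,m channel and source counts (`m <= n`).
#' @param fs sampling rate in Hz.
#' @param noise_sd sensor noise standard deviation.
#' @param modulated_source index of the class-modulated source.
#' @param amplitude_ratio positive-trial amplitude multiplier (> 0).
#' @param subject_sd scale of the per-subject mixing-matrix perturbation,
#'   relative to the template's entries.
#' @param master_seed seed controlling the whole dataset.
#' @return An object of class `"SyntheticDatasetConfig"`.
#' @export
synthetic_config <- function(n_subjects = 4, trials_per_subject = 10,
                             trial_seconds = 30, n = 8, m = 3, fs = 128,
                             noise_sd = 0.1, modulated_source = 1,
                             amplitude_ratio = 2, subject_sd = 0.1,
                             master_seed = 2020) {
  stopifnot(n_subjects >= 1, trials_per_subject >= 1, trial_seconds >= 1,
            n >= 1, m >= 1, amplitude_ratio > 0)
  if (m > n) stop("config error: m > n")
  structure(as.list(environment()), class = "SyntheticDatasetConfig")
}

#' Generate a labeled synthetic dataset
#'
#' Produces one recording and one trial label per (subject, trial), plus a
#' ground-truth manifest holding each subject's mixing matrix and the class
#' effect, for source-recovery and oracle-classifier tests. Deterministic
#' given `cfg$master_seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return A list with `recordings` (list of [recording()]), `labels`
#'   (a [trial_labels()] table with `dimension = "predefined"`), and
#'   `manifest` (per-subject [mixing_model()]s, the modulated source index
#'   and amplitude ratio, and per-trial true source matrices' seeds).
#' @export
make_labeled_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticDatasetConfig"))
  t_samp <- round(cfg$trial_seconds * cfg$fs)
  set.seed(cfg$master_seed)
  template <- matrix(stats::rnorm(cfg$n * cfg$m), cfg$n, cfg$m)
  template <- template / max(abs(template))
  specs <- default_source_specs(cfg$m)
  models <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    Ms <- template + matrix(stats::rnorm(cfg$n * cfg$m,
                                         sd = cfg$subject_sd), cfg$n, cfg$m)
    models[[s]] <- mixing_model(Ms, specs, noise_sd = cfg$noise_sd,
                                fs = cfg$fs)
  }
  recs <- list(); subj <- character(); trl <- character(); kls <- character()
  k <- 0L
  half <- cfg$trials_per_subject %/% 2
  for (s in seq_len(cfg$n_subjects)) {
    sid <- sprintf("s%02d", s)
    # balanced classes, alternating so odd trial counts stay near-balanced
    classes <- rep(c("negative", "positive"), length.out = cfg$trials_per_subject)
    for (tr in seq_len(cfg$trials_per_subject)) {
      k <- k + 1L
      tid <- sprintf("t%02d", tr)
      seed_tr <- (cfg$master_seed + 7919L * s + 104729L * tr) %% 2147483647L
      S <- generate_sources(models[[s]], t_samp, seed = seed_tr)
      if (classes[tr] == "positive")
        S[cfg$modulated_source, ] <- S[cfg$modulated_source, ] * cfg$amplitude_ratio
      recs[[k]] <- mix(S, models[[s]], seed = seed_tr + 1L,
                       subject_id = sid, trial_id = tid)
      subj[k] <- sid; trl[k] <- tid; kls[k] <- classes[tr]
    }
  }
  labels <- trial_labels(subj, trl, rep("predefined", k), rep(NA_real_, k), kls)
  manifest <- list(models = models, modulated_source = cfg$modulated_source,
                   amplitude_ratio = cfg$amplitude_ratio, config = cfg)
  list(recordings = recs, labels = labels, manifest = manifest)
}

#' Write a synthetic dataset to a directory
#'
#' Recordings go to `<dir>/<subject>_<trial>.dat` containers, labels to
#' `<dir>/labels.tsv`, and the ground-truth manifest (per-subject mixing
#' matrices, class effect, config) to `<dir>/manifest.json`.
#'
#' @param ds result of [make_labeled_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in ds$recordings)
    write_recording(rec, file.path(dir, sprintf("%s_%s.dat", rec$subject_id,
                                                rec$trial_id)))
  write_labels(ds$labels, file.path(dir, "labels.tsv"))
  man <- ds$manifest
  json <- list(
    modulated_source = man$modulated_source,
    amplitude_ratio = man$amplitude_ratio,
    config = unclass(man$config),
    mixing_matrices = lapply(man$models, function(mm)
      list(nrow = nrow(mm$M), ncol = ncol(mm$M), values = as.vector(mm$M))))
  jsonlite::write_json(json, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Synthetic 10-20 montage labels
#'
#' Channel label sets for simulated recordings: the standard 32-channel
#' 10-20 montage (which contains every electrode of the default asymmetry
#' pair registry), optionally extended with additional 10-20/10-10 names up
#' to 62 channels for dense-montage simulations.
#'
#' @param n 32 or 62.
#' @return Character vector of `n` unique channel labels.
#' @export
standard_montage <- function(n = 32) {
  base32 <- c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5",
              "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
              "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "Cz", "C4",
              "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2")
  if (n == 32) return(base32)
  if (n == 62) {
    extra <- c("AF7", "AF8", "AFz", "F1", "F2", "F5", "F6", "FT7", "FT8",
               "FC3", "FC4", "FCz", "C1", "C2", "C5", "C6", "TP7", "TP8",
               "CP3", "CP4", "CPz", "P1", "P2", "P5", "P6", "PO7", "PO8",
               "POz", "O9", "O10")
    return(c(base32, extra))
  }
  stop("config error: montage defined for n = 32 or 62")
}
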