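#' Canonical EEG rhythm band definitions
#'
#' Conventional boundaries: theta 4-8, alpha 8-13, beta 13-30, gamma
#' 30-45 Hz. All edges are configurable at call sites; these are the
#' defaults used by the feature bank.
#'
#' @return Named list of `BandDefinition` lists with `name`, `low_hz`,
#'   `high_hz`.
#' @export
default_bands <- function() {
  list(theta = band_definition("theta", 4, 8),
       alpha = band_definition("alpha", 8, 13),
       beta  = band_definition("beta", 13, 30),
       gamma = band_definition("gamma", 30, 45))
}

#' @rdname default_bands
#' @param name band name.
#' @param low_hz,high_hz band edges in Hz, `0 < low_hz < high_hz`.
#' @export
band_definition <- function(name, low_hz, high_hz) {
  if (!(low_hz > 0 && low_hz < high_hz))
    stop("config error: need 0 < low_hz < high_hz")
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz),
            class = "BandDefinition")
}

#' Z-score each channel of a recording
#'
#' Per-channel standardization to mean 0 and unit standard deviation, the
#' per-subject normalization applied before decoder training. Constant
#' channels cannot be standardized; they are mapped to all-zeros with a
#' warning.
#'
#' @param rec a [recording()] with at least 2 samples per channel.
#' @return A standardized [recording()].
#' @export
zscore_per_channel <- function(rec) {
  validate_recording(rec)
  if (ncol(rec$data) < 2L) stop("need >= 2 samples per channel")
  mu <- rowMeans(rec$data)
  sdv <- apply(rec$data, 1, stats::sd)
  flat <- sdv < .Machine$double.eps^0.5
  if (any(flat)) {
    warning(sprintf("constant channel(s) mapped to zeros: %s",
                    paste(rec$channel_labels[flat], collapse = ", ")))
    sdv[flat] <- 1
  }
  out <- (rec$data - mu) / sdv
  out[flat, ] <- 0
  recording(out, rec$channel_labels, rec$fs,
            subject_id = rec$subject_id, trial_id = rec$trial_id)
}

#' Zero-phase band-pass filter a recording
#'
#' Forward-backward (zero-phase) Butterworth IIR filtering per channel.
#' Phase linearity matters downstream: asymmetry and entropy features would
#' be corrupted by phase distortion.
#'
#' @param rec a [recording()].
#' @param band a [band_definition()]; `high_hz` must be below Nyquist.
#' @param order filter order of the underlying one-pass design (default 4).
#' @return A filtered [recording()] of identical shape.
#' @export
bandpass <- function(rec, band, order = 4) {
  validate_recording(rec)
  nyq <- rec$fs / 2
  if (band$high_hz >= nyq)
    stop(sprintf("config error: band [%g, %g] exceeds Nyquist %g Hz",
                 band$low_hz, band$high_hz, nyq))
  bf <- signal::butter(order, c(band$low_hz, band$high_hz) / nyq,
                       type = "pass")
  out <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  recording(out, rec$channel_labels, rec$fs,
            subject_id = rec$subject_id, trial_id = rec$trial_id)
}

#' Cut trials out of a continuous recording
#'
#' @param rec a [recording()].
#' @param trials data.frame with columns `trial_id`, `start`, `stop`:
#'   0-based sample indices, half-open `[start, stop)`, each within
#'   `[0, t]`. Segments may overlap.
#' @return A list of [recording()]s, one per row, lengths `stop - start`.
#' @export
segment_trials <- function(rec, trials) {
  validate_recording(rec)
  t_total <- ncol(rec$data)
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    a <- trials$start[i]; b <- trials$stop[i]
    if (a < 0 || b > t_total || a >= b)
      stop(sprintf("validation error: segment [%d, %d) out of bounds [0, %d)",
                   a, b, t_total))
    out[[i]] <- recording(rec$data[, (a + 1):b, drop = FALSE],
                          rec$channel_labels, rec$fs,
                          subject_id = rec$subject_id,
                          trial_id = as.character(trials$trial_id[i]))
  }
  out
}
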