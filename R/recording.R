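#' Construct a multichannel EEG recording
#'
#' A `Recording` is the package's canonical container for one stretch of
#' multichannel EEG: a channels-by-time real matrix plus the metadata needed
#' to interpret it (10-20 channel labels, sampling rate, subject and trial
#' identity). Rows are channels, columns are time samples; time is
#' sample-indexed from 0 and seconds are derived via `fs`.
#'
#' @param data numeric matrix, rows = channels, columns = time samples.
#' @param channel_labels character vector of unique channel names (10-20
#'   system names for real EEG); length must equal `nrow(data)`.
#' @param fs sampling rate in Hz, a single positive number.
#' @param subject_id subject identifier (coerced to character).
#' @param trial_id trial identifier or `NULL` for a whole-session recording.
#' @return An object of class `"Recording"`.
#' @examples
#' rec <- recording(matrix(rnorm(8 * 256), 8), paste0("ch", 1:8), fs = 128,
#'                  subject_id = "s01")
#' dim(rec$data)
#' @export
recording <- function(data, channel_labels, fs, subject_id = "s01",
                      trial_id = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  rec <- structure(
    list(subject_id = as.character(subject_id),
         trial_id = if (is.null(trial_id)) NULL else as.character(trial_id),
         channel_labels = as.character(channel_labels),
         fs = as.numeric(fs),
         data = data),
    class = "Recording")
  validate_recording(rec)
  rec
}

#' Validate a Recording's invariants
#'
#' Checks finiteness of every entry (reporting the first offending channel
#' and sample index), uniqueness of channel labels, label/row agreement and
#' positivity of the sampling rate.
#'
#' @param rec object to validate.
#' @return `rec`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_recording <- function(rec) {
  if (!inherits(rec, "Recording")) stop("not a Recording object")
  if (length(rec$fs) != 1L || !is.finite(rec$fs) || rec$fs <= 0)
    stop("fs must be a single positive number")
  if (!is.matrix(rec$data)) stop("data must be a matrix")
  n <- nrow(rec$data)
  if (length(rec$channel_labels) != n)
    stop(sprintf("channel label count (%d) does not match row count (%d)",
                 length(rec$channel_labels), n))
  dup <- rec$channel_labels[duplicated(rec$channel_labels)]
  if (length(dup))
    stop(sprintf("duplicate channel labels: %s",
                 paste(unique(dup), collapse = ", ")))
  bad <- which(!is.finite(rec$data))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% n) + 1L
    j <- ((bad[1] - 1L) %/% n) + 1L
    stop(sprintf("non-finite value in channel '%s' at sample index %d",
                 rec$channel_labels[i], j - 1L))
  }
  invisible(rec)
}

#' @export
print.Recording <- function(x, ...) {
  cat(sprintf("<Recording> subject %s%s: %d channels x %d samples @ %g Hz\n",
              x$subject_id,
              if (is.null(x$trial_id)) "" else paste0(" trial ", x$trial_id),
              nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Construct a latent factor sequence
#'
#' An `m x t` matrix of latent factor activations (the decoded "independent
#' components") for one recording, tagged with the decoder that produced it
#' and the sampling rate inherited from the source recording.
#'
#' @param factors numeric matrix, rows = factors (m), columns = time samples.
#' @param fs sampling rate in Hz of the source recording.
#' @param subject_id,trial_id identity of the source recording.
#' @param model_id string naming the decoder (e.g. `"vae_m3"`).
#' @return An object of class `"FactorSequence"`.
#' @export
factor_sequence <- function(factors, fs, subject_id = "s01", trial_id = NULL,
                            model_id = "unknown") {
  factors <- as.matrix(factors)
  storage.mode(factors) <- "double"
  fseq <- structure(
    list(subject_id = as.character(subject_id),
         trial_id = if (is.null(trial_id)) NULL else as.character(trial_id),
         model_id = as.character(model_id),
         fs = as.numeric(fs),
         factors = factors),
    class = "FactorSequence")
  validate_factor_sequence(fseq)
  fseq
}

#' Validate a FactorSequence's invariants
#' @param fseq object to validate.
#' @return `fseq` invisibly, or an error.
#' @export
validate_factor_sequence <- function(fseq) {
  if (!inherits(fseq, "FactorSequence")) stop("not a FactorSequence object")
  if (nrow(fseq$factors) < 1L) stop("factor sequence must have m >= 1 rows")
  if (any(!is.finite(fseq$factors)))
    stop("non-finite value in factor sequence")
  if (length(fseq$fs) != 1L || !is.finite(fseq$fs) || fseq$fs <= 0)
    stop("fs must be a single positive number")
  invisible(fseq)
}

#' @export
print.FactorSequence <- function(x, ...) {
  cat(sprintf("<FactorSequence> %s subject %s%s: %d factors x %d samples @ %g Hz\n",
              x$model_id, x$subject_id,
              if (is.null(x$trial_id)) "" else paste0(" trial ", x$trial_id),
              nrow(x$factors), ncol(x$factors), x$fs))
  invisible(x)
}

#' Construct a trial label table
#'
#' One row per (subject, trial, rating dimension). `klass` is the binarized
#' emotional class; `rating` is the raw 1-9 self-assessment score (or `NA`
#' for datasets with predefined classes).
#'
#' @param subject_id,trial_id character vectors.
#' @param dimension one of `"valence"`, `"arousal"`, `"predefined"` per row.
#' @param rating numeric in `[1, 9]` or `NA`.
#' @param klass one of `"positive"`, `"negative"`, `"excluded"` per row.
#' @return A data.frame of class `"TrialLabelTable"`.
#' @export
trial_labels <- function(subject_id, trial_id, dimension, rating, klass) {
  df <- data.frame(subject_id = as.character(subject_id),
                   trial_id = as.character(trial_id),
                   dimension = as.character(dimension),
                   rating = as.numeric(rating),
                   klass = as.character(klass),
                   stringsAsFactors = FALSE)
  class(df) <- c("TrialLabelTable", "data.frame")
  validate_trial_labels(df)
  df
}

#' Validate a trial label table
#' @param df a `TrialLabelTable`.
#' @return `df` invisibly, or an error.
#' @export
validate_trial_labels <- function(df) {
  stopifnot(is.data.frame(df))
  ok_dim <- df$dimension %in% c("valence", "arousal", "predefined")
  if (!all(ok_dim))
    stop("dimension must be one of valence/arousal/predefined")
  ok_k <- df$klass %in% c("positive", "negative", "excluded")
  if (!all(ok_k))
    stop("klass must be one of positive/negative/excluded")
  key <- paste(df$subject_id, df$trial_id, df$dimension)
  if (anyDuplicated(key))
    stop("(subject_id, trial_id, dimension) rows must be unique")
  has_r <- !is.na(df$rating)
  if (any(has_r & (df$rating < 1 | df$rating > 9)))
    stop("ratings must lie in [1, 9]")
  # klass must agree with the rating-based binarization rule when present
  expect <- ifelse(df$rating > 5, "positive",
                   ifelse(df$rating < 5, "negative", "excluded"))
  bad <- has_r & df$dimension != "predefined" & expect != df$klass
  if (any(bad))
    stop(sprintf("klass inconsistent with rating for %s/%s",
                 df$subject_id[which(bad)[1]], df$trial_id[which(bad)[1]]))
  invisible(df)
}
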