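#' Encode a recording into a latent factor sequence
#'
#' Applies the fitted model's deterministic encoder to every time sample of
#' the recording: the AE hidden layer, the GRBM hidden conditional mean
#' `P(h | x)`, the VAE posterior mean `mu` (no sampling at inference), or
#' the linear unmixing projection (ICA/PCA). The recording must be z-scored
#' with the same convention used at fit time and its channel count must
#' equal the model's `n`.
#'
#' @param model a fitted `"AEModel"`, `"GRBMModel"`, `"VAEModel"` or
#'   `"LinearDecoderModel"`.
#' @param rec a [recording()].
#' @param model_id optional identifier stored in the output (defaults to a
#'   tag built from the model class and `m`).
#' @return A [factor_sequence()] of dimension `m x t`.
#' @export
encode <- function(model, rec, model_id = NULL) UseMethod("encode")

check_encode_dims <- function(model, rec) {
  validate_recording(rec)
  if (nrow(rec$data) != model$n)
    stop(sprintf("validation error: recording has %d channels, model expects %d",
                 nrow(rec$data), model$n))
}

default_model_id <- function(model) {
  kind <- switch(class(model)[1],
                 AEModel = "ae", GRBMModel = "grbm", VAEModel = "vae",
                 LinearDecoderModel = model$kind)
  sprintf("%s_m%d", kind, model$m)
}

wrap_factors <- function(F, model, rec, model_id) {
  factor_sequence(F, rec$fs, subject_id = rec$subject_id,
                  trial_id = rec$trial_id,
                  model_id = model_id %||% default_model_id(model))
}

#' @export
encode.AEModel <- function(model, rec, model_id = NULL) {
  check_encode_dims(model, rec)
  wrap_factors(t(ae_forward_hidden(model, t(rec$data))), model, rec, model_id)
}

#' @export
encode.GRBMModel <- function(model, rec, model_id = NULL) {
  check_encode_dims(model, rec)
  wrap_factors(t(grbm_hidden_prob(model, t(rec$data))), model, rec, model_id)
}

#' @export
encode.VAEModel <- function(model, rec, model_id = NULL) {
  check_encode_dims(model, rec)
  wrap_factors(t(vae_encode_mu(model, t(rec$data))), model, rec, model_id)
}

#' @export
encode.LinearDecoderModel <- function(model, rec, model_id = NULL) {
  check_encode_dims(model, rec)
  Xc <- sweep(t(rec$data), 2, model$center)
  wrap_factors(t(Xc %*% t(model$unmix)), model, rec, model_id)
}

#' Reconstruct channel data from a latent factor sequence
#'
#' Applies the model's decoder per time sample, yielding an `n x t`
#' recording. Deterministic for every model class (the VAE decodes the
#' factor values as given, without sampling).
#'
#' @param model a fitted decoder model (see [encode()]).
#' @param fseq a [factor_sequence()] with `m` matching the model.
#' @param channel_labels labels for the reconstructed channels (default
#'   `ch1..chn`).
#' @return A [recording()].
#' @export
reconstruct <- function(model, fseq, channel_labels = NULL)
  UseMethod("reconstruct")

check_decode_dims <- function(model, fseq) {
  validate_factor_sequence(fseq)
  if (nrow(fseq$factors) != model$m)
    stop(sprintf("validation error: sequence has m=%d, model expects m=%d",
                 nrow(fseq$factors), model$m))
}

wrap_recon <- function(X, model, fseq, channel_labels) {
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(model$n))
  recording(X, channel_labels, fseq$fs, subject_id = fseq$subject_id,
            trial_id = fseq$trial_id)
}

#' @export
reconstruct.AEModel <- function(model, fseq, channel_labels = NULL) {
  check_decode_dims(model, fseq)
  wrap_recon(t(ae_forward_out(model, t(fseq$factors))), model, fseq,
             channel_labels)
}

#' @export
reconstruct.GRBMModel <- function(model, fseq, channel_labels = NULL) {
  check_decode_dims(model, fseq)
  wrap_recon(t(grbm_visible_mean(model, t(fseq$factors))), model, fseq,
             channel_labels)
}

#' @export
reconstruct.VAEModel <- function(model, fseq, channel_labels = NULL) {
  check_decode_dims(model, fseq)
  wrap_recon(t(vae_decode_mean(model, t(fseq$factors))), model, fseq,
             channel_labels)
}

#' @export
reconstruct.LinearDecoderModel <- function(model, fseq, channel_labels = NULL) {
  check_decode_dims(model, fseq)
  X <- t(t(fseq$factors) %*% t(model$mix_back)) + model$center
  wrap_recon(X, model, fseq, channel_labels)
}
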