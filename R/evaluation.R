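#' Pearson correlation between two series
#'
#' Standard centered product-moment correlation, the reconstruction metric.
#' Degenerate (constant) inputs yield 0 with a warning rather than `NA`.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @param warn warn on degenerate input (default TRUE).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y, warn = TRUE) {
  if (length(x) != length(y))
    stop("validation error: series lengths differ")
  if (length(x) < 2) stop("validation error: need at least 2 points")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx < .Machine$double.eps^0.5 || sy < .Machine$double.eps^0.5) {
    if (warn) warning("constant series: correlation reported as 0")
    return(0)
  }
  sum((x - mean(x)) * (y - mean(y))) / ((length(x) - 1) * sx * sy)
}

#' F1 score from predicted and true labels
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`. Any zero
#' denominator yields 0 with a warning.
#'
#' @param pred,true character label vectors of equal length; values must
#'   come from the two-class universe `{positive_class, negative_class}`.
#' @param positive_class label counted as positive (default `"positive"`).
#' @param negative_class the other admissible label (default `"negative"`).
#' @return List with `f1`, `precision`, `recall` and confusion counts
#'   `tp`, `fp`, `fn`, `tn`.
#' @export
f1_score <- function(pred, true, positive_class = "positive",
                     negative_class = "negative") {
  if (length(pred) != length(true))
    stop("validation error: label vectors differ in length")
  allowed <- c(positive_class, negative_class)
  if (!all(pred %in% allowed))
    stop(sprintf("validation error: unknown predicted label '%s'",
                 setdiff(pred, allowed)[1]))
  if (!all(true %in% allowed))
    stop(sprintf("validation error: unknown true label '%s'",
                 setdiff(true, allowed)[1]))
  p <- pred == positive_class; t_ <- true == positive_class
  tp <- sum(p & t_); fp <- sum(p & !t_); fn <- sum(!p & t_)
  tn <- sum(!p & !t_)
  prec <- if (tp + fp == 0) {
    warning("no positive predictions: precision reported as 0"); 0
  } else tp / (tp + fp)
  rec <- if (tp + fn == 0) {
    warning("no positive ground truth: recall reported as 0"); 0
  } else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(f1 = f1, precision = prec, recall = rec,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Binarize self-assessment ratings into emotional classes
#'
#' Under the `deap_median5` scheme a rating over five points is positive
#' and below five negative; exactly five is excluded by default (the
#' boundary is not assigned to either class) or mapped to negative with
#' `ties = "negative"`. The `predefined` scheme passes labels through
#' untouched.
#'
#' @param rating numeric vector of ratings in `[1, 9]` (for
#'   `deap_median5`), or already-binarized labels (for `predefined`).
#' @param scheme `"deap_median5"` or `"predefined"`.
#' @param ties `"excluded"` (default) or `"negative"` for rating == 5.
#' @return Character vector in `{"positive", "negative", "excluded"}`.
#' @export
label_binarize <- function(rating, scheme = c("deap_median5", "predefined"),
                           ties = c("excluded", "negative")) {
  scheme <- match.arg(scheme); ties <- match.arg(ties)
  if (scheme == "predefined") return(as.character(rating))
  rating <- as.numeric(rating)
  if (any(is.na(rating) | rating < 1 | rating > 9))
    stop("validation error: ratings must lie in [1, 9]")
  out <- ifelse(rating > 5, "positive",
                ifelse(rating < 5, "negative", ties))
  out
}

#' Reconstruction report for a fitted decoder
#'
#' Encodes and reconstructs each recording, computes the per-channel
#' Pearson correlation between original and reconstruction, and averages
#' over recordings (and subjects). For ICA models the channel-counterpart
#' matching protocol over the retained restarts is used instead, since
#' component order is ambiguous.
#'
#' @param model a fitted decoder model.
#' @param recordings list of [recording()]s, z-scored per the fit
#'   convention.
#' @param ica_protocol use [ica_reconstruction_protocol()] for ICA models
#'   (default: yes when the model is ICA).
#' @return A `"ReconstructionReport"`: `model_id`, `m`, `channels` (named
#'   mean r per channel label), `mean_r`, `per_subject` (named vector of
#'   subject-mean r).
#' @export
reconstruction_report <- function(model, recordings,
                                  ica_protocol = inherits(model, "LinearDecoderModel") &&
                                    identical(model$kind, "ica")) {
  stopifnot(length(recordings) >= 1)
  labels <- recordings[[1]]$channel_labels
  acc <- setNames(rep(0, length(labels)), labels)
  subj_acc <- list()
  for (rec in recordings) {
    if (ica_protocol) {
      per <- ica_reconstruction_protocol(model, rec)$per_channel_r
    } else {
      rhat <- reconstruct(model, encode(model, rec),
                          channel_labels = rec$channel_labels)
      per <- vapply(seq_along(labels), function(i)
        pearson_r(rec$data[i, ], rhat$data[i, ], warn = FALSE), numeric(1))
      names(per) <- labels
    }
    acc <- acc + per
    sid <- rec$subject_id
    subj_acc[[sid]] <- c(subj_acc[[sid]], mean(per))
  }
  channels <- acc / length(recordings)
  structure(list(model_id = default_model_id(model), m = model$m,
                 channels = channels, mean_r = mean(channels),
                 per_subject = vapply(subj_acc, mean, numeric(1))),
            class = "ReconstructionReport")
}

#' Export a reconstruction report's channel map as heatmap JSON
#'
#' Writes `{channel label: mean r}` pairs for channel-layout heatmap
#' rendering.
#'
#' @param report a `"ReconstructionReport"`.
#' @param path output JSON path.
#' @return `path` invisibly.
#' @export
write_heatmap_json <- function(report, path) {
  jsonlite::write_json(as.list(report$channels), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @export
print.ReconstructionReport <- function(x, ...) {
  cat(sprintf("<ReconstructionReport> %s (m=%d): mean r = %.4f over %d channels\n",
              x$model_id, x$m, x$mean_r, length(x$channels)))
  invisible(x)
}

derive_seed <- function(seed, k) (as.integer(seed) + 1000003L * k) %% 2147483647L

fit_decoder <- function(kind, data, m, seed, args = list()) {
  fn <- switch(kind, ae = fit_ae, grbm = fit_grbm, vae = fit_vae,
               ica = fit_ica, pca = fit_pca,
               stop(sprintf("unknown decoder kind '%s'", kind)))
  base <- list(data, m = m)
  if (kind != "pca") base$seed <- seed
  do.call(fn, c(base, args))
}

#' Leave-one-subject-out cross-validation of the full pipeline
#'
#' For each fold one subject is held out: the decoder is fitted on the
#' pooled time samples of the training subjects only, every recording is
#' encoded to factor sequences, sequences are standardized with
#' training-fold statistics, thinned at `step_seconds`, and a many-to-one
#' LSTM is trained on the training subjects and evaluated (F1) on the
#' held-out subject. No held-out sample influences any training artifact.
#'
#' @param dataset list with `recordings` (list of [recording()]s) and
#'   `labels` (a [trial_labels()] table); e.g. [make_labeled_dataset()]
#'   output.
#' @param decoder decoder kind: `"ae"`, `"grbm"`, `"vae"`, `"ica"`,
#'   `"pca"`.
#' @param m latent factor count.
#' @param decoder_args extra arguments for the decoder's fit function.
#' @param step_seconds sequence sampling step (default 0.25 s).
#' @param lstm an [lstm_config()].
#' @param dimension label dimension to use (default `"predefined"`).
#' @param seed master seed for the fold-level fits.
#' @param permute_labels permute training labels within each fold (leakage
#'   control; performance should collapse to chance).
#' @param zscore per-subject z-scoring before decoding (default TRUE).
#' @return A `"CVResult"`: `per_subject` (named F1), `mean_f1`,
#'   `confusion` (per-fold counts), `skipped` (subjects without both
#'   classes).
#' @export
loso_cv <- function(dataset, decoder = "vae", m = 3, decoder_args = list(),
                    step_seconds = 0.25, lstm = lstm_config(),
                    dimension = "predefined", seed = 1,
                    permute_labels = FALSE, zscore = TRUE) {
  recs <- dataset$recordings
  labels <- dataset$labels[dataset$labels$dimension == dimension, ]
  subjects <- unique(vapply(recs, function(r) r$subject_id, character(1)))
  if (length(subjects) < 2) stop("LOSO needs at least 2 subjects")
  if (zscore) recs <- zscore_by_subject(recs)
  key <- function(r) paste(r$subject_id, r$trial_id)
  lab_of <- setNames(labels$klass, paste(labels$subject_id, labels$trial_id))
  keep <- vapply(recs, function(r)
    !is.na(lab_of[key(r)]) && lab_of[key(r)] != "excluded", logical(1))
  recs <- recs[keep]
  rec_subj <- vapply(recs, function(r) r$subject_id, character(1))
  per_subject <- numeric(0); confusion <- list(); skipped <- character(0)
  for (fold in seq_along(subjects)) {
    test_subj <- subjects[fold]
    test_idx <- which(rec_subj == test_subj)
    train_idx <- which(rec_subj != test_subj)
    test_labs <- lab_of[vapply(recs[test_idx], key, character(1))]
    train_labs <- lab_of[vapply(recs[train_idx], key, character(1))]
    if (length(unique(test_labs)) < 2) {
      warning(sprintf("fold %s skipped: held-out subject has a single class",
                      test_subj))
      skipped <- c(skipped, test_subj)
      next
    }
    if (length(unique(train_labs)) < 2) {
      warning(sprintf("fold %s skipped: training subjects have a single class",
                      test_subj))
      skipped <- c(skipped, test_subj)
      next
    }
    fseed <- derive_seed(seed, fold)
    pooled <- do.call(rbind, lapply(recs[train_idx], function(r) t(r$data)))
    dec <- fit_decoder(decoder, pooled, m, fseed, decoder_args)
    mk_samples <- function(idx) {
      lapply(idx, function(i)
        build_sequences(encode(dec, recs[[i]]),
                        list(klass = lab_of[key(recs[[i]])]),
                        step_seconds))
    }
    train_s <- mk_samples(train_idx)
    test_s <- mk_samples(test_idx)
    std <- standardize_sequences(train_s)
    train_s <- std$samples
    test_s <- standardize_sequences_apply(test_s, std$center, std$scale)
    if (permute_labels) {
      set.seed(fseed + 1L)
      perm <- sample(vapply(train_s, function(s) s$label, character(1)))
      for (i in seq_along(train_s)) train_s[[i]]$label <- perm[i]
    }
    cfg <- lstm; cfg$seed <- fseed + 2L
    clf <- train_lstm(train_s, cfg)
    pred <- predict(clf, test_s)
    sc <- f1_score(pred$labels, test_labs)
    per_subject[test_subj] <- sc$f1
    confusion[[test_subj]] <- sc[c("tp", "fp", "fn", "tn")]
  }
  structure(list(per_subject = per_subject,
                 mean_f1 = mean(per_subject),
                 confusion = confusion, skipped = skipped,
                 decoder = decoder, m = m),
            class = "CVResult")
}

standardize_sequences_apply <- function(samples, center, scale) {
  lapply(samples, function(s) {
    s$steps <- sweep(sweep(s$steps, 2, center), 2, scale, "/")
    s
  })
}

#' Z-score recordings subject by subject
#'
#' Each subject's per-channel statistics are computed over the
#' concatenation of all of that subject's recordings and applied to each of
#' their trials, so subjects are normalized independently of one another.
#'
#' @param recordings list of [recording()]s.
#' @return List of standardized recordings in the same order.
#' @export
zscore_by_subject <- function(recordings) {
  subj <- vapply(recordings, function(r) r$subject_id, character(1))
  out <- recordings
  for (s in unique(subj)) {
    idx <- which(subj == s)
    all_data <- do.call(cbind, lapply(recordings[idx], function(r) r$data))
    mu <- rowMeans(all_data)
    sdv <- apply(all_data, 1, stats::sd)
    sdv[sdv < .Machine$double.eps^0.5] <- 1
    for (i in idx) {
      r <- recordings[[i]]
      out[[i]] <- recording((r$data - mu) / sdv, r$channel_labels, r$fs,
                            subject_id = r$subject_id, trial_id = r$trial_id)
    }
  }
  out
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("<CVResult> %s (m=%d): mean F1 = %.4f over %d subjects%s\n",
              x$decoder, x$m, x$mean_f1, length(x$per_subject),
              if (length(x$skipped)) sprintf(" (%d skipped)",
                                             length(x$skipped)) else ""))
  invisible(x)
}
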