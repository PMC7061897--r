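#' Build a many-to-one training sequence from a trial's factor sequence
#'
#' High-sampling-rate factor sequences are thinned at equal intervals: the
#' factor vector is taken at sample indices `round(k * step_seconds * fs)`,
#' `k = 0, 1, ...`, strictly inside the trial, and the trial's single label
#' attaches to the whole sequence (the many-to-one mapping).
#'
#' @param fseq a [factor_sequence()] for one trial.
#' @param label one row of a [trial_labels()] table for that trial (klass
#'   must not be `"excluded"`).
#' @param step_seconds sampling step in seconds (default 0.25).
#' @return A `"SequenceSample"`: `steps` (`n_steps x m` matrix, one row per
#'   sampled time point), `label`, `subject_id`, `trial_id`.
#' @export
build_sequences <- function(fseq, label, step_seconds = 0.25) {
  validate_factor_sequence(fseq)
  stopifnot(step_seconds > 0)
  klass <- if (is.list(label) || is.data.frame(label)) label$klass else label
  if (identical(klass, "excluded"))
    stop("validation error: excluded trials cannot form training sequences")
  if (!klass %in% c("positive", "negative"))
    stop("validation error: label must be positive or negative")
  t_total <- ncol(fseq$factors)
  if (step_seconds * fseq$fs > t_total)
    stop("validation error: sampling step longer than the trial")
  k <- 0:ceiling(t_total / max(step_seconds * fseq$fs, 1e-12))
  idx0 <- round(k * step_seconds * fseq$fs)        # 0-based sample indices
  idx0 <- idx0[idx0 < t_total]
  if (!length(idx0))
    stop("validation error: sampling step longer than the trial")
  structure(list(steps = t(fseq$factors[, idx0 + 1, drop = FALSE]),
                 label = klass,
                 subject_id = fseq$subject_id, trial_id = fseq$trial_id),
            class = "SequenceSample")
}

#' LSTM classifier configuration
#'
#' Defaults follow the reference architecture for full-montage EEG factors:
#' 200 LSTM units feeding a 100-unit rectified-linear dense layer and a
#' 2-way softmax, dropout 0.5 on the last two layers, binary cross-entropy
#' loss, RMSprop, batch 50. The epoch cap is 100 with early stopping on a
#' training-loss plateau.
#'
#' @param lstm_units,dense_units layer widths (>= 1).
#' @param dense_activation activation tag for the dense layer.
#' @param dropout_rate dropout probability in `[0, 1)`.
#' @param batch,epochs,lr,seed training schedule.
#' @param patience early-stopping patience (epochs without >0.1% relative
#'   improvement).
#' @return An `"LSTMConfig"` list.
#' @export
lstm_config <- function(lstm_units = 200, dense_units = 100,
                        dense_activation = "relu", dropout_rate = 0.5,
                        batch = 50, epochs = 100, lr = 0.002, seed = 1,
                        patience = 8) {
  stopifnot(lstm_units >= 1, dense_units >= 1,
            dropout_rate >= 0, dropout_rate < 1)
  structure(as.list(environment()), class = "LSTMConfig")
}

# forward pass over a batch of equal-length sequences.
# X: list of T matrices (B x m). Returns caches when training.
lstm_forward <- function(p, X, U, keep_cache = FALSE) {
  B <- nrow(X[[1]]); TT <- length(X)
  H <- matrix(0, B, U); C <- matrix(0, B, U)
  cache <- if (keep_cache) vector("list", TT) else NULL
  for (t in seq_len(TT)) {
    g <- X[[t]] %*% p$Wx + H %*% p$Wh + matrix(p$b, B, 4 * U, byrow = TRUE)
    i <- sigmoid(g[, 1:U, drop = FALSE])
    f <- sigmoid(g[, (U + 1):(2 * U), drop = FALSE])
    o <- sigmoid(g[, (2 * U + 1):(3 * U), drop = FALSE])
    a <- tanh(g[, (3 * U + 1):(4 * U), drop = FALSE])
    Cp <- C
    C <- f * Cp + i * a
    tC <- tanh(C)
    Hp <- H
    H <- o * tC
    if (keep_cache)
      cache[[t]] <- list(i = i, f = f, o = o, a = a, C = C, Cp = Cp,
                         tC = tC, Hp = Hp, X = X[[t]])
  }
  list(H = H, cache = cache)
}

lstm_head_forward <- function(p, H, dropout, training, act) {
  B <- nrow(H)
  m1 <- if (training && dropout > 0)
    matrix(stats::rbinom(length(H), 1, 1 - dropout), B) / (1 - dropout)
  else 1
  Hd <- H * m1
  A1 <- act$f(sweep(Hd %*% p$Wd, 2, p$bd, "+"))
  m2 <- if (training && dropout > 0)
    matrix(stats::rbinom(length(A1), 1, 1 - dropout), B) / (1 - dropout)
  else 1
  A1d <- A1 * m2
  logits <- sweep(A1d %*% p$Wo, 2, p$bo, "+")
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  list(probs = probs, A1 = A1, Hd = Hd, A1d = A1d, m1 = m1, m2 = m2)
}

#' Train a many-to-one LSTM on labeled factor sequences
#'
#' Architecture: LSTM(`lstm_units`) read out at the final step, a dense
#' rectified-linear layer, and a 2-way softmax; dropout on the two fully
#' connected layers; binary cross-entropy loss minimized by RMSprop with
#' full backpropagation through time. Sequences of unequal length are
#' batched by length. Training stops at the epoch cap or when the epoch
#' loss plateaus.
#'
#' @param samples list of `"SequenceSample"` objects from
#'   [build_sequences()]; both classes must be present and all step vectors
#'   must share one dimension.
#' @param cfg an [lstm_config()].
#' @return An `"LSTMClassifier"` with weights, `classes`
#'   (`c("negative", "positive")`), per-epoch `losses` and the config.
#' @export
train_lstm <- function(samples, cfg = lstm_config()) {
  stopifnot(length(samples) >= 2)
  labs <- vapply(samples, function(s) s$label, character(1))
  classes <- c("negative", "positive")
  if (length(unique(labs)) < 2)
    stop("validation error: training data contains a single class")
  dims <- vapply(samples, function(s) ncol(s$steps), integer(1))
  if (length(unique(dims)) != 1)
    stop("validation error: sequences have differing factor dimensions")
  m <- dims[1]; U <- cfg$lstm_units; D <- cfg$dense_units
  y <- match(labs, classes)                        # 1 = negative, 2 = positive
  set.seed(cfg$seed)
  p <- list(Wx = glorot(m, 4 * U), Wh = glorot(U, 4 * U),
            b = c(rep(0, U), rep(1, U), rep(0, 2 * U)),  # forget bias 1
            Wd = glorot(U, D), bd = rep(0, D),
            Wo = glorot(D, 2), bo = rep(0, 2))
  opt <- opt_init("rmsprop", p, lr = cfg$lr)
  act <- act_fun(cfg$dense_activation)
  lens <- vapply(samples, function(s) nrow(s$steps), integer(1))
  losses <- numeric(0)
  best <- Inf; stall <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ep_loss <- 0; nb <- 0L
    ord <- sample.int(length(samples))
    for (len in unique(lens[ord])) {
      grp <- ord[lens[ord] == len]
      for (bidx in split(grp, ceiling(seq_along(grp) / cfg$batch))) {
        B <- length(bidx)
        X <- lapply(seq_len(len), function(t)
          do.call(rbind, lapply(samples[bidx], function(s) s$steps[t, ])))
        fw <- lstm_forward(p, X, U, keep_cache = TRUE)
        hd <- lstm_head_forward(p, fw$H, cfg$dropout_rate, TRUE, act)
        yi <- y[bidx]
        pr <- pmax(hd$probs[cbind(seq_len(B), yi)], 1e-12)
        loss <- -mean(log(pr))
        check_finite_loss(loss, "LSTM training")
        # softmax + cross-entropy gradient
        dlog <- hd$probs
        dlog[cbind(seq_len(B), yi)] <- dlog[cbind(seq_len(B), yi)] - 1
        dlog <- dlog / B
        g <- list(Wo = t(hd$A1d) %*% dlog, bo = colSums(dlog))
        dA1d <- dlog %*% t(p$Wo)
        dA1 <- dA1d * hd$m2 * act$df(hd$A1)
        g$Wd <- t(hd$Hd) %*% dA1; g$bd <- colSums(dA1)
        dH <- (dA1 %*% t(p$Wd)) * hd$m1
        # BPTT
        g$Wx <- matrix(0, m, 4 * U); g$Wh <- matrix(0, U, 4 * U)
        g$b <- rep(0, 4 * U)
        dC <- matrix(0, B, U)
        for (t in rev(seq_len(len))) {
          cc <- fw$cache[[t]]
          do_ <- dH * cc$tC
          dC <- dC + dH * cc$o * (1 - cc$tC^2)
          di <- dC * cc$a; df_ <- dC * cc$Cp; da <- dC * cc$i
          dg <- cbind(di * cc$i * (1 - cc$i),
                      df_ * cc$f * (1 - cc$f),
                      do_ * cc$o * (1 - cc$o),
                      da * (1 - cc$a^2))
          g$Wx <- g$Wx + t(cc$X) %*% dg
          g$Wh <- g$Wh + t(cc$Hp) %*% dg
          g$b <- g$b + colSums(dg)
          dH <- dg %*% t(p$Wh)
          dC <- dC * cc$f
        }
        # simple gradient clipping for stability on long sequences
        for (k in c("Wx", "Wh", "b")) {
          nrm <- sqrt(sum(g[[k]]^2))
          if (nrm > 5) g[[k]] <- g[[k]] * 5 / nrm
        }
        st <- opt_step(opt, p, g)
        opt <- st$opt; p <- st$params
        ep_loss <- ep_loss + loss; nb <- nb + 1L
      }
    }
    ep_loss <- ep_loss / nb
    losses <- c(losses, ep_loss)
    if (ep_loss < best * 0.999) { best <- ep_loss; stall <- 0L }
    else stall <- stall + 1L
    if (stall >= cfg$patience) break
  }
  structure(list(params = p, classes = classes, m = m, config = cfg,
                 losses = losses),
            class = "LSTMClassifier")
}

#' Predict emotional classes for factor sequences
#'
#' Deterministic inference (dropout disabled): forward pass, softmax, and
#' argmax per sequence.
#'
#' @param object a trained `"LSTMClassifier"`.
#' @param samples list of `"SequenceSample"` objects with matching factor
#'   dimension.
#' @param ... unused.
#' @return List with `labels` (character vector) and `probs`
#'   (`n_samples x 2` matrix, columns `negative`/`positive`).
#' @export
predict.LSTMClassifier <- function(object, samples, ...) {
  dims <- vapply(samples, function(s) ncol(s$steps), integer(1))
  if (any(dims != object$m))
    stop(sprintf("validation error: sequence dimension %d does not match model m=%d",
                 dims[which(dims != object$m)[1]], object$m))
  U <- object$config$lstm_units
  act <- act_fun(object$config$dense_activation)
  lens <- vapply(samples, function(s) nrow(s$steps), integer(1))
  probs <- matrix(NA_real_, length(samples), 2,
                  dimnames = list(NULL, object$classes))
  for (len in unique(lens)) {
    grp <- which(lens == len)
    X <- lapply(seq_len(len), function(t)
      do.call(rbind, lapply(samples[grp], function(s) s$steps[t, ])))
    fw <- lstm_forward(object$params, X, U, keep_cache = FALSE)
    hd <- lstm_head_forward(object$params, fw$H, 0, FALSE, act)
    probs[grp, ] <- hd$probs
  }
  list(labels = object$classes[max.col(probs, ties.method = "first")],
       probs = probs)
}

#' Standardize factor sequences with training-fold statistics
#'
#' Computes per-factor mean and sd over all steps of the training samples
#' and applies the affine map to any sample list, so held-out subjects are
#' scaled with statistics they did not influence.
#'
#' @param train_samples samples defining the statistics.
#' @param apply_samples samples to transform (default: the training ones).
#' @return List with `samples` (transformed) and `center`/`scale`.
#' @export
standardize_sequences <- function(train_samples, apply_samples = train_samples) {
  allsteps <- do.call(rbind, lapply(train_samples, function(s) s$steps))
  center <- colMeans(allsteps)
  scale <- apply(allsteps, 2, stats::sd)
  scale[scale < .Machine$double.eps^0.5] <- 1
  out <- lapply(apply_samples, function(s) {
    s$steps <- sweep(sweep(s$steps, 2, center), 2, scale, "/")
    s
  })
  list(samples = out, center = center, scale = scale)
}
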