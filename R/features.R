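#' Hjorth parameters of a signal
#'
#' Activity is the variance; mobility the square root of the variance
#' ratio of the first difference to the signal; complexity the mobility of
#' the first difference divided by the mobility of the signal. A constant
#' signal yields `(0, 0, 0)` with a warning.
#'
#' @param x numeric series, length >= 3.
#' @return Named vector `c(activity, mobility, complexity)`.
#' @export
hjorth <- function(x) {
  stopifnot(length(x) >= 3)
  v0 <- stats::var(x)
  if (v0 < .Machine$double.eps) {
    warning("constant signal: Hjorth parameters reported as 0")
    return(c(activity = 0, mobility = 0, complexity = 0))
  }
  d1 <- diff(x); d2 <- diff(d1)
  mob <- sqrt(stats::var(d1) / v0)
  mob_d <- if (stats::var(d1) < .Machine$double.eps) 0
           else sqrt(stats::var(d2) / stats::var(d1))
  comp <- if (mob == 0) 0 else mob_d / mob
  c(activity = v0, mobility = mob, complexity = comp)
}

# one-sided raw periodogram: P_k = |FFT_k|^2 / N at frequencies k*fs/N,
# k = 0..floor(N/2). This fixed convention underlies every spectral feature.
periodogram <- function(x, fs) {
  N <- length(x)
  P <- Mod(stats::fft(x))^2 / N
  k <- 0:floor(N / 2)
  list(freq = k * fs / N, power = P[k + 1])
}

#' Time-frequency-domain feature set (9 features)
#'
#' Peak-peak mean (mean over sub-windows of max - min; window length
#' `pp_window_seconds`), mean square value, variance, the three Hjorth
#' parameters, the frequency of the periodogram maximum, that maximum's
#' density, and the total spectral power sum. The periodogram convention
#' is `|FFT|^2 / N` over the one-sided frequency axis.
#'
#' @param x numeric series, length >= 16.
#' @param fs sampling rate in Hz.
#' @param pp_window_seconds sub-window length for the peak-peak mean
#'   (default 1 s; the whole series if shorter).
#' @return Named numeric vector of 9 features.
#' @export
tfd_features <- function(x, fs, pp_window_seconds = 1) {
  stopifnot(length(x) >= 16)
  w <- max(2L, min(length(x), round(pp_window_seconds * fs)))
  nw <- length(x) %/% w
  ppm <- mean(vapply(seq_len(nw), function(i) {
    seg <- x[((i - 1) * w + 1):(i * w)]
    max(seg) - min(seg)
  }, numeric(1)))
  hj <- suppressWarnings(hjorth(x))
  pg <- periodogram(x, fs)
  imax <- which.max(pg$power)
  c(ppmean = ppm,
    msv = mean(x^2),
    variance = stats::var(x),
    hjorth_activity = unname(hj["activity"]),
    hjorth_mobility = unname(hj["mobility"]),
    hjorth_complexity = unname(hj["complexity"]),
    max_psd_freq = pg$freq[imax],
    max_psd = pg$power[imax],
    power_sum = sum(pg$power))
}

# evenly-spaced subsample used by the quadratic-cost embedding estimators
thin_series <- function(x, max_points) {
  if (length(x) <= max_points) return(x)
  x[round(seq(1, length(x), length.out = max_points))]
}

embed_series <- function(x, dim, delay = 1) {
  n <- length(x) - (dim - 1) * delay
  if (n < 2) return(NULL)
  sapply(seq_len(dim), function(d) x[(1 + (d - 1) * delay):((d - 1) * delay + n)])
}

corr_sum <- function(E, r) {
  d <- as.vector(stats::dist(E))
  mean(d < r)
}

#' Nonlinear dynamical-system feature set (9 features)
#'
#' Approximate entropy (embedding 2, tolerance `0.2 * sd`), C0 complexity
#' (power fraction of the irregular spectral component after removing
#' lines exceeding `c0_threshold` times the mean spectral power),
#' correlation dimension (Grassberger-Procaccia slope), correlation
#' entropy K2 (a desk-computable estimate of the Kolmogorov entropy),
#' largest Lyapunov exponent (Rosenstein's method, per second),
#' permutation entropy (order 3, delay 1, normalized to `[0, 1]`),
#' singular-spectrum entropy, Shannon entropy of the amplitude histogram,
#' and spectral entropy of the normalized periodogram. Estimators that
#' cannot run on a given series return 0 with a warning so the feature
#' vector stays finite; every parameter is a function argument.
#'
#' @param x numeric series (>= 256 samples recommended; shorter input
#'   warns).
#' @param fs sampling rate in Hz.
#' @param max_points cap on points used by the quadratic-cost embedding
#'   estimators (series evenly thinned above it).
#' @param embed_dim embedding dimension for the correlation-integral and
#'   Lyapunov estimators.
#' @param c0_threshold spectral-line threshold factor for C0 complexity.
#' @param hist_bins amplitude histogram bins for the Shannon entropy.
#' @param theiler temporal exclusion window (samples) for the Lyapunov
#'   nearest-neighbour search.
#' @param lyap_steps divergence-tracking horizon (samples).
#' @return Named numeric vector of 9 features, all finite.
#' @export
nds_features <- function(x, fs, max_points = 300, embed_dim = 3,
                         c0_threshold = 5, hist_bins = 16, theiler = 10,
                         lyap_steps = 20) {
  if (length(x) < 256)
    warning(sprintf("series of length %d is short for NDS estimators (>= 256 recommended)",
                    length(x)))
  guarded <- function(f) {
    v <- suppressWarnings(tryCatch(f(), error = function(e) NaN))
    if (length(v) != 1 || !is.finite(v)) {
      warning("NDS estimator failed; value reported as 0")
      0
    } else as.numeric(v)
  }
  sdx <- stats::sd(x)
  if (sdx < .Machine$double.eps^0.5) {
    warning("constant signal: NDS features reported as 0")
    return(setNames(rep(0, 9),
                    c("apen", "c0", "corr_dim", "k2", "lyapunov", "perm_en",
                      "sse", "shannon", "spec_en")))
  }
  xt <- thin_series(x, max_points)
  apen <- guarded(function()
    pracma::approx_entropy(xt, edim = 2, r = 0.2 * stats::sd(xt)))
  c0 <- guarded(function() {
    F <- stats::fft(x)
    pw <- Mod(F)^2
    keep <- pw > c0_threshold * mean(pw)
    Freg <- F; Freg[!keep] <- 0
    reg <- Re(stats::fft(Freg, inverse = TRUE)) / length(x)
    sum((x - reg)^2) / sum(x^2)
  })
  r_grid <- sdx * c(0.25, 0.35, 0.5, 0.7, 1)
  corr_dim <- guarded(function() {
    E <- embed_series(xt, embed_dim)
    cs <- vapply(r_grid, function(r) corr_sum(E, r), numeric(1))
    ok <- cs > 0
    if (sum(ok) < 2) return(NaN)
    stats::coef(stats::lm(log(cs[ok]) ~ log(r_grid[ok])))[2]
  })
  k2 <- guarded(function() {
    E1 <- embed_series(xt, embed_dim)
    E2 <- embed_series(xt, embed_dim + 1)
    r <- 0.5 * sdx
    c1 <- corr_sum(E1[seq_len(nrow(E2)), , drop = FALSE], r)
    c2 <- corr_sum(E2, r)
    if (c1 <= 0 || c2 <= 0) return(NaN)
    log(c1 / c2)
  })
  lyap <- guarded(function() rosenstein_lyap(xt, fs * length(xt) / length(x),
                                             embed_dim, theiler, lyap_steps))
  perm_en <- guarded(function() permutation_entropy(x, order = 3, delay = 1))
  sse <- guarded(function() {
    w <- min(20L, length(xt) %/% 2)
    E <- embed_series(xt, w)
    sv <- svd(E, nu = 0, nv = 0)$d
    p <- sv^2 / sum(sv^2)
    p <- p[p > 0]
    -sum(p * log(p))
  })
  shan <- guarded(function() {
    h <- tabulate(cut(x, breaks = hist_bins, labels = FALSE), hist_bins)
    p <- h / sum(h); p <- p[p > 0]
    -sum(p * log(p))
  })
  spec_en <- guarded(function() spectral_entropy(x, fs))
  c(apen = apen, c0 = c0, corr_dim = unname(corr_dim), k2 = k2,
    lyapunov = lyap, perm_en = perm_en, sse = sse, shannon = shan,
    spec_en = spec_en)
}

#' Permutation entropy of ordinal patterns
#'
#' Counts ordinal patterns of `order` consecutive (lagged) samples and
#' returns the Shannon entropy of their distribution normalized by
#' `log(order!)`, so a strictly monotonic series scores exactly 0 and an
#' ideally irregular one 1.
#'
#' @param x numeric series.
#' @param order pattern length (default 3).
#' @param delay lag between pattern elements (default 1).
#' @return Normalized permutation entropy in `[0, 1]`.
#' @export
permutation_entropy <- function(x, order = 3, delay = 1) {
  n <- length(x) - (order - 1) * delay
  stopifnot(n >= 1)
  pats <- vapply(seq_len(n), function(i) {
    w <- x[seq(i, by = delay, length.out = order)]
    paste(order(w), collapse = "")
  }, character(1))
  p <- table(pats) / n
  h <- -sum(p * log(p))
  h / log(factorial(order))
}

#' Spectral entropy of the normalized periodogram
#'
#' Shannon entropy of the one-sided periodogram normalized to a
#' probability distribution, divided by the log bin count; near 1 for
#' white noise, near 0 for a pure tone.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @return Normalized spectral entropy in `[0, 1]`.
#' @export
spectral_entropy <- function(x, fs) {
  pg <- periodogram(x, fs)
  p <- pg$power / sum(pg$power)
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(pg$power))
}

# Rosenstein largest-Lyapunov estimate on an embedded series
rosenstein_lyap <- function(x, fs, embed_dim, theiler, steps) {
  E <- embed_series(x, embed_dim)
  n <- nrow(E)
  if (n < theiler + steps + 2) return(NaN)
  D <- as.matrix(stats::dist(E))
  diag(D) <- Inf
  for (off in seq_len(min(theiler, n - 1)))
    for (i in seq_len(n - off)) D[i, i + off] <- D[i + off, i] <- Inf
  usable <- seq_len(n - steps)
  nb <- apply(D[usable, usable, drop = FALSE], 1, which.min)
  logd <- matrix(NA_real_, length(usable), steps)
  for (k in seq_len(steps)) {
    i <- usable; j <- nb
    d <- sqrt(rowSums((E[i + k, , drop = FALSE] - E[j + k, , drop = FALSE])^2))
    logd[, k] <- ifelse(d > 0, log(d), NA)
  }
  y <- colMeans(logd, na.rm = TRUE)
  ks <- seq_len(steps)
  ok <- is.finite(y)
  if (sum(ok) < 2) return(NaN)
  unname(stats::coef(stats::lm(y[ok] ~ ks[ok]))[2]) * fs
}

#' Homologous electrode pair registry
#'
#' The standard 14 left/right electrode pairs used for hemispheric
#' asymmetry on a 32-channel 10-20 montage, ordered Fp1-Fp2 first. For
#' other montages supply your own pairs.
#'
#' @param pairs optional 2-column character matrix or list of `c(left,
#'   right)` pairs.
#' @return A `"PairRegistry"`: data.frame with columns `left`, `right`,
#'   `name`.
#' @export
default_pair_registry <- function(pairs = NULL) {
  if (is.null(pairs)) {
    left <- c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5",
              "CP1", "P3", "P7", "PO3", "O1")
    right <- c("Fp2", "AF4", "F4", "F8", "FC6", "FC2", "C4", "T8", "CP6",
               "CP2", "P4", "P8", "PO4", "O2")
  } else {
    pairs <- do.call(rbind, lapply(pairs, function(p) p))
    left <- pairs[, 1]; right <- pairs[, 2]
  }
  reg <- data.frame(left = left, right = right,
                    name = paste0(left, right), stringsAsFactors = FALSE)
  class(reg) <- c("PairRegistry", "data.frame")
  reg
}

#' Brain-hemisphere asymmetry features for one band-filtered trial
#'
#' Per registry pair, the difference of log band powers, `log P(left) -
#' log P(right)` (band power = mean squared amplitude of the band-filtered
#' signal); `convention = "linear"` uses the plain power difference
#' instead. Output order follows the registry.
#'
#' @param trial a band-filtered [recording()] containing every registry
#'   electrode.
#' @param registry a [default_pair_registry()].
#' @param convention `"log"` (default) or `"linear"`.
#' @return Named numeric vector, one value per pair.
#' @export
bhaa_features <- function(trial, registry = default_pair_registry(),
                          convention = c("log", "linear")) {
  convention <- match.arg(convention)
  validate_recording(trial)
  missing <- setdiff(c(registry$left, registry$right), trial$channel_labels)
  if (length(missing))
    stop(sprintf("validation error: electrode(s) %s missing for pair registry",
                 paste(missing, collapse = ", ")))
  bp <- function(lab) mean(trial$data[match(lab, trial$channel_labels), ]^2)
  out <- vapply(seq_len(nrow(registry)), function(i) {
    pl <- bp(registry$left[i]); pr <- bp(registry$right[i])
    if (convention == "log") log(pmax(pl, 1e-300)) - log(pmax(pr, 1e-300))
    else pl - pr
  }, numeric(1))
  names(out) <- registry$name
  out
}

#' Full handcrafted feature vector for one trial
#'
#' Band-passes the trial into the four rhythms and concatenates, in
#' canonical order, per-rhythm-per-channel time-frequency and
#' nonlinear-dynamical features (named `{rhythm}_{channel}_{feature}`)
#' followed by per-rhythm asymmetry features (`{rhythm}_asym_{pair}`).
#' Total length is `4 * n * 18 + 4 * 14` -- 2360 dimensions for a
#' 32-channel trial, 4520 for 62 channels.
#'
#' @param trial a [recording()].
#' @param bands list of [band_definition()]s (default the four rhythms).
#' @param registry a [default_pair_registry()], or `NULL` to skip
#'   asymmetry features (montages without the registry electrodes).
#' @param nds_args list of extra arguments for [nds_features()].
#' @return Named numeric vector of length `4 * n * 18 + 56`.
#' @export
feature_vector <- function(trial, bands = default_bands(),
                           registry = default_pair_registry(),
                           nds_args = list()) {
  validate_recording(trial)
  out <- numeric(0)
  for (band in bands) {
    fb <- bandpass(trial, band)
    for (ci in seq_along(fb$channel_labels)) {
      x <- fb$data[ci, ]
      tf <- tfd_features(x, fb$fs)
      nd <- do.call(nds_features, c(list(x, fb$fs), nds_args))
      v <- c(tf, nd)
      names(v) <- paste(band$name, fb$channel_labels[ci], names(v), sep = "_")
      out <- c(out, v)
    }
    if (!is.null(registry)) {
      av <- bhaa_features(fb, registry)
      names(av) <- paste(band$name, "asym", names(av), sep = "_")
      out <- c(out, av)
    }
  }
  if (anyDuplicated(names(out))) stop("internal error: duplicate feature names")
  out
}
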