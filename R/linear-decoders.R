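#' Fit a PCA decoder
#'
#' Top-`m` principal directions of the sample covariance. Encoding projects
#' a centered channel vector onto the (orthonormal) component rows;
#' reconstruction is mean plus back-projection.
#'
#' @param data `N x n` matrix of time-sample channel vectors.
#' @param m number of components (`m <= n`).
#' @return `"LinearDecoderModel"` with `kind = "pca"`, `unmix` (`m x n`,
#'   orthonormal rows), `mix_back` (`n x m`), `center`, `eigenvalues` and
#'   `explained_variance_ratio`.
#' @export
fit_pca <- function(data, m) {
  data <- as.matrix(data)
  n <- ncol(data)
  if (m > n) stop("config error: m > n for PCA")
  center <- colMeans(data)
  Xc <- sweep(data, 2, center)
  C <- crossprod(Xc) / (nrow(data) - 1)
  eg <- eigen(C, symmetric = TRUE)
  P <- t(eg$vectors[, seq_len(m), drop = FALSE])   # m x n, orthonormal rows
  structure(list(kind = "pca", unmix = P, mix_back = t(P), center = center,
                 eigenvalues = eg$values,
                 explained_variance_ratio = eg$values / sum(eg$values),
                 component_order = seq_len(m), n = n, m = m),
            class = "LinearDecoderModel")
}

# symmetric fixed-point FastICA with logcosh nonlinearity on whitened data;
# Z is m x N (whitened), returns orthonormal m x m rotation
fastica_core <- function(Z, max_iter, tol) {
  m <- nrow(Z); N <- ncol(Z)
  W <- matrix(stats::rnorm(m * m), m, m)
  sym_decorrelate <- function(W) {
    sw <- eigen(W %*% t(W), symmetric = TRUE)
    solve_sqrt <- sw$vectors %*% diag(1 / sqrt(pmax(sw$values, 1e-12)),
                                      m) %*% t(sw$vectors)
    solve_sqrt %*% W
  }
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WX <- W %*% Z                       # m x N
    G <- tanh(WX)
    dG <- 1 - G^2
    W1 <- (G %*% t(Z)) / N - diag(rowMeans(dG), m) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  list(W = W, converged = converged, iterations = it)
}

#' Fit a FastICA decoder
#'
#' Blind source separation by FastICA: the data are centered, whitened and
#' reduced to `m` dimensions by eigendecomposition, then rotated by the
#' symmetric fixed-point iteration with the logcosh contrast. Because ICA
#' leaves component order and sign ambiguous, `n_runs` independent restarts
#' are retained so the channel-counterpart matching protocol
#' ([ica_reconstruction_protocol()]) can average over them.
#'
#' @param data `N x n` matrix of time-sample channel vectors (z-scored).
#' @param m number of components (`m <= n`).
#' @param seed RNG seed; the fit (all restarts) is deterministic given it.
#' @param n_runs independent restarts retained (default 10).
#' @param max_iter,tol fixed-point iteration controls.
#' @return `"LinearDecoderModel"` with `kind = "ica"`, `unmix` (`m x n`),
#'   `mix_back` (`n x m`, pseudo-inverse), `center`, and `restarts` (list of
#'   `unmix`/`mix_back` pairs, first entry = the primary fit).
#' @export
fit_ica <- function(data, m, seed = 1, n_runs = 10, max_iter = 200,
                    tol = 1e-6) {
  data <- as.matrix(data)
  n <- ncol(data); N <- nrow(data)
  if (m > n) stop("config error: m > n for ICA")
  center <- colMeans(data)
  Xc <- sweep(data, 2, center)
  C <- crossprod(Xc) / (N - 1)
  eg <- eigen(C, symmetric = TRUE)
  K <- diag(1 / sqrt(pmax(eg$values[seq_len(m)], 1e-12)), m) %*%
    t(eg$vectors[, seq_len(m), drop = FALSE])      # m x n whitening
  Z <- K %*% t(Xc)                                 # m x N
  set.seed(seed)
  restarts <- vector("list", n_runs)
  any_fail <- FALSE
  for (r in seq_len(n_runs)) {
    fit <- fastica_core(Z, max_iter, tol)
    if (!fit$converged) any_fail <- TRUE
    unmix <- fit$W %*% K                           # m x n
    restarts[[r]] <- list(unmix = unmix, mix_back = pracma::pinv(unmix),
                          converged = fit$converged,
                          iterations = fit$iterations)
  }
  if (any_fail)
    warning("FastICA did not converge in max_iter for some restart(s); best iterate returned")
  structure(list(kind = "ica", unmix = restarts[[1]]$unmix,
                 mix_back = restarts[[1]]$mix_back, center = center,
                 restarts = restarts, component_order = seq_len(m),
                 n = n, m = m),
            class = "LinearDecoderModel")
}

#' @export
print.LinearDecoderModel <- function(x, ...) {
  cat(sprintf("<LinearDecoderModel> %s: n=%d m=%d%s\n", x$kind, x$n, x$m,
              if (x$kind == "ica") sprintf(" (%d restarts)",
                                           length(x$restarts)) else ""))
  invisible(x)
}

#' Match reconstructed channels to their originals by maximum correlation
#'
#' For each original channel, finds the reconstructed signal with the
#' highest Pearson correlation and reports that correlation -- the
#' admittedly crude counterpart rule used when component order is ambiguous
#' (duplicates permitted; ties broken by lowest index). `strict = TRUE`
#' instead builds a one-to-one assignment greedily by descending
#' correlation, which recovers the exact permutation whenever each channel's
#' true counterpart dominates its row.
#'
#' @param original,reconstructed [recording()]s with identical dimensions.
#' @param strict logical; one-to-one matching instead of free matching.
#' @return List with `matched_r` (named per original channel), `map`
#'   (index of the chosen reconstructed signal per original channel) and
#'   `mean_r`.
#' @export
ica_match_channels <- function(original, reconstructed, strict = FALSE) {
  validate_recording(original); validate_recording(reconstructed)
  if (!all(dim(original$data) == dim(reconstructed$data)))
    stop("validation error: original and reconstructed dimensions differ")
  n <- nrow(original$data)
  R <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    R[i, j] <- pearson_r(original$data[i, ], reconstructed$data[j, ],
                         warn = FALSE)
  map <- integer(n); matched <- numeric(n)
  if (!strict) {
    for (i in seq_len(n)) {
      map[i] <- which.max(R[i, ])          # which.max takes the lowest index on ties
      matched[i] <- R[i, map[i]]
    }
  } else {
    free <- rep(TRUE, n)
    ord <- order(-apply(R, 1, max, na.rm = TRUE))
    for (i in ord) {
      j <- which(R[i, ] == max(R[i, free], na.rm = TRUE) & free)[1]
      map[i] <- j; matched[i] <- R[i, j]; free[j] <- FALSE
    }
  }
  names(matched) <- original$channel_labels
  list(matched_r = matched, map = map, mean_r = mean(matched))
}

#' Run the ICA reconstruction-evaluation protocol
#'
#' Reconstructs the recording through each retained FastICA restart,
#' applies the counterpart-matching rule of [ica_match_channels()], and
#' averages the matched per-channel correlations over restarts to stabilize
#' the estimate.
#'
#' @param model an ICA `"LinearDecoderModel"` from [fit_ica()].
#' @param rec a [recording()] (z-scored as at fit time).
#' @param strict passed to [ica_match_channels()].
#' @return List with `per_channel_r` (restart-averaged, named) and `mean_r`.
#' @export
ica_reconstruction_protocol <- function(model, rec, strict = FALSE) {
  stopifnot(inherits(model, "LinearDecoderModel"), model$kind == "ica")
  validate_recording(rec)
  acc <- 0
  for (rs in model$restarts) {
    Xc <- sweep(t(rec$data), 2, model$center)      # t x n
    recon <- t(Xc %*% t(rs$unmix) %*% t(rs$mix_back)) +
      model$center                                  # n x t
    rrec <- recording(recon, rec$channel_labels, rec$fs,
                      subject_id = rec$subject_id, trial_id = rec$trial_id)
    acc <- acc + ica_match_channels(rec, rrec, strict = strict)$matched_r
  }
  per <- acc / length(model$restarts)
  list(per_channel_r = per, mean_r = mean(per))
}
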