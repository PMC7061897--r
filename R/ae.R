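#' Fit a one-hidden-layer autoencoder on per-sample channel vectors
#'
#' The encoder maps a channel vector `x` (one time sample, z-scored) to `m`
#' latent activations `h = f(W1 x + b1)`; the decoder reconstructs
#' `x_hat = g(W2 h + b2)`. Parameters minimize the mean squared
#' reconstruction error by backpropagation with the Adam optimizer. Encoder
#' and decoder weights are untied. With linear activations the optimum
#' coincides with the rank-`m` principal subspace projection, which the test
#' suite uses as an independent oracle.
#'
#' @param data `N x n` numeric matrix of pooled time-sample channel vectors
#'   (rows = samples), expected z-scored.
#' @param m number of latent factors (>= 1). `m > n` is allowed
#'   (over-complete) but warned about.
#' @param epochs training epochs (default 20, which suffices to reach a loss
#'   plateau at the default batch size on data of this kind).
#' @param batch minibatch size (default 500).
#' @param lr Adam learning rate.
#' @param seed RNG seed; the fit is deterministic given it.
#' @param lr_decay epoch-wise 1/t learning-rate decay factor (default 0.1).
#' @param hidden_activation `"tanh"` (default), `"sigmoid"` or `"linear"`.
#' @param output_activation `"linear"` (default; z-scored targets are
#'   unbounded).
#' @return An object of class `"AEModel"`: weights `W1` (`m x n`), `b1`,
#'   `W2` (`n x m`), `b2`, activation tags, and `losses` (per-epoch mean
#'   squared error).
#' @export
fit_ae <- function(data, m, epochs = 20, batch = 500, lr = 0.01, seed = 1,
                   hidden_activation = "tanh", output_activation = "linear",
                   lr_decay = 0.1) {
  data <- as.matrix(data)
  N <- nrow(data); n <- ncol(data)
  stopifnot(m >= 1, N >= 1)
  if (batch > N) batch <- N
  if (m > n) warning(sprintf("over-complete autoencoder: m=%d > n=%d", m, n))
  set.seed(seed)
  params <- list(W1 = glorot(m, n), b1 = rep(0, m),
                 W2 = glorot(n, m), b2 = rep(0, n))
  model <- ae_train(params, data, epochs, batch, lr,
                    hidden_activation, output_activation, optimizer = "adam",
                    lr_decay = lr_decay)
  structure(c(model, list(n = n, m = m,
                          hidden_activation = hidden_activation,
                          output_activation = output_activation)),
            class = "AEModel")
}

# shared trainer (also used for GRBM unroll fine-tuning)
ae_train <- function(params, data, epochs, batch, lr, hidden_activation,
                     output_activation, optimizer = "adam", lr_decay = 0.1) {
  N <- nrow(data)
  hact <- act_fun(hidden_activation); oact <- act_fun(output_activation)
  opt <- opt_init(optimizer, params, lr = lr)
  losses <- numeric(0)
  for (ep in seq_len(max(epochs, 0))) {
    opt$lr <- lr / (1 + lr_decay * (ep - 1))   # 1/t decay sharpens the plateau
    ep_loss <- 0; nb <- 0L
    for (idx in minibatches(N, batch)) {
      X <- data[idx, , drop = FALSE]
      B <- nrow(X)
      H <- hact$f(sweep(X %*% t(params$W1), 2, params$b1, "+"))
      XH <- oact$f(sweep(H %*% t(params$W2), 2, params$b2, "+"))
      err <- XH - X
      loss <- mean(err^2)
      check_finite_loss(loss, "autoencoder training")
      dout <- (2 / length(err)) * err * oact$df(XH)
      grads <- list(
        W1 = NULL, b1 = NULL,
        W2 = t(dout) %*% H, b2 = colSums(dout))
      dH <- (dout %*% params$W2) * hact$df(H)
      grads$W1 <- t(dH) %*% X
      grads$b1 <- colSums(dH)
      st <- opt_step(opt, params, grads)
      opt <- st$opt; params <- st$params
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    losses <- c(losses, ep_loss / nb)
  }
  list(W1 = params$W1, b1 = params$b1, W2 = params$W2, b2 = params$b2,
       losses = losses)
}

ae_forward_hidden <- function(model, X) {
  hact <- act_fun(model$hidden_activation)
  hact$f(sweep(X %*% t(model$W1), 2, model$b1, "+"))
}

ae_forward_out <- function(model, H) {
  oact <- act_fun(model$output_activation)
  oact$f(sweep(H %*% t(model$W2), 2, model$b2, "+"))
}

#' @export
print.AEModel <- function(x, ...) {
  cat(sprintf("<AEModel> n=%d m=%d (%s hidden, %s output), %d epochs, final loss %.4g\n",
              x$n, x$m, x$hidden_activation, x$output_activation,
              length(x$losses),
              if (length(x$losses)) tail(x$losses, 1) else NA))
  invisible(x)
}
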