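#' Fit a Gaussian-Bernoulli restricted Boltzmann machine by CD-k
#'
#' Real-valued Gaussian visible units model the z-scored channel vector;
#' binary stochastic hidden units are the latent factors. The joint density
#' is the Boltzmann distribution of the energy
#' \deqn{E(x,h) = \sum_i (x_i - a_i)^2 / (2\sigma_i^2) - \sum_j b_j h_j
#'   - \sum_{ij} (x_i/\sigma_i) W_{ij} h_j}
#' whose conditionals are \eqn{P(h_j = 1 | x) = \mathrm{logistic}(\sum_i
#' W_{ij} x_i/\sigma_i + b_j)} and \eqn{x_i | h \sim N(a_i + \sigma_i \sum_j
#' W_{ij} h_j, \sigma_i^2)}. The intractable partition function is
#' sidestepped by contrastive divergence with `cd_k` truncated Gibbs steps;
#' updates use plain SGD with momentum. Visible scales `sigma` are fixed at
#' 1 (inputs are z-scored).
#'
#' @param data `N x n` matrix of pooled z-scored time-sample vectors.
#' @param m number of hidden (latent) units.
#' @param cd_k Gibbs steps per update (>= 1; default 1).
#' @param epochs,lr,momentum,batch SGD schedule (defaults: 10 epochs,
#'   lr 0.01, momentum 0.5, batch 500).
#' @param seed RNG seed; fit is deterministic given it.
#' @param sigma per-visible scale vector (> 0), default all 1.
#' @return `"GRBMModel"`: `W` (`n x m`), visible biases `a`, hidden biases
#'   `b`, `sigma`, and `losses` (per-epoch mean-field reconstruction MSE).
#' @export
fit_grbm <- function(data, m, cd_k = 1, epochs = 10, lr = 0.01,
                     momentum = 0.5, batch = 500, seed = 1, sigma = NULL) {
  data <- as.matrix(data)
  N <- nrow(data); n <- ncol(data)
  stopifnot(m >= 1, cd_k >= 1)
  if (is.null(sigma)) sigma <- rep(1, n)
  if (any(sigma <= 0)) stop("config error: sigma must be positive")
  if (batch > N) batch <- N
  set.seed(seed)
  params <- list(W = 0.01 * matrix(stats::rnorm(n * m), n, m),
                 a = rep(0, n), b = rep(0, m))
  vel <- zeros_like(params)
  losses <- numeric(0)
  Xs <- sweep(data, 2, sigma, "/")
  for (ep in seq_len(epochs)) {
    ep_loss <- 0; nb <- 0L
    for (idx in minibatches(N, batch)) {
      v0 <- data[idx, , drop = FALSE]
      v0s <- Xs[idx, , drop = FALSE]
      B <- nrow(v0)
      ph0 <- sigmoid(sweep(v0s %*% params$W, 2, params$b, "+"))
      hk <- (matrix(stats::runif(B * m), B, m) < ph0) * 1
      vk <- v0
      for (k in seq_len(cd_k)) {
        # mean-field visibles (stable CD variant), sampled hiddens
        vk <- sweep(hk %*% t(params$W) * rep(sigma, each = B), 2, params$a, "+")
        phk <- sigmoid(sweep(sweep(vk, 2, sigma, "/") %*% params$W, 2,
                             params$b, "+"))
        if (k < cd_k) hk <- (matrix(stats::runif(B * m), B, m) < phk) * 1
      }
      vks <- sweep(vk, 2, sigma, "/")
      gW <- (t(v0s) %*% ph0 - t(vks) %*% phk) / B
      ga <- colMeans(v0 - vk)
      gb <- colMeans(ph0 - phk)
      vel$W <- momentum * vel$W + lr * gW
      vel$a <- momentum * vel$a + lr * ga
      vel$b <- momentum * vel$b + lr * gb
      params$W <- params$W + vel$W
      params$a <- params$a + vel$a
      params$b <- params$b + vel$b
      # mean-field reconstruction error from the data-driven hidden probs
      recon <- sweep(ph0 %*% t(params$W) * rep(sigma, each = B), 2,
                     params$a, "+")
      loss <- mean((v0 - recon)^2)
      check_finite_loss(loss, "GRBM CD training")
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    losses <- c(losses, ep_loss / nb)
  }
  structure(list(W = params$W, a = params$a, b = params$b, sigma = sigma,
                 n = n, m = m, cd_k = cd_k, losses = losses),
            class = "GRBMModel")
}

#' GRBM conditionals and energy
#'
#' `grbm_hidden_prob` evaluates \eqn{P(h_j = 1 | x)} for a batch of visible
#' vectors; `grbm_visible_mean` the conditional mean of `x | h`;
#' `grbm_energy` the Gaussian-visible energy for one `(x, h)` pair (used by
#' the exhaustive-enumeration tests).
#'
#' @param model a `"GRBMModel"`.
#' @param X `N x n` visible matrix.
#' @return `grbm_hidden_prob`: `N x m` matrix of probabilities.
#' @export
grbm_hidden_prob <- function(model, X) {
  X <- matrix(X, ncol = model$n)
  sigmoid(sweep(sweep(X, 2, model$sigma, "/") %*% model$W, 2, model$b, "+"))
}

#' @rdname grbm_hidden_prob
#' @param H `N x m` hidden matrix (0/1 or probabilities).
#' @export
grbm_visible_mean <- function(model, H) {
  H <- matrix(H, ncol = model$m)
  sweep(H %*% t(model$W) * rep(model$sigma, each = nrow(H)), 2, model$a, "+")
}

#' @rdname grbm_hidden_prob
#' @param x visible vector (length n).
#' @param h hidden 0/1 vector (length m).
#' @export
grbm_energy <- function(model, x, h) {
  sum((x - model$a)^2 / (2 * model$sigma^2)) - sum(model$b * h) -
    sum((x / model$sigma) * (model$W %*% h))
}

#' Unroll a trained GRBM into an autoencoder and fine-tune it
#'
#' The GRBM is unrolled into a symmetric autoencoder -- encoder
#' `W1 = t(W)`, `b1 = b` with sigmoid hidden units, decoder `W2 = W`,
#' `b2 = a` with linear output -- so that with zero fine-tuning epochs the
#' AE reproduces the GRBM's deterministic mean-field reconstruction exactly.
#' The unrolled parameters are then fine-tuned on mean squared
#' reconstruction error by backpropagation (Adam).
#'
#' @param model a fitted `"GRBMModel"` with unit `sigma`.
#' @param data `N x n` z-scored training matrix.
#' @param epochs fine-tuning epochs (0 = pure unrolling).
#' @param batch,lr,seed as in [fit_ae()].
#' @return An `"AEModel"` (sigmoid hidden, linear output).
#' @export
grbm_unroll_finetune <- function(model, data, epochs = 10, batch = 500,
                                 lr = 0.01, seed = 1) {
  stopifnot(inherits(model, "GRBMModel"))
  if (any(abs(model$sigma - 1) > 1e-12))
    stop("unrolling assumes unit visible scales (z-scored data)")
  data <- as.matrix(data)
  set.seed(seed)
  params <- list(W1 = t(model$W), b1 = model$b, W2 = model$W, b2 = model$a)
  if (epochs > 0) {
    fit <- ae_train(params, data, epochs, min(batch, nrow(data)), lr,
                    "sigmoid", "linear", optimizer = "adam")
  } else {
    fit <- c(params, list(losses = numeric(0)))
  }
  structure(c(fit[c("W1", "b1", "W2", "b2", "losses")],
              list(n = model$n, m = model$m,
                   hidden_activation = "sigmoid",
                   output_activation = "linear")),
            class = "AEModel")
}

#' @export
print.GRBMModel <- function(x, ...) {
  cat(sprintf("<GRBMModel> n=%d m=%d CD-%d, %d epochs, final recon MSE %.4g\n",
              x$n, x$m, x$cd_k, length(x$losses),
              if (length(x$losses)) tail(x$losses, 1) else NA))
  invisible(x)
}
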