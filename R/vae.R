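#' Closed-form Gaussian KL divergence of the variational posterior
#'
#' For a diagonal-Gaussian posterior `N(mu, diag(sigma^2))` against the
#' standard-normal prior, the KL divergence has the closed form
#' \deqn{D_{KL} = -\tfrac12 \sum_j (1 + \log\sigma_j^2 - \mu_j^2 -
#'   \sigma_j^2),} which is exactly 0 when `mu = 0, sigma = 1`.
#'
#' @param mu matrix (`N x m`) or vector of posterior means.
#' @param log_var matching matrix/vector of posterior log-variances.
#' @return Per-row KL divergence (vector of length `N`), always >= 0.
#' @export
vae_kl <- function(mu, log_var) {
  mu <- rbind(mu); log_var <- rbind(log_var)
  as.numeric(-0.5 * rowSums(1 + log_var - mu^2 - exp(log_var)))
}

#' Reparameterized Gaussian draw
#'
#' `z = mu + sigma * eps` with `eps ~ N(0, I)`, the change of variables
#' that lets gradients flow through the sampling step.
#'
#' @param mu,sigma matrices (`N x m`) of posterior means / sds.
#' @param eps optional pre-drawn standard-normal matrix; drawn if missing.
#' @return Matrix of latent draws, same shape as `mu`.
#' @export
reparameterize <- function(mu, sigma, eps = NULL) {
  if (is.null(eps)) eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  mu + sigma * eps
}

#' Fit a variational autoencoder on per-sample channel vectors
#'
#' One-hidden-layer architecture in which the latent layer itself is the
#' hidden layer: the encoder computes `mu = Wmu x + bmu` and
#' `log sigma^2 = Wlv x + blv`; the decoder maps a latent draw back with
#' `x_hat = Wd z + bd`. Training maximizes the variational lower bound
#' (ELBO): a Gaussian reconstruction likelihood with fixed unit observation
#' variance (so the likelihood term reduces to a scaled squared error) minus
#' the closed-form KL term of [vae_kl()]. Latent draws use the
#' reparameterization trick with `L` Monte Carlo samples (default 1, the
#' common minimum). Optimized by RMSprop.
#'
#' @param data `N x n` z-scored matrix of time-sample channel vectors.
#' @param m latent dimensionality `J`.
#' @param epochs,batch,lr training schedule (defaults 20 / 500 / 0.003).
#' @param seed RNG seed; fit is deterministic given it.
#' @param L Monte Carlo samples per datapoint (>= 1).
#' @return `"VAEModel"` with encoder/decoder weights and per-epoch `losses`
#'   (negative ELBO), plus `recon_losses` and `kl_losses` logged separately.
#' @export
fit_vae <- function(data, m, epochs = 20, batch = 500, lr = 0.003, seed = 1,
                    L = 1) {
  data <- as.matrix(data)
  N <- nrow(data); n <- ncol(data)
  stopifnot(m >= 1)
  if (L < 1) stop("config error: L must be >= 1")
  if (batch > N) batch <- N
  set.seed(seed)
  params <- list(Wmu = glorot(m, n), bmu = rep(0, m),
                 Wlv = 0.01 * glorot(m, n), blv = rep(0, m),
                 Wd = glorot(n, m), bd = rep(0, n))
  opt <- opt_init("rmsprop", params, lr = lr)
  losses <- rl <- kl <- numeric(0)
  for (ep in seq_len(epochs)) {
    ep_loss <- ep_r <- ep_k <- 0; nb <- 0L
    for (idx in minibatches(N, batch)) {
      X <- data[idx, , drop = FALSE]
      B <- nrow(X)
      mu <- sweep(X %*% t(params$Wmu), 2, params$bmu, "+")
      lv <- pmin(pmax(sweep(X %*% t(params$Wlv), 2, params$blv, "+"), -10), 10)
      sg <- exp(0.5 * lv)
      gmu <- matrix(0, B, m); glv <- matrix(0, B, m)
      gWd <- matrix(0, n, m); gbd <- rep(0, n)
      recon_term <- 0
      for (l in seq_len(L)) {
        eps <- matrix(stats::rnorm(B * m), B, m)
        z <- mu + sg * eps
        xh <- sweep(z %*% t(params$Wd), 2, params$bd, "+")
        err <- xh - X                              # d(0.5*sum err^2)/dxh
        recon_term <- recon_term + 0.5 * sum(err^2) / B
        dz <- err %*% params$Wd
        gWd <- gWd + t(err) %*% z
        gbd <- gbd + colSums(err)
        gmu <- gmu + dz
        glv <- glv + dz * sg * eps * 0.5
      }
      recon_term <- recon_term / L
      kl_term <- mean(vae_kl(mu, lv))
      loss <- recon_term + kl_term
      check_finite_loss(loss, "VAE training")
      # KL gradients: d/dmu = mu, d/dlv = 0.5*(sigma^2 - 1)
      gmu <- gmu / L + mu
      glv <- glv / L + 0.5 * (exp(lv) - 1)
      grads <- list(
        Wmu = t(gmu) %*% X / B, bmu = colMeans(gmu),
        Wlv = t(glv) %*% X / B, blv = colMeans(glv),
        Wd = gWd / (L * B), bd = gbd / (L * B))
      st <- opt_step(opt, params, grads)
      opt <- st$opt; params <- st$params
      ep_loss <- ep_loss + loss; ep_r <- ep_r + recon_term
      ep_k <- ep_k + kl_term; nb <- nb + 1L
    }
    losses <- c(losses, ep_loss / nb)
    rl <- c(rl, ep_r / nb); kl <- c(kl, ep_k / nb)
  }
  structure(c(params, list(n = n, m = m, L = L, losses = losses,
                           recon_losses = rl, kl_losses = kl)),
            class = "VAEModel")
}

vae_encode_mu <- function(model, X)
  sweep(X %*% t(model$Wmu), 2, model$bmu, "+")

vae_decode_mean <- function(model, Z)
  sweep(Z %*% t(model$Wd), 2, model$bd, "+")

#' @export
print.VAEModel <- function(x, ...) {
  cat(sprintf("<VAEModel> n=%d m=%d L=%d, %d epochs, final -ELBO %.4g (recon %.4g + KL %.4g)\n",
              x$n, x$m, x$L, length(x$losses),
              if (length(x$losses)) tail(x$losses, 1) else NA,
              if (length(x$losses)) tail(x$recon_losses, 1) else NA,
              if (length(x$losses)) tail(x$kl_losses, 1) else NA))
  invisible(x)
}
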