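# Shared neural-network primitives: parameter init, activations, and
# first-order optimizers (Adam, RMSprop, SGD+momentum) operating on named
# lists of numeric arrays. All training code in the package routes through
# these so that fits are bit-reproducible given (data, config, seed).

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

act_fun <- function(tag) {
  switch(tag,
         linear = list(f = identity, df = function(a) 1),
         tanh = list(f = tanh, df = function(a) 1 - a^2),
         sigmoid = list(f = function(x) 1 / (1 + exp(-x)),
                        df = function(a) a * (1 - a)),
         relu = list(f = function(x) pmax(x, 0),
                     df = function(a) (a > 0) * 1),
         stop(sprintf("unknown activation '%s'", tag)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

zeros_like <- function(params) lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))

`%||%` <- function(a, b) if (is.null(a)) b else a

opt_init <- function(kind = c("adam", "rmsprop", "sgd_momentum"), params,
                     lr = 1e-3, beta1 = 0.9, beta2 = 0.999, rho = 0.9,
                     momentum = 0.5, eps = 1e-8) {
  kind <- match.arg(kind)
  list(kind = kind, lr = lr, beta1 = beta1, beta2 = beta2, rho = rho,
       momentum = momentum, eps = eps, t = 0L,
       m = zeros_like(params), v = zeros_like(params))
}

opt_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  for (k in names(params)) {
    g <- grads[[k]]
    if (opt$kind == "adam") {
      opt$m[[k]] <- opt$beta1 * opt$m[[k]] + (1 - opt$beta1) * g
      opt$v[[k]] <- opt$beta2 * opt$v[[k]] + (1 - opt$beta2) * g^2
      mhat <- opt$m[[k]] / (1 - opt$beta1^opt$t)
      vhat <- opt$v[[k]] / (1 - opt$beta2^opt$t)
      params[[k]] <- params[[k]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    } else if (opt$kind == "rmsprop") {
      opt$v[[k]] <- opt$rho * opt$v[[k]] + (1 - opt$rho) * g^2
      params[[k]] <- params[[k]] - opt$lr * g / (sqrt(opt$v[[k]]) + opt$eps)
    } else {
      opt$m[[k]] <- opt$momentum * opt$m[[k]] - opt$lr * g
      params[[k]] <- params[[k]] + opt$m[[k]]
    }
  }
  list(opt = opt, params = params)
}

# epoch-shuffled minibatch index list
minibatches <- function(N, batch) {
  idx <- sample.int(N)
  split(idx, ceiling(seq_along(idx) / batch))
}

check_finite_loss <- function(loss, what) {
  if (!is.finite(loss))
    stop(sprintf("training error: non-finite loss in %s (lr too high or bad input scaling)", what))
  loss
}
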