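#' Train a handcrafted-feature baseline classifier
#'
#' The roster mirrors the standard comparison set: `svm_l1` (linear SVM
#' with an L1 penalty, in-package proximal subgradient solver for the
#' objective `sum_i hinge_i + C * ||w||_1`; zero-weight features are
#' reported as eliminated), `rf` (random forest, 100 trees), `knn`
#' (k-nearest neighbours, 7 neighbours), `lr` (logistic regression), `nb`
#' (Gaussian naive Bayes) and `dnn` (a 3 x 100 rectified-linear MLP with
#' softmax head). All except `svm_l1` and `dnn` are thin wrappers over the
#' established implementations.
#'
#' @param features numeric matrix, rows = trials, finite entries.
#' @param labels character vector with exactly two classes.
#' @param kind one of `"svm_l1"`, `"rf"`, `"knn"`, `"lr"`, `"nb"`,
#'   `"dnn"`.
#' @param params named list of kind-specific parameters: `C` (svm_l1
#'   penalty weight, default 0.01), `ntree` (rf), `k` (knn), `hidden`
#'   (dnn layer sizes), `epochs`, `lr`, `seed`.
#' @param positive_class label treated as positive (default
#'   `"positive"`).
#' @return A `"BaselineModel"`; for `svm_l1` it carries `w`, `w0`,
#'   `eliminated` (names/indices of zero-weight features) and `nnz`.
#' @export
train_baseline <- function(features, labels,
                           kind = c("svm_l1", "rf", "knn", "lr", "nb", "dnn"),
                           params = list(), positive_class = "positive") {
  kind <- match.arg(kind)
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop("validation error: non-finite features")
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2) stop("validation error: need exactly 2 classes")
  neg <- setdiff(cls, positive_class)
  y <- ifelse(labels == positive_class, 1, -1)
  seed <- params$seed %||% 1
  fit <- switch(kind,
    svm_l1 = svm_l1_fit(features, y, C = params$C %||% 0.01,
                        iters = params$iters %||% 5000,
                        lr0 = params$lr %||% NULL),
    rf = {
      set.seed(seed)
      randomForest::randomForest(features, factor(labels),
                                 ntree = params$ntree %||% 100)
    },
    knn = list(train = features, labels = labels, k = params$k %||% 7),
    lr = {
      df <- data.frame(y = factor(labels), features)
      suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    },
    nb = e1071::naiveBayes(features, factor(labels)),
    dnn = mlp_fit(features, y, hidden = params$hidden %||% c(100, 100, 100),
                  epochs = params$epochs %||% 50,
                  batch = params$batch %||% 32,
                  lr = params$lr %||% 0.001, seed = seed))
  structure(list(kind = kind, fit = fit, classes = cls,
                 positive_class = positive_class, negative_class = neg,
                 feature_names = colnames(features)),
            class = "BaselineModel")
}

#' @export
predict.BaselineModel <- function(object, features, ...) {
  features <- as.matrix(features)
  pos <- object$positive_class; neg <- object$negative_class
  switch(object$kind,
    svm_l1 = ifelse(drop(features %*% object$fit$w) + object$fit$w0 >= 0,
                    pos, neg),
    rf = as.character(predict(object$fit, features)),
    knn = as.character(class::knn(object$fit$train, features,
                                  factor(object$fit$labels),
                                  k = object$fit$k)),
    lr = {
      p <- stats::predict(object$fit, data.frame(features), type = "response")
      lev <- levels(object$fit$model$y)
      ifelse(p >= 0.5, lev[2], lev[1])
    },
    nb = as.character(predict(object$fit, features)),
    dnn = ifelse(mlp_forward(object$fit, features) >= 0, pos, neg))
}

# ---- L1-penalized linear SVM --------------------------------------------
# minimize sum_i hinge(y_i (w0 + w.x_i)) + C * ||w||_1, with the hinge
# Huber-smoothed (parameter delta) so a convergent proximal-gradient (ISTA)
# scheme applies; the proximal step produces exact zero patterns and the
# smoothing can be made arbitrarily tight. Intercept unpenalized.
svm_l1_fit <- function(X, y, C, iters = 2000, lr0 = NULL, w_init = NULL,
                       w0_init = 0, delta = 0.1, tol = 1e-8) {
  n <- nrow(X); q <- ncol(X)
  w <- w_init %||% rep(0, q); w0 <- w0_init
  # smoothed hinge: 0 for m >= 1; 1 - m - delta/2 for m <= 1 - delta;
  # (1 - m)^2 / (2 delta) between. Gradient wrt the margin m below.
  dhinge <- function(m) ifelse(m >= 1, 0,
                               ifelse(m <= 1 - delta, -1, -(1 - m) / delta))
  obj <- function(w, w0) {
    m <- y * (drop(X %*% w) + w0)
    h <- ifelse(m >= 1, 0,
                ifelse(m <= 1 - delta, 1 - m - delta / 2,
                       (1 - m)^2 / (2 * delta)))
    sum(h) + C * sum(abs(w))
  }
  # Lipschitz constant of the smooth part via the top singular value of [X 1]
  Xa <- cbind(X, 1)
  s1 <- sqrt(top_eigval(crossprod(Xa)))
  L <- s1^2 / delta
  step <- 1 / L
  prev <- obj(w, w0)
  # FISTA acceleration over the extrapolated point (vw, vw0)
  vw <- w; vw0 <- w0; tk <- 1
  for (t in seq_len(iters)) {
    marg <- y * (drop(X %*% vw) + vw0)
    d <- dhinge(marg) * y
    gw <- drop(crossprod(X, d))
    g0 <- sum(d)
    w_new <- soft_threshold(vw - step * gw, step * C)
    w0_new <- vw0 - step * g0
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    vw <- w_new + ((tk - 1) / tk_new) * (w_new - w)
    vw0 <- w0_new + ((tk - 1) / tk_new) * (w0_new - w0)
    w <- w_new; w0 <- w0_new; tk <- tk_new
    if (t %% 50 == 0) {
      cur <- obj(w, w0)
      if (abs(prev - cur) < tol * max(1, abs(cur))) break
      prev <- cur
    }
  }
  nz <- abs(w) > 1e-8
  list(w = w, w0 = w0, objective = obj(w, w0), nnz = sum(nz),
       eliminated = which(!nz), C = C)
}

top_eigval <- function(A, iters = 100) {
  v <- rep(1, ncol(A))
  lam <- 0
  for (i in seq_len(iters)) {
    v <- drop(A %*% v)
    nl <- sqrt(sum(v^2))
    if (nl == 0) return(0)
    v <- v / nl
    if (abs(nl - lam) < 1e-10 * max(1, lam)) { lam <- nl; break }
    lam <- nl
  }
  lam
}

soft_threshold <- function(x, lam) sign(x) * pmax(abs(x) - lam, 0)

#' Sparsity path of the L1-penalized SVM
#'
#' Refits the L1-SVM along a grid of penalty weights `C` (warm-started
#' from large to small penalties) and reports the nonzero-weight count at
#' each, tracing how the L1 penalty prunes the feature set.
#'
#' @param features,labels as in [train_baseline()].
#' @param C_grid penalty weights; fitted in decreasing order.
#' @param positive_class positive label.
#' @param iters solver iterations per grid point.
#' @return data.frame with columns `C` and `nnz`, ordered by decreasing
#'   `C`.
#' @export
svm_l1_path <- function(features, labels, C_grid, positive_class = "positive",
                        iters = 5000) {
  X <- as.matrix(features)
  y <- ifelse(as.character(labels) == positive_class, 1, -1)
  C_grid <- sort(C_grid, decreasing = TRUE)
  w <- rep(0, ncol(X)); w0 <- 0
  nnz <- integer(length(C_grid))
  for (i in seq_along(C_grid)) {
    fit <- svm_l1_fit(X, y, C_grid[i], iters = iters, w_init = w,
                      w0_init = w0)
    w <- fit$w; w0 <- fit$w0
    nnz[i] <- fit$nnz
  }
  data.frame(C = C_grid, nnz = nnz)
}

# ---- minimal MLP (relu stack + 2-way softmax margin head) ----------------
mlp_fit <- function(X, y, hidden, epochs, batch, lr, seed) {
  set.seed(seed)
  sizes <- c(ncol(X), hidden, 1)
  W <- lapply(seq_len(length(sizes) - 1), function(i)
    glorot(sizes[i], sizes[i + 1]))
  b <- lapply(seq_len(length(sizes) - 1), function(i) rep(0, sizes[i + 1]))
  params <- c(setNames(W, paste0("W", seq_along(W))),
              setNames(b, paste0("b", seq_along(b))))
  L <- length(W)
  opt <- opt_init("adam", params, lr = lr)
  N <- nrow(X)
  for (ep in seq_len(epochs)) {
    for (idx in minibatches(N, min(batch, N))) {
      Xi <- X[idx, , drop = FALSE]; yi <- y[idx]
      A <- vector("list", L + 1); A[[1]] <- Xi
      for (l in seq_len(L)) {
        Z <- sweep(A[[l]] %*% params[[paste0("W", l)]], 2,
                   params[[paste0("b", l)]], "+")
        A[[l + 1]] <- if (l < L) pmax(Z, 0) else Z
      }
      s <- drop(A[[L + 1]])
      # logistic margin loss on the scalar score
      p <- sigmoid(yi * s)
      dZ <- matrix(-yi * (1 - p) / length(yi), ncol = 1)
      grads <- params
      for (l in rev(seq_len(L))) {
        grads[[paste0("W", l)]] <- t(A[[l]]) %*% dZ
        grads[[paste0("b", l)]] <- colSums(dZ)
        if (l > 1) dZ <- (dZ %*% t(params[[paste0("W", l)]])) * (A[[l]] > 0)
      }
      st <- opt_step(opt, params, grads)
      opt <- st$opt; params <- st$params
    }
  }
  list(params = params, L = L)
}

mlp_forward <- function(fit, X) {
  A <- X
  for (l in seq_len(fit$L)) {
    Z <- sweep(A %*% fit$params[[paste0("W", l)]], 2,
               fit$params[[paste0("b", l)]], "+")
    A <- if (l < fit$L) pmax(Z, 0) else Z
  }
  drop(A)
}
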