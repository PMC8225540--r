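# Feed-forward network regressor: two ReLU hidden layers, inverted dropout,
# full-batch ADAM on the mean-squared error. Inputs and target are
# standardized internally; predictions are returned on the original scale.

.nn_init <- function(p, hidden, seed) {
  set.seed(seed)
  sizes <- c(p, hidden, 1L)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    # He initialization for ReLU layers
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0,
                                  sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

.nn_forward <- function(par, X, dropout = 0, rng = FALSE) {
  L <- length(par$W)
  A <- X
  cache <- list(A0 = X)
  for (l in seq_len(L - 1)) {
    Z <- sweep(A %*% par$W[[l]], 2, par$b[[l]], "+")
    A <- pmax(Z, 0)
    if (rng && dropout > 0) {
      mask <- matrix(stats::runif(length(A)) >= dropout, nrow(A), ncol(A))
      A <- A * mask / (1 - dropout)
      cache[[paste0("M", l)]] <- mask
    }
    cache[[paste0("Z", l)]] <- Z
    cache[[paste0("A", l)]] <- A
  }
  out <- drop(sweep(A %*% par$W[[L]], 2, par$b[[L]], "+"))
  cache$out <- out
  cache
}

.nn_backward <- function(par, cache, y, dropout) {
  L <- length(par$W)
  n <- length(y)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- matrix(2 * (cache$out - y) / n, n, 1)
  for (l in L:1) {
    A_prev <- cache[[paste0("A", l - 1)]] %||% cache$A0
    gW[[l]] <- crossprod(A_prev, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(par$W[[l]])
      mask <- cache[[paste0("M", l - 1)]]
      if (!is.null(mask)) delta <- delta * mask / (1 - dropout)
      delta <- delta * (cache[[paste0("Z", l - 1)]] > 0)
    }
  }
  list(W = gW, b = gb)
}

# ADAM with early stopping on a held-out set; returns the best weights seen
.nn_train <- function(x, y, hidden = c(500L, 500L), dropout = 0.3,
                      epochs = 500L, lr = 1e-3, patience = 25L,
                      val_frac = 0.15, seed = 1L) {
  x <- as.matrix(x)
  mu_x <- colMeans(x); sd_x <- pmax(apply(x, 2, stats::sd), 1e-12)
  mu_y <- mean(y); sd_y <- max(stats::sd(y), 1e-12)
  Xs <- sweep(sweep(x, 2, mu_x), 2, sd_x, "/")
  ys <- (y - mu_y) / sd_y
  set.seed(seed)
  n <- nrow(Xs)
  n_val <- max(1L, round(val_frac * n))
  vix <- sample.int(n, n_val)
  Xtr <- Xs[-vix, , drop = FALSE]; ytr <- ys[-vix]
  Xva <- Xs[vix, , drop = FALSE]; yva <- ys[vix]
  par <- .nn_init(ncol(Xs), hidden, seed)
  L <- length(par$W)
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(par = par, mse = Inf, epoch = 0L)
  wait <- 0L
  for (ep in seq_len(epochs)) {
    cache <- .nn_forward(par, Xtr, dropout = dropout, rng = TRUE)
    g <- .nn_backward(par, cache, ytr, dropout)
    for (l in seq_len(L)) {
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$W[[l]]
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$W[[l]]^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$b[[l]]
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$b[[l]]^2
      mhW <- mW[[l]] / (1 - b1^ep); vhW <- vW[[l]] / (1 - b2^ep)
      mhb <- mb[[l]] / (1 - b1^ep); vhb <- vb[[l]] / (1 - b2^ep)
      par$W[[l]] <- par$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
      par$b[[l]] <- par$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
    }
    pv <- .nn_forward(par, Xva)$out
    mse <- mean((pv - yva)^2)
    if (mse < best$mse - 1e-10) {
      best <- list(par = par, mse = mse, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  list(par = best$par, mu_x = mu_x, sd_x = sd_x, mu_y = mu_y, sd_y = sd_y,
       best_epoch = best$epoch, val_mse = best$mse,
       feature_names = colnames(x))
}

.nn_predict <- function(fit, x) {
  x <- as.matrix(x)[, fit$feature_names, drop = FALSE]
  Xs <- sweep(sweep(x, 2, fit$mu_x), 2, fit$sd_x, "/")
  .nn_forward(fit$par, Xs)$out * fit$sd_y + fit$mu_y
}
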