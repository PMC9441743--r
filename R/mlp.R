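# Feed-forward regression network: ReLU hidden layers, linear output,
# full-batch Adam, early stopping on validation MAE. Internal engine behind
# train_regressor(); weights are plain matrices so runs are deterministic
# given the seed.

mlp_init <- function(n_in, hidden, y_mean, seed) {
  set.seed(seed)
  sizes <- c(n_in, hidden, 1L)
  W <- b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    fan_in <- sizes[l]
    W[[l]] <- matrix(stats::rnorm(fan_in * sizes[l + 1L], 0,
                                  sqrt(2 / fan_in)),
                     fan_in, sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  b[[length(b)]] <- y_mean                     # start at the mean predictor
  list(W = W, b = b)
}

mlp_forward <- function(par, X) {
  L <- length(par$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% par$W[[l]], 2L, par$b[[l]], `+`)
    A[[l + 1L]] <- if (l < L) pmax(Z, 0) else Z
  }
  A
}

mlp_predict <- function(par, X) {
  drop(mlp_forward(par, X)[[length(par$W) + 1L]])
}

mlp_gradients <- function(par, A, y) {
  L <- length(par$W)
  n <- length(y)
  gW <- gb <- vector("list", L)
  delta <- (A[[L + 1L]] - y) * (2 / n)         # d MSE / d output
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) delta <- (delta %*% t(par$W[[l]])) * (A[[l]] > 0)
  }
  list(W = gW, b = gb)
}

mlp_train <- function(X, y, X_val, y_val, hidden,
                      learning_rate = 0.01, max_epochs = 500L,
                      patience = 20L, seed = 1L) {
  par <- mlp_init(ncol(X), hidden, mean(y), seed)
  L <- length(par$W)
  m <- v <- list(W = lapply(par$W, function(w) w * 0),
                 b = lapply(par$b, function(x) x * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best <- list(par = par, mae = Inf, epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(max_epochs)) {
    A <- mlp_forward(par, X)
    g <- mlp_gradients(par, A, y)
    corr1 <- 1 - beta1^epoch; corr2 <- 1 - beta2^epoch
    for (l in seq_len(L)) {
      m$W[[l]] <- beta1 * m$W[[l]] + (1 - beta1) * g$W[[l]]
      v$W[[l]] <- beta2 * v$W[[l]] + (1 - beta2) * g$W[[l]]^2
      par$W[[l]] <- par$W[[l]] -
        learning_rate * (m$W[[l]] / corr1) / (sqrt(v$W[[l]] / corr2) + eps)
      m$b[[l]] <- beta1 * m$b[[l]] + (1 - beta1) * g$b[[l]]
      v$b[[l]] <- beta2 * v$b[[l]] + (1 - beta2) * g$b[[l]]^2
      par$b[[l]] <- par$b[[l]] -
        learning_rate * (m$b[[l]] / corr1) / (sqrt(v$b[[l]] / corr2) + eps)
    }
    val_mae <- mean(abs(mlp_predict(par, X_val) - y_val))
    if (val_mae < best$mae - 1e-9) {
      best <- list(par = par, mae = val_mae, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  best
}
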