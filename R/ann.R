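# Feed-forward neural network back-end: a three-layer network
# (input -> one hidden dense layer with rectifier activation -> softmax
# output) trained by mini-batch Adam on the multinomial cross-entropy.
# Written as plain matrix algebra so that training is deterministic given
# the seed and has a fixed epoch budget.

ann_fit <- function(X, y, hidden = NULL, epochs = 30L, batch_size = 256L,
                    lr = 1e-3, l2 = 1e-4, seed = 1L) {
  X <- as.matrix(X)
  y <- factor(y)
  classes <- levels(y)
  k <- length(classes)
  p <- ncol(X)
  n <- nrow(X)
  if (is.null(hidden)) hidden <- max(64L, 2L * k)
  Y <- matrix(0, n, k)
  Y[cbind(seq_len(n), as.integer(y))] <- 1

  set.seed(seed)
  W1 <- matrix(stats::rnorm(p * hidden, sd = sqrt(2 / p)), p, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(stats::rnorm(hidden * k, sd = sqrt(2 / hidden)), hidden, k)
  b2 <- numeric(k)

  adam <- function() list(m = 0, v = 0)
  st <- list(W1 = adam(), b1 = adam(), W2 = adam(), b2 = adam())
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L

  upd <- function(s, g) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    s
  }
  step_val <- function(s) {
    mh <- s$m / (1 - beta1^t_step)
    vh <- s$v / (1 - beta2^t_step)
    lr * mh / (sqrt(vh) + eps)
  }

  n_batch <- ceiling(n / batch_size)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (bi in seq_len(n_batch)) {
      rows <- ord[((bi - 1L) * batch_size + 1L):min(bi * batch_size, n)]
      Xb <- X[rows, , drop = FALSE]
      Yb <- Y[rows, , drop = FALSE]
      nb <- length(rows)

      H <- Xb %*% W1
      H <- H + rep(b1, each = nb)
      A <- H * (H > 0)                       # ReLU
      O <- A %*% W2
      O <- O + rep(b2, each = nb)
      O <- O - apply(O, 1, max)
      E <- exp(O)
      P <- E / rowSums(E)

      dO <- (P - Yb) / nb
      gW2 <- crossprod(A, dO) + l2 * W2
      gb2 <- colSums(dO)
      dA <- dO %*% t(W2)
      dH <- dA * (H > 0)
      gW1 <- crossprod(Xb, dH) + l2 * W1
      gb1 <- colSums(dH)

      t_step <- t_step + 1L
      st$W1 <- upd(st$W1, gW1); W1 <- W1 - step_val(st$W1)
      st$b1 <- upd(st$b1, gb1); b1 <- b1 - step_val(st$b1)
      st$W2 <- upd(st$W2, gW2); W2 <- W2 - step_val(st$W2)
      st$b2 <- upd(st$b2, gb2); b2 <- b2 - step_val(st$b2)
    }
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, classes = classes,
       hidden = hidden, epochs = epochs)
}

ann_predict_probs <- function(fit, X) {
  X <- as.matrix(X)
  H <- X %*% fit$W1
  H <- H + rep(fit$b1, each = nrow(X))
  A <- H * (H > 0)
  O <- A %*% fit$W2
  O <- O + rep(fit$b2, each = nrow(X))
  O <- O - apply(O, 1, max)
  E <- exp(O)
  P <- E / rowSums(E)
  colnames(P) <- fit$classes
  P
}
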