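# Gaussian naive Bayes and a one-hidden-layer perceptron classifier —
# small baseline classifiers, written directly against their textbook
# definitions.

fit_gnb <- function(Z, labels, var_smoothing = 1e-9) {
  Z <- as.matrix(Z)
  f <- factor(labels)
  lev <- levels(f)
  if (length(lev) < 2) stop("classification needs at least two classes")
  stats_by <- lapply(lev, function(lv) {
    Zi <- Z[f == lv, , drop = FALSE]
    list(mean = colMeans(Zi),
         var = if (nrow(Zi) > 1) matrixStats_colVars(Zi) * (nrow(Zi) - 1) /
           nrow(Zi) else rep(0, ncol(Zi)),
         prior = nrow(Zi) / nrow(Z))
  })
  eps <- var_smoothing * max(matrixStats_colVars(Z), 1e-12)
  for (i in seq_along(stats_by)) stats_by[[i]]$var <- stats_by[[i]]$var + eps
  structure(list(classes = lev, stats = stats_by), class = "gnb_model")
}

predict_gnb <- function(model, Z_new) {
  Z_new <- as.matrix(Z_new)
  n <- nrow(Z_new)
  ll <- vapply(model$stats, function(st) {
    V <- matrix(st$var, n, length(st$var), byrow = TRUE)
    M <- matrix(st$mean, n, length(st$mean), byrow = TRUE)
    rowSums(-0.5 * log(2 * pi * V) - 0.5 * (Z_new - M)^2 / V) + log(st$prior)
  }, numeric(n))
  ll <- matrix(ll, nrow = n)
  factor(model$classes[max.col(ll, ties.method = "first")],
         levels = model$classes)
}

# One hidden layer (ReLU), softmax output, Adam, full-batch gradient
# descent; the common-library baseline configuration (100 hidden units,
# learning rate 1e-3, 200 epochs, L2 penalty 1e-4).
fit_mlp <- function(Z, labels, hidden = 100, epochs = 200, lr = 1e-3,
                    l2 = 1e-4) {
  Z <- as.matrix(Z)
  f <- factor(labels)
  lev <- levels(f)
  if (length(lev) < 2) stop("classification needs at least two classes")
  Y <- outer(as.character(f), lev, "==") * 1
  n <- nrow(Z); p <- ncol(Z); K <- length(lev)
  W1 <- matrix(rnorm(p * hidden, 0, sqrt(2 / p)), p, hidden)
  b1 <- rep(0, hidden)
  W2 <- matrix(rnorm(hidden * K, 0, sqrt(2 / hidden)), hidden, K)
  b2 <- rep(0, K)
  ms <- list(W1 = 0 * W1, b1 = 0 * b1, W2 = 0 * W2, b2 = 0 * b2)
  vs <- ms
  beta1 <- 0.9; beta2 <- 0.999; epsa <- 1e-8
  for (t in seq_len(epochs)) {
    H <- pmax(sweep(Z %*% W1, 2, b1, "+"), 0)
    S <- sweep(H %*% W2, 2, b2, "+")
    P <- exp(S - apply(S, 1, max)); P <- P / rowSums(P)
    dS <- (P - Y) / n
    gW2 <- crossprod(H, dS) + l2 * W2
    gb2 <- colSums(dS)
    dH <- dS %*% t(W2)
    dH[H <= 0] <- 0
    gW1 <- crossprod(Z, dH) + l2 * W1
    gb1 <- colSums(dH)
    grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
    params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    for (nm in names(params)) {
      ms[[nm]] <- beta1 * ms[[nm]] + (1 - beta1) * grads[[nm]]
      vs[[nm]] <- beta2 * vs[[nm]] + (1 - beta2) * grads[[nm]]^2
      mhat <- ms[[nm]] / (1 - beta1^t)
      vhat <- vs[[nm]] / (1 - beta2^t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + epsa)
    }
    W1 <- params$W1; b1 <- params$b1; W2 <- params$W2; b2 <- params$b2
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, classes = lev),
            class = "mlp_model")
}

predict_mlp <- function(model, Z_new) {
  H <- pmax(sweep(as.matrix(Z_new) %*% model$W1, 2, model$b1, "+"), 0)
  S <- sweep(H %*% model$W2, 2, model$b2, "+")
  factor(model$classes[max.col(S, ties.method = "first")],
         levels = model$classes)
}
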