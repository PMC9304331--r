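# RBF-kernel support vector machines solved as dual quadratic programs
# (quadprog). Sized for biparental-population n (hundreds), not thousands.

rbf_kernel_theta <- function(X1, X2, theta) {
  q1 <- rowSums(X1 * X1); q2 <- rowSums(X2 * X2)
  d2 <- outer(q1, q2, "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  exp(-theta * d2)
}

# epsilon-SVR dual in the 2n variables (alpha, alpha*), box [0, C],
# sum(alpha - alpha*) = 0.
fit_svr_rbf <- function(Z, y, theta, C = 1, epsilon = 0.1, ridge = 1e-8) {
  Z <- as.matrix(Z); y <- as.numeric(y)
  n <- nrow(Z)
  K <- rbf_kernel_theta(Z, Z, theta)
  D <- rbind(cbind(K, -K), cbind(-K, K)) + diag(ridge, 2 * n)
  d <- c(y - epsilon, -y - epsilon)
  # constraints: equality first, then lower bounds >= 0, then -x >= -C
  A <- cbind(c(rep(1, n), rep(-1, n)), diag(2 * n), -diag(2 * n))
  b0 <- c(0, rep(0, 2 * n), rep(-C, 2 * n))
  sol <- quadprog::solve.QP(D, d, A, b0, meq = 1)
  beta <- sol$solution[1:n] - sol$solution[(n + 1):(2 * n)]
  f0 <- as.numeric(K %*% beta)
  free <- which(abs(beta) > 1e-6 & abs(beta) < C - 1e-6)
  b <- if (length(free) > 0) {
    mean(y[free] - f0[free] - epsilon * sign(beta[free]))
  } else {
    mean(y - f0)
  }
  list(Z = Z, beta = beta, b = b, theta = theta)
}

predict_svr_rbf <- function(model, Z_new) {
  Kn <- rbf_kernel_theta(as.matrix(Z_new), model$Z, model$theta)
  as.numeric(Kn %*% model$beta + model$b)
}

# binary C-SVC dual; labels in {-1, +1}
fit_svc_binary <- function(Z, yb, theta, C = 1, ridge = 1e-8) {
  n <- nrow(Z)
  K <- rbf_kernel_theta(Z, Z, theta)
  D <- (yb %o% yb) * K + diag(ridge, n)
  A <- cbind(yb, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(D, rep(1, n), A, b0, meq = 1)
  a <- sol$solution
  coefs <- a * yb
  f0 <- as.numeric(K %*% coefs)
  free <- which(a > 1e-6 & a < C - 1e-6)
  b <- if (length(free) > 0) mean(yb[free] - f0[free]) else {
    sv <- which(a > 1e-6)
    if (length(sv) > 0) mean(yb[sv] - f0[sv]) else 0
  }
  list(coefs = coefs, b = b)
}

# multiclass via one-vs-one voting (ties to the first level), the standard
# decomposition for kernel SVC
fit_svc_rbf <- function(Z, labels, theta, C = 1) {
  Z <- as.matrix(Z)
  f <- factor(labels)
  lev <- levels(f)
  if (length(lev) < 2) stop("classification needs at least two classes")
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  fits <- lapply(pairs, function(pr) {
    sel <- f %in% pr
    yb <- ifelse(f[sel] == pr[1], 1, -1)
    c(fit_svc_binary(Z[sel, , drop = FALSE], yb, theta, C),
      list(rows = which(sel), pair = pr))
  })
  structure(list(Z = Z, fits = fits, levels = lev, theta = theta),
            class = "svc_model")
}

predict_svc_rbf <- function(model, Z_new) {
  Z_new <- as.matrix(Z_new)
  votes <- matrix(0L, nrow(Z_new), length(model$levels),
                  dimnames = list(NULL, model$levels))
  for (ft in model$fits) {
    Kn <- rbf_kernel_theta(Z_new, model$Z[ft$rows, , drop = FALSE],
                           model$theta)
    dec <- as.numeric(Kn %*% ft$coefs + ft$b)
    winner <- ifelse(dec >= 0, ft$pair[1], ft$pair[2])
    for (lv in ft$pair) votes[, lv] <- votes[, lv] + (winner == lv)
  }
  factor(model$levels[max.col(votes, ties.method = "first")],
         levels = model$levels)
}
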