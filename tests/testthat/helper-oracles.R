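# Independent oracles used to cross-check the package's own implementations.
# These deliberately take different computational routes than the code under
# test.

# Moore-Penrose pseudoinverse via SVD; oracle for least-squares solvers.
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

ols_fitted_oracle <- function(X, y) {
  D <- cbind(1, as.matrix(X))
  drop(D %*% (pinv(D) %*% y))
}

# PLS1 by the SIMPLS recursion (de Jong 1993) on pre-scaled data; for a
# univariate response it spans the same Krylov space as NIPALS and must
# produce identical predictions, while sharing no code with the NIPALS
# implementation under test.
simpls1_coef <- function(Xs, ys, a) {
  p <- ncol(Xs)
  S <- drop(crossprod(Xs, ys))
  R <- matrix(0, p, a)
  V <- matrix(0, p, a)
  q <- numeric(a)
  for (m in seq_len(a)) {
    r <- S
    t_ <- drop(Xs %*% r)
    nt <- sqrt(sum(t_^2))
    r <- r / nt
    t_ <- t_ / nt
    pv <- drop(crossprod(Xs, t_))
    q[m] <- sum(ys * t_)
    v <- pv
    if (m > 1) {
      Vm <- V[, seq_len(m - 1), drop = FALSE]
      v <- v - drop(Vm %*% crossprod(Vm, pv))
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v * sum(v * S)
    R[, m] <- r
    V[, m] <- v
  }
  drop(R %*% q)
}

# Brute-force leave-one-out PRESS using the SIMPLS oracle, with per-fold
# autoscaling.
press_loo_oracle <- function(X, y, a_max) {
  X <- as.matrix(X)
  n <- nrow(X)
  press <- numeric(a_max)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    yi <- y[-i]
    mu <- colMeans(Xi)
    sc <- apply(Xi, 2, sd)
    Xs <- scale(Xi, center = mu, scale = sc)
    ym <- mean(yi)
    xn <- (X[i, ] - mu) / sc
    for (a in seq_len(a_max)) {
      b <- simpls1_coef(Xs, yi - ym, a)
      press[a] <- press[a] + (y[i] - (ym + sum(xn * b)))^2
    }
  }
  press
}

# Closed-form mean and SD of a normal truncated to [lower, upper]; oracle
# for the synthetic GPC distribution.
truncnorm_moments <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  mu <- mean + sd * (dnorm(a) - dnorm(b)) / Z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                 ((dnorm(a) - dnorm(b)) / Z)^2)
  c(mean = mu, sd = sqrt(v))
}

# Small random regression instance with named columns.
random_instance <- function(n, p, seed, noise = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  beta <- rnorm(p)
  list(X = X, y = drop(X %*% beta) + rnorm(n, 0, noise))
}
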