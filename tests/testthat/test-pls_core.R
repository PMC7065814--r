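# PLS1 core: NIPALS fit, PRESS selection, VIP.

test_that("a noiseless univariate relation is recovered exactly", {
  x <- matrix(seq(1, 5, by = 0.5), ncol = 1, dimnames = list(NULL, "x1"))
  y <- 2 * x[, 1]
  m <- fit_pls(x, y, a = 1)
  expect_equal(unname(m$coefficients), 2, tolerance = 1e-12)
  expect_equal(m$intercept, 0, tolerance = 1e-12)
  expect_equal(predict(m, x), y, tolerance = 1e-12)
})

test_that("PLS with a = p reproduces OLS fitted values on full-rank designs", {
  for (seed in c(3, 14, 25)) {
    inst <- random_instance(30, 4, seed)
    m <- fit_pls(inst$X, inst$y, a = 4)
    expect_equal(predict(m, inst$X), ols_fitted_oracle(inst$X, inst$y),
                 tolerance = 1e-8)
  }
})

test_that("score vectors are mutually orthogonal", {
  inst <- random_instance(40, 6, 7)
  Xs <- scale(inst$X)
  eng <- wheatgpc:::pls_engine(Xs, inst$y - mean(inst$y), 6)
  G <- crossprod(eng$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("latent-path and coefficient-path predictions agree", {
  inst <- random_instance(35, 5, 11)
  m <- fit_pls(inst$X, inst$y, a = 3)
  Xnew <- random_instance(10, 5, 12)$X
  expect_equal(predict(m, Xnew, path = "latent"),
               predict(m, Xnew, path = "coefficients"),
               tolerance = 1e-10)
})

test_that("NIPALS coefficients match the SIMPLS oracle at every a", {
  inst <- random_instance(30, 5, 21)
  Xs <- scale(inst$X)
  ys <- inst$y - mean(inst$y)
  eng <- wheatgpc:::pls_engine(Xs, ys, 5)
  for (a in 1:5) {
    expect_equal(wheatgpc:::pls_coef_scaled(eng, a),
                 simpls1_coef(Xs, ys, a), tolerance = 1e-9)
  }
})

test_that("excess components and zero-variance columns are refused", {
  X <- cbind(a = rnorm(20), b = rnorm(20))
  X <- cbind(X, c = X[, "a"] + X[, "b"])  # rank 2
  y <- rnorm(20)
  expect_error(fit_pls(X, y, a = 3), "rank")
  Xz <- cbind(a = rnorm(20), b = rep(1, 20))
  expect_error(fit_pls(Xz, y, a = 1), "b")
})

test_that("prediction enforces predictor names and order", {
  inst <- random_instance(20, 3, 5)
  m <- fit_pls(inst$X, inst$y, a = 2)
  bad <- inst$X
  colnames(bad) <- c("v1", "v2", "wrong")
  expect_error(predict(m, bad), "v3")
  # shuffled columns are re-ordered by name, not misread
  shuffled <- inst$X[, c(3, 1, 2)]
  expect_equal(predict(m, shuffled), predict(m, inst$X), tolerance = 1e-12)
})

test_that("PRESS is zero for exactly linear univariate data", {
  x <- matrix(seq_len(10), ncol = 1)
  pc <- press_curve(x, 3 * x[, 1] + 1, a_max = 1)
  expect_lt(pc$press[1], 1e-16)
  expect_equal(pc$k, 10)
})

test_that("PRESS equals the brute-force leave-one-out oracle on small instances", {
  cases <- list(c(n = 6, p = 2), c(n = 8, p = 3), c(n = 10, p = 4),
                c(n = 12, p = 5))
  for (cs in cases) {
    inst <- random_instance(cs["n"], cs["p"], seed = sum(cs))
    a_max <- min(cs["p"], cs["n"] - 2)
    pc <- press_curve(inst$X, inst$y, a_max)
    expect_equal(pc$press, press_loo_oracle(inst$X, inst$y, a_max),
                 tolerance = 1e-10)
  }
})

test_that("pure-noise responses drive PRESS back up beyond its minimum", {
  rising <- logical(50)
  for (k in 1:50) {
    set.seed(k)
    pc <- press_curve(matrix(rnorm(40 * 6), 40, 6), rnorm(40), 6)
    i <- pc$argmin_a
    if (i < 6) {
      seg <- pc$press[i:6]
      rising[k] <- unname(coef(lm(seg ~ seq_along(seg)))[2]) >= 0
    }
  }
  expect_gte(mean(rising), 0.8)
})

test_that("component selection takes the PRESS minimum with parsimony ties", {
  curve <- function(p) structure(list(a_values = seq_along(p), press = p,
                                      k = 10, argmin_a = which.min(p)),
                                 class = "press_curve")
  expect_equal(select_components(curve(c(30, 25, 21.39, 22, 28))), 3)
  expect_equal(select_components(curve(c(9, 7, 5, 3, 1))), 5)
  expect_equal(select_components(curve(c(10, 10, 12))), 1)
})

test_that("VIP scores are normalized and rank informative predictors first", {
  x <- matrix(rnorm(60), ncol = 1, dimnames = list(NULL, "x1"))
  m1 <- fit_pls(x, 2 * x[, 1] + rnorm(60, 0, 0.1), a = 1)
  expect_equal(unname(vip_scores(m1)), 1, tolerance = 1e-12)
  set.seed(6)
  X <- cbind(signal = rnorm(80), noise = rnorm(80))
  y <- 3 * X[, "signal"] + rnorm(80, 0, 0.2)
  v <- vip_scores(fit_pls(X, y, a = 2))
  expect_gt(v["signal"], 1)
  expect_lt(v["noise"], 1)
  for (seed in c(2, 9)) {
    inst <- random_instance(30, 5, seed)
    v <- vip_scores(fit_pls(inst$X, inst$y, a = 3))
    expect_equal(mean(v^2), 1, tolerance = 1e-10)
  }
})

test_that("models round-trip through their JSON document", {
  inst <- random_instance(30, 4, 13)
  m <- fit_pls(inst$X, inst$y, a = 2)
  pc <- press_curve(inst$X, inst$y, 3)
  path <- tempfile(fileext = ".json")
  write_model(m, path, press = pc)
  m2 <- read_model(path)
  expect_equal(predict(m2, inst$X), predict(m, inst$X), tolerance = 1e-12)
  expect_equal(attr(m2, "press")$press, pc$press, tolerance = 1e-12)
  ols <- fit_ols(inst$X, inst$y)
  path2 <- tempfile(fileext = ".json")
  write_model(ols, path2)
  expect_equal(predict(read_model(path2), inst$X), predict(ols, inst$X),
               tolerance = 1e-12)
  unlink(c(path, path2))
})
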