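# PLS1 regression core.
#
# A from-scratch univariate-response partial least squares implementation:
# NIPALS with X-deflation on autoscaled predictors, leave-one-out PRESS for
# choosing the number of latent components, and VIP variable-importance
# scores. Coefficients are back-transformed to the original variable scale
# so the fitted equation can be applied directly to raw indices.
#
# For a univariate response the NIPALS inner iteration converges in a single
# pass (the weight vector is proportional to X'y), so each component is
# computed directly:
#   w_a = E'f / ||E'f||,  t_a = E w_a,  p_a = E't_a / t_a't_a,
#   q_a = f't_a / t_a't_a,  E <- E - t_a p_a',  f <- f - q_a t_a.

# Core recursion on pre-scaled data. Returns weights W, X-loadings P,
# y-loadings q and score norms tt, all for `a` components.
pls_engine <- function(Xs, ys, a, tol = 1e-12) {
  n <- nrow(Xs); p <- ncol(Xs)
  W <- matrix(0, p, a); P <- matrix(0, p, a)
  q <- numeric(a); tt <- numeric(a)
  scores <- matrix(0, n, a)
  E <- Xs; f <- ys
  for (m in seq_len(a)) {
    w <- drop(crossprod(E, f))
    wn <- sqrt(sum(w^2))
    if (!is.finite(wn) || wn < tol) {
      stop(sprintf("component %d: residual X carries no covariance with y (a exceeds the effective rank)",
                   m), call. = FALSE)
    }
    w <- w / wn
    t_ <- drop(E %*% w)
    tsq <- sum(t_^2)
    if (tsq < tol) {
      stop(sprintf("component %d: degenerate score vector (a exceeds the effective rank)",
                   m), call. = FALSE)
    }
    p_ <- drop(crossprod(E, t_)) / tsq
    q_ <- sum(f * t_) / tsq
    E <- E - tcrossprod(t_, p_)
    f <- f - q_ * t_
    W[, m] <- w; P[, m] <- p_; q[m] <- q_; tt[m] <- tsq
    scores[, m] <- t_
  }
  list(W = W, P = P, q = q, tt = tt, scores = scores)
}

# Regression coefficients on the scaled metric for the first `a` components.
pls_coef_scaled <- function(eng, a) {
  W <- eng$W[, seq_len(a), drop = FALSE]
  P <- eng$P[, seq_len(a), drop = FALSE]
  q <- eng$q[seq_len(a)]
  drop(W %*% solve(crossprod(P, W), q))
}

#' Fit a PLS1 regression model
#'
#' NIPALS partial least squares with a single response. Predictors are
#' autoscaled (centered, unit variance) and the response centered before
#' extraction; the returned coefficients and intercept are on the original
#' variable scale, so `predict()` is simply `intercept + X %*% coefficients`.
#'
#' @param X Numeric matrix or data frame of predictors (n x p), no missing
#'   values, every column with positive variance.
#' @param y Numeric response vector (here: GPC, % dry matter).
#' @param a Number of latent components, `1 <= a <=` effective rank of the
#'   centered `X`; requesting more components than the data support is an
#'   error.
#' @return An object of class `pls_model` with elements `n_components`,
#'   `predictor_names`, `x_means`, `x_scales`, `y_mean`, `weights`,
#'   `loadings`, `y_loadings`, `score_norms2`, `coefficients`, `intercept`.
#' @export
#' @examples
#' X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
#' y <- 1 + X[, 1] - 0.5 * X[, 2] + rnorm(20, 0, 0.1)
#' m <- fit_pls(X, y, a = 2)
#' m$coefficients
fit_pls <- function(X, y, a) {
  X <- as_numeric_matrix(X, "X")
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("`X` and `y` sizes differ", call. = FALSE)
  if (a < 1) stop("`a` must be at least 1", call. = FALSE)
  if (n < a + 1) stop("need at least a + 1 samples", call. = FALSE)
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("x", seq_len(p))
  x_means <- colMeans(X)
  x_scales <- apply(X, 2, sd)
  zero_var <- x_scales == 0 | !is.finite(x_scales)
  if (any(zero_var)) {
    stop(sprintf("zero-variance predictor column(s): %s",
                 paste(nms[zero_var], collapse = ", ")), call. = FALSE)
  }
  Xs <- scale(X, center = x_means, scale = x_scales)
  y_mean <- mean(y)
  eng <- pls_engine(Xs, y - y_mean, a)
  b_scaled <- pls_coef_scaled(eng, a)
  coefficients <- b_scaled / x_scales
  names(coefficients) <- nms
  structure(
    list(
      n_components = as.integer(a),
      predictor_names = nms,
      x_means = stats::setNames(x_means, nms),
      x_scales = stats::setNames(x_scales, nms),
      y_mean = y_mean,
      weights = eng$W,
      loadings = eng$P,
      y_loadings = eng$q,
      score_norms2 = eng$tt,
      coefficients = coefficients,
      intercept = y_mean - sum(coefficients * x_means)
    ),
    class = "pls_model"
  )
}

#' Construct a linear GPC predictor from known coefficients
#'
#' Wraps an already-estimated linear equation (for example a published
#' four-index GPC model) in the same prediction interface as fitted models,
#' so it can be applied to variable tables and index grids.
#'
#' @param coefficients Named numeric vector of per-predictor coefficients
#'   on the original variable scale.
#' @param intercept Intercept (% GPC).
#' @param method Tag stored on the object (default `"fixed"`).
#' @return An object of class `linear_model`.
#' @export
#' @examples
#' eq <- new_linear_model(
#'   c(NDVI = 3.873, SIPI = 1.696, PSRI = 2.862, EVI = -1.276),
#'   intercept = 5.821)
#' predict(eq, data.frame(NDVI = 0, SIPI = 0, PSRI = 0, EVI = 0))
new_linear_model <- function(coefficients, intercept, method = "fixed") {
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
    stop("`coefficients` must be a fully named vector", call. = FALSE)
  }
  structure(
    list(
      method = method,
      n_components = 0L,
      predictor_names = names(coefficients),
      coefficients = coefficients,
      intercept = intercept
    ),
    class = "linear_model"
  )
}

# Shared prediction-matrix preparation: enforce predictor names and order.
prediction_matrix <- function(model, newdata) {
  X <- if (is.data.frame(newdata)) as.matrix(newdata) else newdata
  stop_if_not_matrix_like(X, "newdata")
  nms <- colnames(X)
  if (!is.null(nms)) {
    if (!all(model$predictor_names %in% nms)) {
      stop(sprintf("missing predictor column(s): %s",
                   paste(setdiff(model$predictor_names, nms),
                         collapse = ", ")), call. = FALSE)
    }
    X <- X[, model$predictor_names, drop = FALSE]
  } else if (ncol(X) != length(model$predictor_names)) {
    stop("unnamed `newdata` must match the number of model predictors",
         call. = FALSE)
  }
  X
}

#' Predict GPC from a fitted PLS model
#'
#' @param object A [fit_pls()] model.
#' @param newdata Matrix or data frame holding the model's predictor
#'   columns (matched by name when names are present).
#' @param path `"coefficients"` applies `intercept + X b`;
#'   `"latent"` recomputes scores through the NIPALS basis. The two agree
#'   to numerical precision and the latent path exists as an internal
#'   consistency check.
#' @param ... Unused.
#' @return Numeric vector of predicted GPC (% dry matter).
#' @export
predict.pls_model <- function(object, newdata,
                              path = c("coefficients", "latent"), ...) {
  path <- match.arg(path)
  X <- prediction_matrix(object, newdata)
  if (path == "coefficients") {
    return(drop(object$intercept + X %*% object$coefficients))
  }
  Xs <- scale(X, center = object$x_means, scale = object$x_scales)
  a <- object$n_components
  E <- Xs
  yhat <- rep(object$y_mean, nrow(X))
  for (m in seq_len(a)) {
    t_ <- drop(E %*% object$weights[, m])
    yhat <- yhat + object$y_loadings[m] * t_
    E <- E - tcrossprod(t_, object$loadings[, m])
  }
  yhat
}

#' @export
predict.linear_model <- function(object, newdata, ...) {
  X <- prediction_matrix(object, newdata)
  drop(object$intercept + X %*% object$coefficients)
}

#' Leave-one-out PRESS curve over candidate component counts
#'
#' For each candidate number of components `a = 1 ... a_max`, refits the
#' PLS model with each sample held out in turn (centering and scaling
#' re-estimated inside every fold, so no information leaks from the held-out
#' sample) and accumulates the predictive residual error sum of squares
#' `PRESS(a) = sum_i (y_i - yhat_{i,-i})^2`. The minimizer of this curve is
#' the standard choice of model complexity: too few components underfit,
#' too many overfit and the curve rises again.
#'
#' @inheritParams fit_pls
#' @param a_max Largest candidate component count; `n >= a_max + 2`.
#' @return An object of class `press_curve`: list with `a_values`, `press`,
#'   `k` (number of validation iterations, = n for leave-one-out) and
#'   `argmin_a` (ties broken toward the smallest count).
#' @export
press_curve <- function(X, y, a_max) {
  X <- as_numeric_matrix(X, "X")
  y <- as.numeric(y)
  n <- nrow(X)
  if (a_max < 1) stop("`a_max` must be at least 1", call. = FALSE)
  if (n < a_max + 2) stop("need at least a_max + 2 samples", call. = FALSE)
  press <- numeric(a_max)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    yi <- y[-i]
    x_means <- colMeans(Xi)
    x_scales <- apply(Xi, 2, sd)
    if (any(x_scales == 0)) {
      stop(sprintf("fold %d: zero-variance predictor after holding out sample",
                   i), call. = FALSE)
    }
    Xs <- scale(Xi, center = x_means, scale = x_scales)
    y_mean <- mean(yi)
    eng <- pls_engine(Xs, yi - y_mean, a_max)
    x_new <- (X[i, ] - x_means) / x_scales
    for (a in seq_len(a_max)) {
      b <- pls_coef_scaled(eng, a)
      pred <- y_mean + sum(x_new * b)
      press[a] <- press[a] + (y[i] - pred)^2
    }
  }
  structure(
    list(a_values = seq_len(a_max), press = press, k = n,
         argmin_a = which.min(press)),
    class = "press_curve"
  )
}

#' Select the number of components at the PRESS minimum
#'
#' @param curve A [press_curve()] object.
#' @return The component count minimizing PRESS; exact ties resolve to the
#'   smallest count (parsimony).
#' @export
select_components <- function(curve) {
  stopifnot(inherits(curve, "press_curve"))
  if (length(curve$press) < 1) stop("empty PRESS curve", call. = FALSE)
  curve$a_values[which.min(curve$press)]
}

#' Variable importance in projection (VIP) scores
#'
#' Standard VIP over the retained components:
#' `VIP_j = sqrt( p * sum_a SSY_a w_{ja}^2 / sum_a SSY_a )` with
#' `SSY_a = q_a^2 t_a't_a` the response variance captured by component `a`
#' and `w_a` the (unit-norm) weight vectors. Squared VIPs average to 1, so
#' scores above 1 mark predictors that carry more than their share of the
#' explained response variance.
#'
#' @param model A fitted [fit_pls()] model.
#' @return Named numeric vector of VIP scores, one per predictor.
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "pls_model")) {
    stop("`model` must be a fitted pls_model", call. = FALSE)
  }
  a <- model$n_components
  p <- length(model$predictor_names)
  ssy <- model$y_loadings[seq_len(a)]^2 * model$score_norms2[seq_len(a)]
  W <- model$weights[, seq_len(a), drop = FALSE]
  vip <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  stats::setNames(vip, model$predictor_names)
}
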