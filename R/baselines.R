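# Baseline regressions: ordinary least squares and principal-components
# regression, implemented from first principles so their behaviour under
# the multicollinearity typical of vegetation-index tables can be compared
# head-to-head with PLS.

#' Fit ordinary least squares by the normal equations
#'
#' @param X Numeric matrix or data frame of predictors, full column rank,
#'   with `n > p`.
#' @param y Numeric response vector.
#' @return An object of class `linear_model` with `method = "ols"`,
#'   `n_components = 0`, coefficients and intercept on the original scale.
#' @export
fit_ols <- function(X, y) {
  X <- as_numeric_matrix(X, "X")
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("`X` and `y` sizes differ", call. = FALSE)
  if (n <= p) stop("need more samples than predictors", call. = FALSE)
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("x", seq_len(p))
  D <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(D)
  if (qrd$rank < ncol(D)) {
    dropped <- qrd$pivot[(qrd$rank + 1):ncol(D)]
    stop(sprintf("rank-deficient design; offending column(s): %s",
                 paste(colnames(D)[dropped], collapse = ", ")),
         call. = FALSE)
  }
  beta <- qr.coef(qrd, y)
  new_linear_model(stats::setNames(unname(beta[-1]), nms),
                   unname(beta[1]), method = "ols")
}

#' Fit principal-components regression
#'
#' PCA of the autoscaled predictors via eigen-decomposition of the
#' correlation matrix; the response is regressed on the leading
#' `n_components` scores and the coefficients back-transformed to the
#' original variable scale. With `n_components = p` on a full-rank design
#' this reproduces ordinary least squares.
#'
#' @inheritParams fit_ols
#' @param n_components Number of leading principal components to retain,
#'   `1 <= n_components <= p`.
#' @return An object of class `linear_model` with `method = "pcr"`; the
#'   element `eigenvalues` holds the (non-increasing) correlation-matrix
#'   spectrum.
#' @export
fit_pcr <- function(X, y, n_components) {
  X <- as_numeric_matrix(X, "X")
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("`X` and `y` sizes differ", call. = FALSE)
  if (n_components < 1 || n_components > p) {
    stop("`n_components` must lie in 1..p", call. = FALSE)
  }
  if (n <= n_components) {
    stop("need more samples than retained components", call. = FALSE)
  }
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("x", seq_len(p))
  x_means <- colMeans(X)
  x_scales <- apply(X, 2, sd)
  if (any(x_scales == 0)) {
    stop(sprintf("zero-variance predictor column(s): %s",
                 paste(nms[x_scales == 0], collapse = ", ")), call. = FALSE)
  }
  Xs <- scale(X, center = x_means, scale = x_scales)
  eig <- eigen(cor(X), symmetric = TRUE)
  V <- eig$vectors[, seq_len(n_components), drop = FALSE]
  scores <- Xs %*% V
  y_mean <- mean(y)
  gamma <- qr.coef(qr(scores), y - y_mean)
  b_scaled <- drop(V %*% gamma)
  coefficients <- stats::setNames(b_scaled / x_scales, nms)
  out <- new_linear_model(coefficients,
                          y_mean - sum(coefficients * x_means),
                          method = "pcr")
  out$n_components <- as.integer(n_components)
  out$eigenvalues <- eig$values
  out
}
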