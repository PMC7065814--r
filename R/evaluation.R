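# Sample handling and model scoring: the 3:2 modeling/verification split
# with forced inclusion of the GPC extremes, summary statistics, the
# Pearson correlation screen, RMSE/accuracy scoring of predicted vs
# measured GPC, and side-by-side model comparison.

#' Split samples into modeling and verification sets (3:2 by default)
#'
#' The modeling set receives `round(ratio * n)` samples. To stabilize the
#' fitted model's range, the samples carrying the global minimum and
#' maximum GPC are always placed in the modeling set before the remaining
#' slots are filled at random.
#'
#' @param y Numeric GPC vector (one value per sample), `n >= 5`.
#' @param ratio Target modeling-set proportion (default 0.6, i.e. 3:2).
#' @param seed RNG seed; the same seed reproduces the same assignment.
#' @return An object of class `split_assignment`: list with
#'   `modeling_ids`, `verification_ids`, `ratio`, `seed`.
#' @export
#' @examples
#' sp <- split_samples(rnorm(255, 12, 1.4), seed = 3)
#' lengths(sp[c("modeling_ids", "verification_ids")])
split_samples <- function(y, ratio = 0.6, seed = 1L) {
  n <- length(y)
  if (n < 5) stop("need at least 5 samples to split", call. = FALSE)
  if (ratio <= 0 || ratio >= 1) stop("`ratio` must lie in (0, 1)",
                                     call. = FALSE)
  n_model <- round(ratio * n)
  forced <- unique(c(which.min(y), which.max(y)))
  if (n_model < length(forced)) {
    stop("modeling set too small to hold the forced extremes",
         call. = FALSE)
  }
  modeling <- with_seed(seed, {
    pool <- setdiff(seq_len(n), forced)
    sort(c(forced, sample(pool, n_model - length(forced))))
  })
  structure(
    list(
      modeling_ids = modeling,
      verification_ids = setdiff(seq_len(n), modeling),
      ratio = ratio,
      seed = as.integer(seed)
    ),
    class = "split_assignment"
  )
}

#' Summary statistics of a GPC sample set
#'
#' @param y Numeric GPC vector, `n >= 2`.
#' @param label Optional set label (e.g. `"modeling"`).
#' @return Data frame with `n`, `min`, `max`, `mean`, `sd` (n-1
#'   denominator) and `se = sd / sqrt(n)`, at full precision; round for
#'   report rendering.
#' @export
summary_stats <- function(y, label = NA_character_) {
  n <- length(y)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  s <- sd(y)
  data.frame(
    set = label, n = n,
    min = min(y), max = max(y),
    mean = mean(y), sd = s, se = s / sqrt(n)
  )
}

#' Pearson correlation screen over a variable table
#'
#' Correlation of every remote-sensing variable with GPC and with every
#' other variable, plus two-sided significance flags from the t
#' approximation `t = r sqrt((n-2)/(1-r^2))`: `*` at 0.05, `**` at 0.01.
#'
#' @param table A [build_variable_table()] result with a `gpc` column
#'   (or any data frame whose first columns are variables and which has a
#'   `gpc` column), `n >= 3`.
#' @return An object of class `correlation_screen`: list with matrices
#'   `r`, `p_value` and character `significance`, each including a `GPC`
#'   row/column, plus `n`.
#' @export
correlation_matrix <- function(table) {
  if (!"gpc" %in% names(table)) {
    stop("`table` must carry a `gpc` response column", call. = FALSE)
  }
  vars <- setdiff(names(table), "gpc")
  M <- cbind(GPC = table$gpc, as.matrix(table[, vars, drop = FALSE]))
  n <- nrow(M)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(M, 2, sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance column(s): %s",
                 paste(colnames(M)[sds == 0], collapse = ", ")),
         call. = FALSE)
  }
  r <- cor(M)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  sig <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  sig[p < 0.05] <- "*"
  sig[p < 0.01] <- "**"
  diag(sig) <- ""
  structure(list(r = r, p_value = p, significance = sig, n = n),
            class = "correlation_screen")
}

#' Score predicted against measured GPC
#'
#' Computes the root mean square error
#' `RMSE = sqrt(mean((y - yhat)^2))` (% GPC), the mean absolute error, and
#' an accuracy in percent. Two accuracy definitions are available:
#' `"relative"` (the default), `(1 - MAE / mean(y)) * 100`, a relative
#' agreement on the typical GPC level; and `"mae"`, the raw mean absolute
#' error itself (% GPC). The determination coefficient `r2` is that of the
#' least-squares line fitted through the predicted-vs-measured (1:1)
#' scatter; `r2_one_to_one = 1 - SSE/SST` about the identity line is also
#' reported.
#'
#' @param y_measured,y_predicted Numeric vectors of equal length,
#'   `n >= 2`.
#' @param accuracy Accuracy definition, `"relative"` or `"mae"`.
#' @param label Optional set label stored in the report.
#' @return An object of class `fit_report`: list with `set`, `n`, `rmse`,
#'   `mae`, `accuracy`, `accuracy_definition`, `r2`, `r2_one_to_one`,
#'   `slope`, `intercept`.
#' @export
score <- function(y_measured, y_predicted,
                  accuracy = c("relative", "mae"), label = NA_character_) {
  accuracy <- match.arg(accuracy)
  n <- length(y_measured)
  if (length(y_predicted) != n) stop("length mismatch", call. = FALSE)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  resid <- y_measured - y_predicted
  rmse <- sqrt(mean(resid^2))
  mae <- mean(abs(resid))
  acc <- if (accuracy == "relative") (1 - mae / mean(y_measured)) * 100
         else mae
  if (sd(y_measured) > 0 && sd(y_predicted) > 0) {
    # least-squares line through the predicted-vs-measured (1:1) scatter
    r2 <- cor(y_measured, y_predicted)^2
    slope <- stats::cov(y_measured, y_predicted) / var(y_measured)
    intercept <- mean(y_predicted) - slope * mean(y_measured)
  } else {
    r2 <- if (all(resid == 0)) 1 else 0
    slope <- if (all(resid == 0)) 1 else NA_real_
    intercept <- if (all(resid == 0)) 0 else NA_real_
  }
  sst <- sum((y_measured - mean(y_measured))^2)
  r2_sse <- if (sst > 0) 1 - sum(resid^2) / sst
            else as.numeric(all(resid == 0))
  structure(
    list(set = label, n = n, rmse = rmse, mae = mae,
         accuracy = acc, accuracy_definition = accuracy,
         r2 = r2, r2_one_to_one = r2_sse,
         slope = slope, intercept = intercept),
    class = "fit_report"
  )
}

#' Compare scored models across algorithms
#'
#' Collates per-set fit reports of several algorithms scored on identical
#' splits into one table and computes all pairwise accuracy differences
#' (percentage points) per set.
#'
#' @param reports Named list (one entry per algorithm) of lists of
#'   [score()] reports keyed by set (e.g. `modeling`, `verification`).
#' @return List with `table` (one row per algorithm x set) and
#'   `accuracy_deltas` (per set, matrix of row-minus-column accuracy
#'   differences).
#' @export
#' @examples
#' r1 <- score(c(10, 12, 14), c(10.2, 11.8, 13.9), label = "modeling")
#' r2 <- score(c(10, 12, 14), c(11, 11, 13), label = "modeling")
#' compare_models(list(pls = list(modeling = r1), lr = list(modeling = r2)))
compare_models <- function(reports) {
  if (length(reports) < 2 || is.null(names(reports))) {
    stop("need a named list of at least 2 algorithms", call. = FALSE)
  }
  sets <- names(reports[[1]])
  for (alg in names(reports)) {
    if (!identical(names(reports[[alg]]), sets)) {
      stop("all algorithms must be scored on the same sets", call. = FALSE)
    }
  }
  for (s in sets) {
    ns <- vapply(reports, function(r) r[[s]]$n, numeric(1))
    if (length(unique(ns)) != 1) {
      stop(sprintf("mismatched splits: set '%s' sizes differ", s),
           call. = FALSE)
    }
  }
  rows <- do.call(rbind, lapply(names(reports), function(alg) {
    do.call(rbind, lapply(sets, function(s) {
      rep <- reports[[alg]][[s]]
      data.frame(algorithm = alg, set = s, n = rep$n, r2 = rep$r2,
                 rmse = rep$rmse, accuracy = rep$accuracy)
    }))
  }))
  rownames(rows) <- NULL
  deltas <- lapply(sets, function(s) {
    acc <- vapply(reports, function(r) r[[s]]$accuracy, numeric(1))
    outer(acc, acc, `-`)
  })
  names(deltas) <- sets
  list(table = rows, accuracy_deltas = deltas)
}
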