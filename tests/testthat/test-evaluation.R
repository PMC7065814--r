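# Split handling, summary statistics, correlation screen, scoring.

test_that("the 3:2 split yields 153/102 with the GPC extremes in the modeling set", {
  set.seed(1)
  y <- rnorm(255, 12, 1.4)
  for (seed in 1:10) {
    sp <- split_samples(y, seed = seed)
    expect_equal(length(sp$modeling_ids), 153)
    expect_equal(length(sp$verification_ids), 102)
    expect_true(which.min(y) %in% sp$modeling_ids)
    expect_true(which.max(y) %in% sp$modeling_ids)
    expect_equal(sort(c(sp$modeling_ids, sp$verification_ids)), 1:255)
  }
})

test_that("the minimal split keeps both extremes in a 3-sample modeling set", {
  y <- c(3, 1, 4, 1.5, 9)
  sp <- split_samples(y, seed = 2)
  expect_equal(length(sp$modeling_ids), 3)
  expect_true(all(c(which.min(y), which.max(y)) %in% sp$modeling_ids))
  expect_error(split_samples(y[1:4]), "at least 5")
})

test_that("splitting is deterministic in its seed", {
  y <- rnorm(40, 12, 1)
  expect_identical(split_samples(y, seed = 7), split_samples(y, seed = 7))
  expect_false(identical(split_samples(y, seed = 7)$modeling_ids,
                         split_samples(y, seed = 8)$modeling_ids))
})

test_that("summary statistics use the n-1 SD and SE = SD/sqrt(n)", {
  # vectors constructed to carry the exact SD of the reported set summaries
  y153 <- 11.99 + 1.33 * as.numeric(scale(rnorm(153)))
  expect_equal(round(summary_stats(y153)$se, 2), 0.11)
  y102 <- 12.29 + 1.42 * as.numeric(scale(rnorm(102)))
  expect_equal(round(summary_stats(y102)$se, 2), 0.14)
  cs <- summary_stats(rep(5, 10))
  expect_equal(cs$sd, 0)
  expect_equal(cs$se, 0)
  expect_error(summary_stats(1), "at least 2")
})

test_that("correlation screen matches the direct covariance formula", {
  set.seed(44)
  tab <- as.data.frame(matrix(rnorm(10 * 4), 10, 4))
  names(tab) <- c("a", "b", "c", "d")
  tab$gpc <- rnorm(10)
  cs <- correlation_matrix(tab)
  M <- cbind(GPC = tab$gpc, as.matrix(tab[, 1:4]))
  for (i in 1:5) for (j in 1:5) {
    xi <- M[, i]; xj <- M[, j]
    r_oracle <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    expect_equal(cs$r[i, j], r_oracle, tolerance = 1e-12)
  }
  expect_equal(cs$r, t(cs$r))
  expect_equal(unname(diag(cs$r)), rep(1, 5))
  expect_true(all(cs$r >= -1 & cs$r <= 1))
})

test_that("affinely related columns hit the correlation bounds and get flags", {
  x <- rnorm(20)
  tab <- data.frame(up = 2 * x + 1, down = -x, gpc = x)
  cs <- correlation_matrix(tab)
  expect_equal(cs$r["GPC", "up"], 1, tolerance = 1e-12)
  expect_equal(cs$r["GPC", "down"], -1, tolerance = 1e-12)
  expect_equal(cs$significance["GPC", "up"], "**")
  expect_error(correlation_matrix(data.frame(a = rep(1, 10),
                                             gpc = rnorm(10))),
               "zero-variance")
})

test_that("perfect prediction scores RMSE 0, R2 1, accuracy 100%", {
  y <- c(10.2, 11.5, 12.8, 13.1)
  rep <- score(y, y)
  expect_equal(rep$rmse, 0)
  expect_equal(rep$r2, 1)
  expect_equal(rep$accuracy, 100)
})

test_that("RMSE and the literal MAE accuracy follow their definitions", {
  expect_equal(score(c(0, 2), c(1, 1))$rmse, 1)
  rep <- score(c(10, 12, 14), c(11, 12, 13), accuracy = "mae")
  expect_equal(rep$accuracy, 2 / 3, tolerance = 1e-12)
  expect_equal(rep$mae, 2 / 3, tolerance = 1e-12)
  expect_gte(rep$rmse, rep$mae)
  expect_error(score(1:3, 1:2), "mismatch")
})

test_that("scoring is invariant to sample order and RMSE >= MAE always", {
  set.seed(3)
  y <- rnorm(30, 12, 1.4)
  yhat <- y + rnorm(30, 0, 0.5)
  o <- sample(30)
  a <- score(y, yhat)
  b <- score(y[o], yhat[o])
  for (f in c("rmse", "mae", "accuracy", "r2")) {
    expect_equal(a[[f]], b[[f]], tolerance = 1e-12)
  }
  expect_gte(a$rmse, a$mae)
})

test_that("model comparison reports pairwise accuracy deltas", {
  mk <- function(acc) {
    list(modeling = structure(list(set = "modeling", n = 153, r2 = 0.8,
                                   rmse = 0.5, accuracy = acc),
                              class = "fit_report"))
  }
  cmp <- compare_models(list(pls = mk(94.7), lr = mk(74.1)))
  expect_equal(cmp$accuracy_deltas$modeling["pls", "lr"], 20.6,
               tolerance = 1e-9)
  same <- compare_models(list(a = mk(90), b = mk(90)))
  expect_true(all(same$accuracy_deltas$modeling == 0))
  bad <- list(modeling = structure(list(set = "modeling", n = 100,
                                        r2 = 0.8, rmse = 0.5,
                                        accuracy = 80),
                                   class = "fit_report"))
  expect_error(compare_models(list(a = mk(90), b = bad)),
               "sizes differ")
})
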