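test_that("NIPALS recovers a perfect single predictor", {
  set.seed(21)
  n <- 12
  x1 <- scale(rnorm(n))
  # remaining columns orthogonal to x1 (and to each other's y-relation)
  Q <- qr.Q(qr(cbind(x1, matrix(rnorm(n * 4), n, 4))))[, 2:5]
  Xs <- cbind(drop(x1), sqrt(n - 1) * Q)
  colnames(Xs) <- paste0("V", 1:5)
  ys <- drop(x1)
  fit <- fit_pls1(Xs, ys, 1)
  expect_equal(fit$var_y_cum[1], 100, tolerance = 1e-8)
  expect_gt(abs(fit$b["V1"]), 10 * max(abs(fit$b[-1])))
  expect_error(fit_pls1(Xs, rep(0, n) + 0, 1), "covariance|A must")
})

test_that("coefficients at full rank equal the minimum-norm least-squares oracle", {
  set.seed(31)
  for (rep in 1:20) {
    X <- matrix(rnorm(10 * 20), 10, 20)
    Xs <- scale(X)
    ys <- drop(scale(rnorm(10)))
    A <- qr(Xs)$rank
    fit <- fit_pls1(Xs, ys, A)
    expect_equal(unname(fit$b), minnorm_ls(Xs, ys), tolerance = 1e-6)
    # fitted values agree with the least-squares fit too
    expect_equal(drop(Xs %*% fit$b), drop(Xs %*% minnorm_ls(Xs, ys)),
                 tolerance = 1e-6)
  }
})

test_that("scores are orthogonal, fit is monotone, and sign/scale equivariance holds", {
  ds <- simulate_dataset(seed = 13)
  y <- reciprocal_response(ds$ccl17)
  sc <- suppressWarnings(autoscale(ds$X))
  ys <- drop(scale(y))
  fit <- fit_pls1(sc$data, ys, 8)

  G <- crossprod(fit$T)
  offdiag <- abs(G[upper.tri(G)])
  expect_lt(max(offdiag), 1e-8 * max(diag(G)))
  expect_true(all(diff(fit$var_y_cum) >= -1e-10))
  expect_true(all(diff(fit$var_x_cum) >= -1e-10))
  expect_lte(max(fit$var_x_cum, fit$var_y_cum), 100 + 1e-6)

  # flipping the response sign flips every coefficient exactly
  fit_neg <- fit_pls1(sc$data, -ys, 8)
  expect_equal(fit_neg$b, -fit$b, tolerance = 1e-12)

  # rescaling a raw column is absorbed by autoscaling
  X2 <- ds$X
  X2[, 5] <- X2[, 5] * 1234
  sc2 <- suppressWarnings(autoscale(X2))
  fit2 <- fit_pls1(sc2$data, ys, 8)
  expect_equal(fit2$b, fit$b, tolerance = 1e-9)

  # in-sample predictions reproduce the fits; zero-signal model predicts the mean
  ysc <- autoscale(y)
  pred <- predict(fit, ds$X, x_scaling = sc, y_scaling = ysc)
  expect_equal(pred, drop(unscale(ysc, matrix(sc$data %*% fit$b))),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("leave-one-out RMSECV equals a literal refit-per-fold oracle", {
  ds <- simulate_dataset(seed = 17)
  y <- reciprocal_response(ds$ccl17)
  A_max <- 6
  curve <- loo_rmsecv(ds$X, y, A_max = A_max)

  n <- nrow(ds$X)
  ysd_full <- sd(y)
  err <- matrix(NA_real_, n, A_max)
  for (j in seq_len(n)) {
    for (A in seq_len(A_max)) {   # separate refit for every A: no shortcuts
      sc <- suppressWarnings(autoscale(ds$X[-j, , drop = FALSE]))
      ymu <- mean(y[-j]); ysd <- sd(y[-j])
      f <- fit_pls1(sc$data, (y[-j] - ymu) / ysd, A)
      z <- apply_scaling(sc, ds$X[j, , drop = FALSE])
      err[j, A] <- (y[j] - (ymu + ysd * drop(z %*% f$b))) / ysd_full
    }
  }
  expect_equal(curve$rmsecv, sqrt(colMeans(err^2)), tolerance = 1e-10)

  # noiseless linear data: error collapses once the true dimension is reached
  ds0 <- simulate_dataset(seed = 19, sigma_x = 0, sigma_y_rel = 0)
  y0 <- reciprocal_response(ds0$ccl17)
  r0 <- suppressWarnings(loo_rmsecv(ds0$X, y0, A_max = 8))  # deflation exhausts early
  expect_lt(min(r0$rmsecv), 1e-6)
  expect_error(loo_rmsecv(ds$X[1:2, ], y[1:2]), "at least 3")
})

test_that("latent-variable selection follows the relative-improvement rule", {
  # plateau after a final 2.5% improvement step: largest qualifying step wins
  expect_equal(select_n_components(c(1.0, 0.6, 0.4, 0.39, 0.388), rel_tol = 0.02), 4L)
  expect_equal(select_n_components(c(1.0, 0.6, 0.4, 0.398, 0.396), rel_tol = 0.02), 3L)
  # monotone increasing curve: no qualifying step
  expect_equal(select_n_components(c(0.8, 0.9, 1.1)), 1L)
  expect_equal(select_n_components(c(1.0, 0.5, 0.49), rule = "min"), 3L)
  expect_equal(select_n_components(c(1.0, 0.5, 0.49), override = 2), 2L)
  expect_error(select_n_components(numeric(0)), "empty")
  expect_error(select_n_components(c(1, 0.5), override = 9), "range")

  # LOO training-size bound: 13 samples can never select more than 11 LVs
  for (s in 1:5) {
    ds <- simulate_dataset(seed = s)
    curve <- loo_rmsecv(ds$X, reciprocal_response(ds$ccl17))
    expect_lte(select_n_components(curve), 11L)
  }
})
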