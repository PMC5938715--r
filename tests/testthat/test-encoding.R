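test_that("lagged design columns are shifted copies of the regressor", {
  v <- c(1, 2, 3, 4, 5, 6)
  r <- vals_regressor(v, fs = 1, t0 = 0)
  # single regressor, lag 0 only -> the regressor itself
  S0 <- build_lagged_design(list(r), 6, ridge_config(0, -0.4, 0.4))
  expect_equal(ncol(S0), 1)  # shifts round to just lag 0 at fs = 1
  expect_equal(as.numeric(S0), v)
  # unit impulse, lags {-1, 0, +1} samples -> three shifted impulses
  imp <- vals_regressor(c(0, 0, 1, 0, 0), fs = 1, t0 = 0)
  S <- build_lagged_design(list(imp), 5, ridge_config(0, -1, 1))
  expect_equal(ncol(S), 3)
  expect_equal(S[, 1], c(0, 1, 0, 0, 0))  # lag -1: response precedes
  expect_equal(S[, 2], c(0, 0, 1, 0, 0))  # lag 0
  expect_equal(S[, 3], c(0, 0, 0, 1, 0))  # lag +1: regressor leads
  expect_equal(attr(S, "lags"), c(-1, 0, 1))
})

test_that("the study lag window at 200 Hz gives 2 x 161 = 322 columns", {
  n <- 521
  r1 <- const_regressor(1, n)
  r2 <- vals_regressor(seq_len(n) / n)
  S <- build_lagged_design(list(monotonic = r1, modulated = r2), n,
                           ridge_config(4, -0.2, 0.6))
  expect_equal(ncol(S), (0.8 * 200 + 1) * 2)
  expect_length(attr(S, "lags"), 161)
  expect_error(build_lagged_design(list(r1), 100, ridge_config(4, -0.2, 0.6)),
               "invalid-lags")
})

test_that("lagged design matches an independent naive construction", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(20:50, 1)
    v1 <- rnorm(n); v2 <- rnorm(n)
    sh_min <- sample(-4:0, 1); sh_max <- sample(1:4, 1)
    S <- build_lagged_design(
      list(vals_regressor(v1, fs = 1, t0 = 0), vals_regressor(v2, fs = 1, t0 = 0)),
      n, ridge_config(1, sh_min, sh_max))
    expect_equal(unclass(S), naive_lagged(list(v1, v2), n, sh_min:sh_max),
                 ignore_attr = TRUE)
  }
})

test_that("ridge at lambda = 0 equals ordinary least squares", {
  set.seed(4)
  n <- 40
  r <- vals_regressor(rnorm(n), fs = 1, t0 = 0)
  cfg <- ridge_config(0, -2, 2)
  S <- build_lagged_design(list(r), n, cfg)
  y <- rnorm(n)
  w <- fit_trf(S, y, cfg)
  ols <- qr.solve(unclass(S), y)
  expect_equal(as.numeric(w$weights), as.numeric(ols), tolerance = 1e-8)
})

test_that("ridge solution matches the augmented-QR oracle on random instances", {
  set.seed(5)
  for (i in 1:30) {
    n <- sample(15:50, 1)
    n_reg <- sample(1:2, 1)
    sh <- sample(1:2, 1)
    regs <- lapply(seq_len(n_reg), function(...)
      vals_regressor(rnorm(n), fs = 1, t0 = 0))
    cfg <- ridge_config(runif(1, 0.1, 10), -sh, sh)
    S <- build_lagged_design(regs, n, cfg)
    R <- matrix(rnorm(n * 2), n, 2)
    fit <- fit_trf(S, R, cfg)
    W_oracle <- ridge_oracle(unclass(S), R, cfg$lambda)
    W_fit <- matrix(aperm(fit$weights, c(1, 3, 2)), ncol = 2)
    expect_equal(W_fit, W_oracle, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("weights shrink monotonically with lambda", {
  set.seed(6)
  n <- 60
  r <- vals_regressor(rnorm(n), fs = 1, t0 = 0)
  S <- build_lagged_design(list(r), n, ridge_config(1, -3, 3))
  y <- rnorm(n)
  norms <- vapply(c(0.01, 0.1, 1, 10, 100, 1e4), function(lam)
    sqrt(sum(fit_trf(S, y, ridge_config(lam, -3, 3))$weights^2)), 0)
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[length(norms)], 1e-2 * norms[1])
})

test_that("a rank-deficient design at lambda 0 is a clear error", {
  n <- 30
  r <- vals_regressor(rep(0, n), fs = 1, t0 = 0)  # all-zero: singular gram
  cfg <- ridge_config(0, -1, 1)
  S <- build_lagged_design(list(r), n, cfg)
  expect_error(fit_trf(S, rnorm(n), cfg), "rank-deficiency")
})

test_that("fitting is equivariant under channel permutation", {
  set.seed(7)
  n <- 50
  r <- vals_regressor(rnorm(n), fs = 1, t0 = 0)
  cfg <- ridge_config(2, -2, 2)
  S <- build_lagged_design(list(r), n, cfg)
  R <- matrix(rnorm(n * 4), n, 4)
  perm <- c(3, 1, 4, 2)
  w1 <- fit_trf(S, R, cfg)$weights[, perm, , drop = FALSE]
  w2 <- fit_trf(S, R[, perm], cfg)$weights
  expect_equal(w1, w2)
})

test_that("noiseless lag-convolved trials recover the generating weights", {
  set.seed(8)
  n <- 400
  cfg <- ridge_config(1e-6, -0.05, 0.15)
  r1 <- vals_regressor(rnorm(n, sd = 1), fs = 100, t0 = 0)
  r2 <- vals_regressor(rnorm(n, sd = 1), fs = 100, t0 = 0)
  S <- build_lagged_design(list(a = r1, b = r2), n, cfg)
  lags <- attr(S, "lags")
  w_star <- cbind(dnorm(lags, 0.05, 0.02), -dnorm(lags, 0.08, 0.03))
  y <- unclass(S) %*% as.numeric(w_star)
  fit <- fit_trf(S, y, cfg)
  interior <- seq(3, length(lags) - 2)
  for (k in 1:2)
    expect_gt(cor(fit$weights[interior, 1, k], w_star[interior, k]), 0.99)
})

test_that("TRF averaging is the elementwise mean with axis checks", {
  set.seed(9)
  n <- 40
  r <- vals_regressor(rnorm(n), fs = 1, t0 = 0)
  cfg <- ridge_config(1, -1, 1)
  S <- build_lagged_design(list(r), n, cfg)
  w <- fit_trf(S, rnorm(n), cfg)
  expect_equal(average_trfs(list(w))$weights, w$weights)
  neg <- w; neg$weights <- -w$weights
  expect_equal(average_trfs(list(w, neg))$weights, 0 * w$weights)
  expect_equal(average_trfs(list(w, w, w))$weights, w$weights)
  other <- fit_trf(build_lagged_design(list(r), n, ridge_config(1, -2, 2)),
                   rnorm(n), ridge_config(1, -2, 2))
  expect_error(average_trfs(list(w, other)), "alignment")
})

test_that("global field power is the across-channel SD and permutation-invariant", {
  set.seed(10)
  n <- 30
  r <- vals_regressor(rnorm(n), fs = 1, t0 = 0)
  cfg <- ridge_config(1, -1, 1)
  S <- build_lagged_design(list(r), n, cfg)
  R <- matrix(rnorm(n * 5), n, 5)
  w <- fit_trf(S, R, cfg)
  g <- global_field_power(w)
  expect_equal(dim(g), c(3, 1))
  # identical weights on all channels -> zero GFP
  w0 <- w
  w0$weights[] <- rep(w$weights[, 1, ], times = 5)[seq_along(w0$weights)]
  for (ch in 1:5) w0$weights[, ch, ] <- w$weights[, 1, ]
  expect_equal(as.numeric(global_field_power(w0)), rep(0, 3))
  # one +1, one -1, rest 0 at a single lag -> positive GFP only there
  w1 <- w
  w1$weights[] <- 0
  w1$weights[2, 1, 1] <- 1
  w1$weights[2, 2, 1] <- -1
  g1 <- global_field_power(w1)
  expect_gt(g1[2, 1], 0)
  expect_equal(g1[c(1, 3), 1], c(0, 0))
  # channel permutation invariance
  wp <- w
  wp$weights <- w$weights[, c(4, 2, 5, 1, 3), , drop = FALSE]
  expect_equal(global_field_power(wp), g)
  # single channel undefined
  w_single <- fit_trf(S, R[, 1], cfg)
  expect_error(global_field_power(w_single), "undefined-GFP")
})

test_that("prediction is the linear forward map S W", {
  set.seed(11)
  n <- 80
  r <- vals_regressor(rnorm(n), fs = 1, t0 = 0)
  cfg <- ridge_config(1e-8, -2, 2)
  S <- build_lagged_design(list(r), n, cfg)
  y <- matrix(rnorm(n * 2), n, 2)
  w <- fit_trf(S, y, cfg)
  # zero TRF -> zero prediction
  w0 <- w; w0$weights[] <- 0
  expect_equal(predict_response(w0, S), matrix(0, n, 2))
  # in-sample prediction of a noiseless fit correlates ~ 1
  clean <- unclass(S) %*% rnorm(ncol(S))
  wfit <- fit_trf(S, clean, cfg)
  expect_gt(cor(as.numeric(predict_response(wfit, S)), as.numeric(clean)),
            0.999)
  # linearity in the weights: predict(aW1 + bW2) = a predict(W1) + b predict(W2)
  wb <- fit_trf(S, matrix(rnorm(n * 2), n, 2), cfg)
  wc <- w
  wc$weights <- 3 * w$weights - 0.7 * wb$weights
  expect_equal(predict_response(wc, S),
               3 * predict_response(w, S) - 0.7 * predict_response(wb, S),
               tolerance = 1e-10)
})

test_that("TRFs export as long-format CSV with all axes", {
  set.seed(12)
  n <- 25
  r <- vals_regressor(rnorm(n), fs = 1, t0 = 0)
  cfg <- ridge_config(1, -1, 1)
  S <- build_lagged_design(list(haz = r), n, cfg)
  w <- fit_trf(S, matrix(rnorm(n * 2), n, 2), cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trf_csv(w, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 3 * 2 * 1)
  expect_equal(back$weight, as.numeric(w$weights))
})
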