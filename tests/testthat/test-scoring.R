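test_that("Fisher z is atanh with clipping at |r| = 1", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))   # atanh closed form
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisher_z(-r), -fisher_z(r))    # antisymmetry
  expect_warning(z <- fisher_z(c(0.2, 1)), "clipped")
  expect_true(is.finite(z[2]))
})

test_that("t-based confidence intervals behave at edge cases and calibrate", {
  ci <- correlation_ci(rep(0.3, 5))
  expect_equal(ci$ci_z, c(0.3, 0.3))          # zero width
  ci2 <- correlation_ci(c(-0.4, 0.4, -0.1, 0.1))
  expect_equal(ci2$mean_z, 0)
  expect_equal(sum(ci2$ci_z), 0)              # centred at 0
  expect_error(correlation_ci(0.2), "insufficient-data")
  # coverage under the null ~ 95%
  set.seed(123)
  cover <- mean(replicate(1000, {
    ci <- correlation_ci(rnorm(10, 0, 0.2))
    ci$ci_z[1] <= 0 && ci$ci_z[2] >= 0
  }))
  expect_gt(cover, 0.93)
  expect_lt(cover, 0.97)
})

test_that("the correlation index is a bounded, antisymmetric, monotone tie-breaker", {
  expect_equal(correlation_index(0.3, 0.3), 0)          # tie
  expect_gt(correlation_index(0.4, 0.1), 0)
  expect_lt(correlation_index(0.1, 0.4), 0)
  set.seed(31)
  a <- rnorm(200, sd = 2)
  b <- rnorm(200, sd = 2)
  idx <- correlation_index(a, b)
  expect_true(all(idx > -1 & idx < 1))                   # bounded
  expect_equal(correlation_index(b, a), -idx)            # antisymmetry
  # r-scale variant agrees in sign
  expect_equal(sign(correlation_index(a, b, on = "r")), sign(idx))
})

# small two-condition synthetic epoch set with condition-specific TRFs
scored_fixture <- function(snr = 4, n_trials = 10, seed = 99) {
  set.seed(seed)
  fs <- 100
  n <- 150
  cfg <- ridge_config(1, -0.05, 0.2)
  r1 <- vals_regressor(stats::filter(rnorm(n), rep(1, 5) / 5, circular = TRUE),
                       fs = fs, t0 = 0)
  r2 <- vals_regressor(stats::filter(rnorm(n), rep(1, 5) / 5, circular = TRUE),
                       fs = fs, t0 = 0)
  regs <- list(monotonic = r1, modulated = r2)
  S <- build_lagged_design(regs, n, cfg)
  lags <- attr(S, "lags")
  w_a <- c(dnorm(lags, 0.05, 0.03), 0.1 * dnorm(lags, 0.1, 0.04))
  w_b <- c(0.1 * dnorm(lags, 0.05, 0.03), dnorm(lags, 0.1, 0.04))
  n_chan <- 2
  mk <- function(w, cond) {
    clean <- as.numeric(unclass(S) %*% w)
    clean <- clean / sd(clean)
    dat <- array(0, dim = c(n_trials, n_chan, n))
    for (i in seq_len(n_trials)) for (ch in seq_len(n_chan))
      dat[i, ch, ] <- snr * clean + rnorm(n)
    epoch_set(dat, fs, 0,
              data.frame(foreperiod = rep(1.3, n_trials), condition = cond))
  }
  ea <- mk(w_a, "nonpredictive")
  eb <- mk(w_b, "strongly_predictive")
  dat <- array(0, dim = c(2 * n_trials, n_chan, n))
  dat[seq_len(n_trials), , ] <- ea$data
  dat[n_trials + seq_len(n_trials), , ] <- eb$data
  ep <- epoch_set(dat, fs, 0, rbind(ea$trials, eb$trials))
  list(epochs = ep, regs = regs, cfg = cfg)
}

test_that("matched training conditions score higher than mismatched ones", {
  fx <- scored_fixture()
  sc <- loo_predict_scores(fx$epochs, fx$regs, fx$cfg)
  expect_s3_class(sc, "score_table")
  expect_true(all(abs(sc$r) <= 1, na.rm = TRUE))
  m <- tapply(sc$z, sc[, c("testing_condition", "training_condition")], mean)
  expect_gt(m["nonpredictive", "nonpredictive"],
            m["nonpredictive", "strongly_predictive"])
  expect_gt(m["strongly_predictive", "strongly_predictive"],
            m["strongly_predictive", "nonpredictive"])
  # indices carry the same ordering
  ind <- score_indices(sc)
  mi <- tapply(ind$index, ind$testing_condition, mean)
  expect_gt(mi["nonpredictive"], 0)
  expect_lt(mi["strongly_predictive"], 0)
  # participant x channel aggregation has the right shape
  M <- index_matrix(ind, "nonpredictive")
  expect_equal(dim(M), c(1, 2))
})

test_that("with two identical trials the LOO model is the other trial's TRF", {
  set.seed(41)
  fs <- 100
  n <- 120
  cfg <- ridge_config(1, -0.05, 0.1)
  r1 <- vals_regressor(rnorm(n), fs = fs, t0 = 0)
  regs <- list(haz = r1)
  trial <- matrix(rnorm(n * 2), n, 2)
  dat <- array(0, dim = c(2, 2, n))
  dat[1, , ] <- t(trial)
  dat[2, , ] <- t(trial)
  ep <- epoch_set(dat, fs, 0,
                  data.frame(foreperiod = c(1.1, 1.1),
                             condition = c("a", "a")))
  sc <- loo_predict_scores(ep, regs, cfg)
  # both trials identical -> both get the same (other-trial) TRF and score
  expect_equal(sc$r[sc$trial == 1], sc$r[sc$trial == 2])
  # and that score equals predicting a trial from its own single-trial TRF
  S <- build_lagged_design(regs, n, cfg)
  w <- fit_trf(S, trial, cfg)
  pred <- predict_response(w, S)
  k <- sum((0:(n - 1)) / fs <= 1.1)
  r_direct <- vapply(1:2, function(ch)
    cor(pred[seq_len(k), ch], trial[seq_len(k), ch]), 0)
  expect_equal(sort(unique(round(sc$r, 12))), sort(round(r_direct, 12)))
})

test_that("pure-noise trials give prediction correlations centred on zero", {
  set.seed(51)
  fs <- 100
  n <- 150
  cfg <- ridge_config(4, -0.05, 0.2)
  regs <- list(
    monotonic = vals_regressor(seq(0, 1, length.out = n), fs = fs, t0 = 0),
    modulated = vals_regressor(dnorm(seq_len(n), n / 2, n / 8), fs = fs, t0 = 0))
  dat <- array(rnorm(30 * 2 * n), dim = c(30, 2, n))
  ep <- epoch_set(dat, fs, 0,
                  data.frame(foreperiod = rep(1.4, 30),
                             condition = rep(c("a", "b"), 15)))
  sc <- loo_predict_scores(ep, regs, cfg)
  ci <- correlation_ci(sc$z)
  expect_gt(ci$ci_z[2], 0)
  expect_lt(ci$ci_z[1], 0)
})

test_that("score summaries report one row per condition pair", {
  fx <- scored_fixture(n_trials = 5)
  sc <- loo_predict_scores(fx$epochs, fx$regs, fx$cfg)
  summ <- summarize_scores(sc)
  expect_equal(nrow(summ), 4)
  expect_true(all(summ$ci_lo_r <= summ$mean_r & summ$mean_r <= summ$ci_hi_r))
})
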