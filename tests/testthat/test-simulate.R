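test_that("the default schedule reproduces the study's trial arithmetic", {
  spec <- simulation_spec(n_participants = 1)
  sched <- simulate_schedule(spec, seed = 10)
  # 546 trials per participant; one block of each condition holds 91
  expect_equal(nrow(sched), 546)
  per_block <- table(sched$block)
  expect_equal(sort(unique(as.integer(per_block))), c(25L, 32L, 34L))
  per_cond <- table(sched$condition)
  expect_equal(as.integer(per_cond[c("nonpredictive", "weakly_predictive",
                                     "strongly_predictive")]),
               c(6 * 25L, 6 * 32L, 6 * 34L))
  # every nonpredictive block contains all 25 grid foreperiods
  grid <- build_foreperiod_distribution(study_conditions()$nonpredictive)$times
  np_blocks <- unique(sched$block[sched$condition == "nonpredictive"])
  for (b in np_blocks)
    expect_setequal(round(sched$foreperiod[sched$block == b], 10),
                    round(grid, 10))
  # each condition appears as three consecutive blocks per half
  for (half in 1:2) {
    runs <- rle(sched$condition[sched$half == half][!duplicated(
      sched$block[sched$half == half])])
    expect_equal(runs$lengths, rep(3L, 3))
  }
  # ISIs truncated at 5 s and positive
  expect_true(all(sched$isi > 0 & sched$isi <= 5))
})

test_that("schedules are reproducible and differ across participants", {
  spec <- simulation_spec(n_participants = 2)
  s1 <- simulate_schedule(spec, seed = 3)
  s2 <- simulate_schedule(spec, seed = 3)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 2 * 546)
})

test_that("ground-truth TRFs peak where asked and scale with the gains", {
  spec <- tiny_spec()
  w <- simulate_ground_truth_trf(spec, "nonpredictive", peak_lag = 0)
  gfp_mono <- apply(abs(w$weights[, , 1]), 1, max)
  expect_equal(w$lags[which.max(gfp_mono)], 0)
  # two conditions differ only by regressor gains
  g <- condition_gains()
  w_np <- simulate_ground_truth_trf(spec, "nonpredictive")
  w_sp <- simulate_ground_truth_trf(spec, "strongly_predictive")
  ratio_mono <- w_sp$weights[, , 1] / w_np$weights[, , 1]
  ratio_mod <- w_sp$weights[, , 2] / w_np$weights[, , 2]
  expect_equal(unique(round(as.numeric(ratio_mono), 10)),
               round(g$strongly_predictive[["monotonic"]] /
                     g$nonpredictive[["monotonic"]], 10))
  expect_equal(unique(round(as.numeric(ratio_mod), 10)),
               round(g$strongly_predictive[["modulated"]] /
                     g$nonpredictive[["modulated"]], 10))
})

test_that("coloured noise has the requested spectral slope", {
  set.seed(12)
  n <- 2048
  x <- colored_noise(n, 50, exponent = 1, fs = 200)
  # average periodogram over traces, fit log-log slope
  spec_avg <- rowMeans(apply(x, 2, function(v) abs(fft(v))[2:(n / 2)]^2))
  f <- (1:(n / 2 - 1)) * 200 / n
  keep <- f > 1 & f < 50
  slope <- coef(lm(log(spec_avg[keep]) ~ log(f[keep])))[2]
  expect_lt(abs(slope - (-1)), 0.3)
  # white noise has ~ zero slope
  xw <- colored_noise(n, 50, exponent = 0, fs = 200)
  specw <- rowMeans(apply(xw, 2, function(v) abs(fft(v))[2:(n / 2)]^2))
  slope_w <- coef(lm(log(specw[keep]) ~ log(f[keep])))[2]
  expect_lt(abs(slope_w), 0.2)
  # traces are standardised
  expect_equal(apply(x, 2, sd), rep(1, 50), tolerance = 1e-12)
})

test_that("simulated epochs honour the shape contract and the snr limits", {
  spec <- tiny_spec()
  sched <- simulate_schedule(spec, seed = 5)
  sched <- sched[sched$participant == 1, ]
  regs <- study_hazard_regressors(fs = spec$fs, window = spec$window)
  cfg <- ridge_config()
  trfs <- lapply(setNames(nm = names(study_conditions())), function(cnd)
    simulate_ground_truth_trf(spec, cnd, cfg))
  ep <- simulate_epochs(sched, trfs, regs, spec, cfg, seed = 6)
  n_samp <- length(seq(spec$window[1], spec$window[2], by = 1 / spec$fs))
  expect_equal(dim(ep$data), c(nrow(sched), spec$n_channels, n_samp))
  expect_equal(ep$fs, spec$fs)
  expect_equal(ep$t0, spec$window[1])
  # snr = 0: pure noise, unit-SD traces
  spec0 <- tiny_spec(snr = 0)
  ep0 <- simulate_epochs(sched, trfs, regs, spec0, cfg, seed = 6)
  sds <- apply(ep0$data[1:5, 1, ], 1, sd)
  expect_equal(sds, rep(1, 5), tolerance = 1e-10)
  # snr = Inf: noiseless, and the signal is truncated at target onset
  specInf <- tiny_spec(snr = Inf)
  epInf <- simulate_epochs(sched, trfs, regs, specInf, cfg, seed = 6)
  tt <- epoch_times(epInf)
  for (i in 1:10)
    expect_true(all(epInf$data[i, , tt > sched$foreperiod[i] + 1e-9] == 0))
})

test_that("noiseless epochs let fit_trf recover the generating TRF", {
  spec <- tiny_spec(snr = Inf)
  cfg <- ridge_config(lambda = 1e-4)
  regs <- study_hazard_regressors(fs = spec$fs, window = spec$window)
  trfs <- list(nonpredictive = simulate_ground_truth_trf(spec, "nonpredictive", cfg))
  sched <- data.frame(participant = 1, block = 1,
                      condition = "nonpredictive", foreperiod = 3.1)
  ep <- simulate_epochs(sched, trfs, regs, spec, cfg)
  S <- build_lagged_design(regs, dim(ep$data)[3], cfg)
  fit <- fit_trf(S, t(ep$data[1, , ]), cfg)
  interior <- which(fit$lags > -0.15 & fit$lags < 0.55)
  for (k in 1:2) {
    w_hat <- as.numeric(fit$weights[interior, , k])
    w_true <- as.numeric(trfs$nonpredictive$weights[interior, , k])
    expect_gt(cor(w_hat, w_true), 0.99)
  }
})

test_that("resting snippets are reproducible condition-free noise", {
  spec <- tiny_spec()
  sched <- simulate_schedule(spec, seed = 8)
  sched <- sched[sched$participant == 1, ]
  r1 <- simulate_resting_snippets(sched, spec, seed = 9)
  r2 <- simulate_resting_snippets(sched, spec, seed = 9)
  expect_identical(r1$data, r2$data)
  expect_equal(dim(r1$data)[1], nrow(sched))
  # pseudo-metadata copied from the task schedule
  expect_equal(r1$trials$foreperiod, sched$foreperiod)
  expect_equal(r1$trials$condition, as.character(sched$condition))
})
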