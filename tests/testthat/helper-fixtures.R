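# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# Discrete uniform foreperiod distribution on [a, b] with n points,
# bypassing condition_spec (used for degenerate/edge cases).
uniform_dist <- function(n, a = 0.5, b = 3.1) {
  times <- seq(a, b, length.out = n)
  probs <- rep(1 / n, n)
  structure(list(times = times, probs = probs, cum = cumsum(probs),
                 counts = rep(1L, n), label = "uniform"),
            class = "fp_distribution")
}

# Independent brute-force hazard oracle: direct evaluation of
# H = f / (1 - C) with inclusive C, replacement and normalisation done
# step by step (no shared code with compute_hazard).
hazard_oracle <- function(probs) {
  C <- cumsum(probs)
  H <- probs / (1 - C)
  fin <- H[is.finite(H)]
  m <- max(fin)
  H[!is.finite(H)] <- m
  H / m
}

# Constant-value regressor on the standard grid.
const_regressor <- function(value, n, fs = 200, t0 = 0.5,
                            kind = "monotonic") {
  hazardTRF:::new_hazard_regressor(kind, fs, t0, rep(value, n))
}

# Regressor from explicit values.
vals_regressor <- function(values, fs = 200, t0 = 0.5, kind = "monotonic") {
  hazardTRF:::new_hazard_regressor(kind, fs, t0, values)
}

# Small epoch set: deterministic sinusoid + per-trial offset signal.
toy_epochs <- function(n_trials = 4, n_chan = 3, n_samp = 120, fs = 100,
                       t0 = 0, foreperiods = NULL, condition = "a",
                       data = NULL) {
  if (is.null(foreperiods))
    foreperiods <- seq(0.4, 1.0, length.out = n_trials)
  if (is.null(data)) {
    data <- array(0, dim = c(n_trials, n_chan, n_samp))
    tt <- t0 + (seq_len(n_samp) - 1) / fs
    for (i in seq_len(n_trials))
      for (ch in seq_len(n_chan))
        data[i, ch, ] <- sin(2 * pi * (2 + ch) * tt) + 0.1 * i
  }
  epoch_set(data, fs, t0,
            data.frame(foreperiod = rep_len(foreperiods, n_trials),
                       condition = rep_len(condition, n_trials)))
}

# Independent naive lagged-design oracle: explicit time-index double loop.
naive_lagged <- function(values_list, n, shifts) {
  ncols <- length(values_list) * length(shifts)
  S <- matrix(0, n, ncols)
  col <- 0
  for (v in values_list) {
    for (sh in shifts) {
      col <- col + 1
      for (t in seq_len(n)) {
        src <- t - sh
        if (src >= 1 && src <= n) S[t, col] <- v[src]
      }
    }
  }
  S
}

# Independent ridge oracle: augmented least squares
# [S; sqrt(lambda*m) I] w = [r; 0], solved by QR, per channel.
ridge_oracle <- function(S, R, lambda) {
  m <- mean(diag(crossprod(S)))
  aug <- rbind(S, sqrt(lambda * m) * diag(ncol(S)))
  apply(as.matrix(R), 2, function(r)
    qr.solve(aug, c(r, rep(0, ncol(S)))))
}

# Tiny simulation spec for fast end-to-end tests.
tiny_spec <- function(...) {
  simulation_spec(n_participants = 2, n_blocks_per_condition = 2,
                  n_channels = 6, ...)
}
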