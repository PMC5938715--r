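# Zero-phase Butterworth low-pass, applied columnwise to a samples x traces
# matrix. Coefficients from signal::butter; the forward and backward passes
# run through stats::filter (C loops) so that thousands of trial x channel
# traces filter in one call. Edge handling for short epochs: odd-reflection
# padding of 3 * order samples plus constant-pre-history initial conditions
# (the filter starts in steady state at the first padded value), so a DC
# trace passes through exactly.
butter_lowpass <- function(x, cutoff, fs, order = 6) {
  stopifnot(is.matrix(x))
  if (cutoff >= fs / 2)
    stop("invalid-filter: cutoff must be below the Nyquist frequency ",
         fs / 2, " Hz", call. = FALSE)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  n <- nrow(x)
  pad <- min(n - 1L, 3L * order)
  if (pad > 0) {
    # odd reflection about the end samples preserves level and slope
    top <- 2 * x[rep(1L, pad), , drop = FALSE] -
      x[rev(seq_len(pad) + 1L), , drop = FALSE]
    bot <- 2 * x[rep(n, pad), , drop = FALSE] -
      x[n - seq_len(pad), , drop = FALSE]
    xp <- rbind(top, x, bot)
  } else xp <- x
  y <- iir_filter_mat(bf$b, bf$a, xp)                            # forward
  y <- iir_filter_mat(bf$b, bf$a, y[nrow(y):1, , drop = FALSE])  # backward
  y <- y[nrow(y):1, , drop = FALSE]
  y[pad + seq_len(n), , drop = FALSE]
}

# One-pass IIR filter y = filter(b, a, x) on each column of x, with
# constant-pre-history initial conditions: inputs before the first sample
# are taken equal to it, and past outputs sit at the corresponding steady
# state, eliminating the start-up transient for locally constant signals.
iir_filter_mat <- function(b, a, x) {
  nb <- length(b)
  na <- length(a)
  x1 <- x[rep(1L, max(nb - 1L, 1L)), , drop = FALSE]
  v <- stats::filter(rbind(x1, x), b, method = "convolution", sides = 1)
  v <- v[-seq_len(nb - 1L), , drop = FALSE]
  dc_gain <- sum(b) / sum(a)
  init <- matrix(rep(x[1L, ] * dc_gain, each = na - 1L), na - 1L, ncol(x))
  y <- stats::filter(v, -a[-1], method = "recursive", init = init)
  matrix(as.numeric(y), nrow = nrow(x), ncol = ncol(x))
}

# Discrete analytic signal via FFT (Marple's method); returns a complex
# vector whose modulus is the envelope of x.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
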