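#' Simulation specification
#'
#' Defines the synthetic cohort: number of participants and blocks, sensor
#' montage, sampling rate, signal-to-noise ratio of the hazard-driven EEG
#' component, and the spectral slope of the coloured background noise.
#' Defaults reproduce the reference design's trial structure (24
#' participants, 6 blocks per condition, per-block trial counts from the
#' condition specs) on a 16-channel synthetic montage.
#'
#' @param n_participants Number of simulated participants, default 24.
#' @param n_blocks_per_condition Blocks per condition, default 6.
#' @param n_channels Number of channels, default 16.
#' @param fs Sampling rate (Hz), default 200.
#' @param snr Amplitude ratio of the TRF-driven signal to the noise
#'   (RMS over the pre-target window), default 0.5; `0` gives pure noise,
#'   `Inf` noiseless signal.
#' @param noise_exponent Spectral slope of the coloured noise (power ~
#'   1/f^exponent), default 1.
#' @param window Epoch window (s after cue), default `c(0.5, 3.1)`.
#' @param isi_mean,isi_max Inter-stimulus interval: exponential with this
#'   mean (s), redrawn until at most `isi_max` (s). Defaults 1.5 and 5.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_participants = 24, n_blocks_per_condition = 6,
                            n_channels = 16, fs = 200, snr = 0.5,
                            noise_exponent = 1, window = c(0.5, 3.1),
                            isi_mean = 1.5, isi_max = 5) {
  stopifnot(n_participants >= 1, n_blocks_per_condition >= 1,
            n_channels >= 1, fs > 0, snr >= 0, length(window) == 2,
            window[2] > window[1])
  structure(list(n_participants = as.integer(n_participants),
                 n_blocks_per_condition = as.integer(n_blocks_per_condition),
                 n_channels = as.integer(n_channels), fs = fs, snr = snr,
                 noise_exponent = noise_exponent, window = window,
                 isi_mean = isi_mean, isi_max = isi_max),
            class = "simulation_spec")
}

#' Synthetic sensor layout
#'
#' Places channels on a near-square 2-D grid (unit spacing), the layout
#' used for topographies and the k-nearest-neighbour adjacency.
#'
#' @param n_channels Number of channels.
#' @return Numeric matrix, channels x 2, rownames `ch01 ...`.
#' @export
simulate_layout <- function(n_channels) {
  ncol_grid <- ceiling(sqrt(n_channels))
  i <- seq_len(n_channels) - 1L
  coords <- cbind(x = i %% ncol_grid, y = i %/% ncol_grid)
  rownames(coords) <- sprintf("ch%02d", seq_len(n_channels))
  coords
}

#' Simulate a trial schedule
#'
#' Builds the per-participant trial table: six-per-condition blocks are
#' arranged as three consecutive blocks per condition within each
#' experiment half (condition order randomised per half); within a block,
#' every discrete foreperiod of the condition's distribution appears with
#' its planned multiplicity, in random (counterbalanced) order.
#' Inter-stimulus intervals are exponential (mean `spec$isi_mean`), redrawn
#' until at most `spec$isi_max`.
#'
#' @param spec A [simulation_spec()].
#' @param conditions Named list of [condition_spec()]s, default
#'   [study_conditions()].
#' @param seed Optional integer seed.
#' @return Data frame with columns `participant`, `half`, `block`,
#'   `condition`, `foreperiod`, `isi`.
#' @export
simulate_schedule <- function(spec, conditions = study_conditions(),
                              seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(seed)) set.seed(seed)
  dists <- lapply(conditions, build_foreperiod_distribution)
  labels <- unname(vapply(conditions, `[[`, "", "label"))
  n_halves <- 2L
  blocks_per_half <- spec$n_blocks_per_condition / n_halves
  if (blocks_per_half != floor(blocks_per_half))
    stop("n_blocks_per_condition must be even (split over two halves)",
         call. = FALSE)
  out <- vector("list", 0L)
  for (pp in seq_len(spec$n_participants)) {
    blk <- 0L
    for (half in seq_len(n_halves)) {
      for (cond_i in sample(seq_along(conditions))) {
        d <- dists[[cond_i]]
        for (b in seq_len(blocks_per_half)) {
          blk <- blk + 1L
          fps <- sample(rep(d$times, times = d$counts))
          isi <- vapply(fps, function(...) {
            x <- stats::rexp(1, rate = 1 / spec$isi_mean)
            while (x > spec$isi_max) x <- stats::rexp(1, rate = 1 / spec$isi_mean)
            x
          }, 0)
          out[[length(out) + 1L]] <- data.frame(
            participant = pp, half = half, block = blk,
            condition = labels[cond_i], foreperiod = fps, isi = isi)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default ground-truth regressor gains per condition
#'
#' The monotonic-hazard component is strongest in the nonpredictive
#' condition and the modulated component strongest in the strongly
#' predictive condition; the weakly predictive condition sits at the
#' midpoint, so its model comparisons come out near a tie.
#'
#' @return Named list of length-2 numeric vectors
#'   `c(monotonic, modulated)`.
#' @export
condition_gains <- function() {
  list(nonpredictive = c(monotonic = 1.0, modulated = 0.1),
       weakly_predictive = c(monotonic = 0.75, modulated = 0.55),
       strongly_predictive = c(monotonic = 0.5, modulated = 1.0))
}

#' Ground-truth temporal response function for one condition
#'
#' Smooth, band-limited weight curves: the monotonic-hazard TRF is a
#' negative Gaussian bump peaking at `peak_lag` (default 0 s, imitating a
#' near-instantaneous fronto-central negativity), the modulated-hazard TRF
#' a positive bump at a slightly anticipatory lag (default -0.05 s, so the
#' buildup toward the expected target resolves before the target and
#' survives the post-target zeroing); each is multiplied by a
#' smooth spatial loading over the sensor layout and by the condition's
#' regressor gain.
#'
#' @param spec A [simulation_spec()].
#' @param condition Condition label (must match a name of `gains`).
#' @param cfg A [ridge_config()] defining the lag grid.
#' @param gains Per-condition regressor gains, default [condition_gains()].
#' @param peak_lag Lag (s) of the monotonic-component peak, default 0.
#' @param mod_peak_lag Lag (s) of the modulated-component peak, default
#'   -0.05.
#' @return A `trf` with regressors `monotonic` and `modulated`.
#' @export
simulate_ground_truth_trf <- function(spec, condition, cfg = ridge_config(),
                                      gains = condition_gains(),
                                      peak_lag = 0, mod_peak_lag = -0.05) {
  stopifnot(inherits(spec, "simulation_spec"))
  g <- gains[[condition]]
  if (is.null(g)) stop("no gains defined for condition ", condition,
                       call. = FALSE)
  lags <- seq(round(cfg$lag_min * spec$fs),
              round(cfg$lag_max * spec$fs)) / spec$fs
  coords <- simulate_layout(spec$n_channels)
  span <- apply(coords, 2, function(v) diff(range(v))) + 1e-9
  u <- sweep(sweep(coords, 2, apply(coords, 2, min)), 2, span, "/")
  topo_mono <- exp(-rowSums(sweep(u, 2, c(0.5, 0.8))^2) / (2 * 0.35^2))
  topo_mod <- exp(-rowSums(sweep(u, 2, c(0.5, 0.4))^2) / (2 * 0.35^2))
  curve_mono <- -exp(-(lags - peak_lag)^2 / (2 * 0.04^2))
  curve_mod <- exp(-(lags - mod_peak_lag)^2 / (2 * 0.06^2))
  W <- array(0, dim = c(length(lags), spec$n_channels, 2))
  W[, , 1] <- g[["monotonic"]] * outer(curve_mono, topo_mono)
  W[, , 2] <- g[["modulated"]] * outer(curve_mod, topo_mod)
  new_trf(W, lags, c("monotonic", "modulated"), rownames(coords))
}

#' Coloured (1/f^exponent) Gaussian noise
#'
#' Spectral-synthesis noise: white Gaussian spectra are shaped so that
#' power falls off as `1/f^exponent`, then inverse-transformed; each trace
#' is standardised to zero mean and unit SD. `exponent = 0` gives white
#' noise.
#'
#' @param n_samples Samples per trace.
#' @param n_traces Number of independent traces.
#' @param exponent Spectral slope, default 1.
#' @param fs Sampling rate (Hz), default 1 (only sets the frequency axis).
#' @return Numeric matrix, `n_samples` x `n_traces`.
#' @export
colored_noise <- function(n_samples, n_traces, exponent = 1, fs = 1) {
  w <- matrix(stats::rnorm(n_samples * n_traces), n_samples, n_traces)
  if (exponent == 0) return(scale_traces(w))
  # synthesise at a highly composite length (fast FFT), then truncate
  n_fft <- stats::nextn(n_samples, c(2, 3, 5))
  if (n_fft > n_samples)
    w <- rbind(w, matrix(stats::rnorm((n_fft - n_samples) * n_traces),
                         n_fft - n_samples, n_traces))
  W <- stats::mvfft(w)
  freq <- seq_len(n_fft) - 1L
  freq <- pmin(freq, n_fft - freq)   # two-sided frequency index
  f <- freq * fs / n_fft
  amp <- ifelse(f > 0, f^(-exponent / 2), 0)
  X <- W * amp
  x <- Re(stats::mvfft(X, inverse = TRUE)) / n_fft
  scale_traces(x[seq_len(n_samples), , drop = FALSE])
}

scale_traces <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  s <- sqrt(colSums(x^2) / (nrow(x) - 1L))
  s[s == 0] <- 1
  sweep(x, 2, s, "/")
}

#' Simulate synthetic EEG epochs from ground-truth TRFs
#'
#' Each trial is the sum over regressors of the ground-truth TRF of the
#' trial's condition convolved with the hazard regressors, truncated at the
#' trial's target onset (the hazard-driven component is only defined up to
#' the awaited event), plus coloured noise. The clean signal is scaled per
#' trial so that its RMS over the pre-target window is `spec$snr` times the
#' unit-RMS noise; `snr = Inf` yields noiseless epochs, `snr = 0` pure
#' noise.
#'
#' @param schedule Trial table from [simulate_schedule()] (any subset of
#'   participants).
#' @param trfs Named list of ground-truth `trf`s, one per condition label
#'   appearing in the schedule.
#' @param regressors Named list of `hazard_regressor`s sampled at
#'   `spec$fs` over `spec$window`.
#' @param spec A [simulation_spec()].
#' @param cfg A [ridge_config()] matching the lag grid of `trfs`.
#' @param seed Optional integer seed.
#' @return An `epoch_set` (t0 = `spec$window[1]`).
#' @export
simulate_epochs <- function(schedule, trfs, regressors, spec,
                            cfg = ridge_config(), seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(spec$window[1], spec$window[2], by = 1 / spec$fs)
  n_samp <- length(tt)
  n_trials <- nrow(schedule)
  design <- build_lagged_design(regressors, n_samp, cfg)
  clean <- lapply(trfs, predict_response, design = design)  # per condition
  data <- array(0, dim = c(n_trials, spec$n_channels, n_samp))
  noise <- if (is.infinite(spec$snr)) NULL else
    colored_noise(n_samp, n_trials * spec$n_channels, spec$noise_exponent,
                  fs = spec$fs)
  for (i in seq_len(n_trials)) {
    sig <- clean[[as.character(schedule$condition[i])]]
    if (is.null(sig)) stop("no ground-truth TRF for condition ",
                           schedule$condition[i], call. = FALSE)
    k <- sum(tt <= schedule$foreperiod[i] + 1e-9)
    sig_t <- sig
    if (k < n_samp) sig_t[(k + 1L):n_samp, ] <- 0
    rms <- sqrt(mean(sig_t[seq_len(max(k, 1L)), ]^2))
    gain <- if (rms > 0) 1 / rms else 0
    if (is.infinite(spec$snr)) {
      data[i, , ] <- t(sig_t * gain)
    } else {
      ncols <- (i - 1L) * spec$n_channels + seq_len(spec$n_channels)
      data[i, , ] <- t(sig_t * (gain * spec$snr) + noise[, ncols])
    }
  }
  trials <- data.frame(participant = schedule$participant,
                       block = schedule$block,
                       condition = as.character(schedule$condition),
                       foreperiod = schedule$foreperiod)
  epoch_set(data, spec$fs, spec$window[1], trials,
            channels = rownames(simulate_layout(spec$n_channels)))
}

#' Simulate condition-free resting noise epochs
#'
#' Coloured-noise-only epochs with the same shape as task epochs, carrying
#' pseudo foreperiods and condition labels copied from a task schedule so
#' the identical analysis pipeline runs end to end. Serves as the null
#' control: no dependence on condition exists in these data.
#'
#' @inheritParams simulate_epochs
#' @return An `epoch_set` of pure noise.
#' @export
simulate_resting_snippets <- function(schedule, spec, seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(spec$window[1], spec$window[2], by = 1 / spec$fs)
  n_samp <- length(tt)
  n_trials <- nrow(schedule)
  noise <- colored_noise(n_samp, n_trials * spec$n_channels,
                         spec$noise_exponent, fs = spec$fs)
  data <- aperm(array(noise, dim = c(n_samp, spec$n_channels, n_trials)),
                c(3, 2, 1))
  trials <- data.frame(participant = schedule$participant,
                       block = schedule$block,
                       condition = as.character(schedule$condition),
                       foreperiod = schedule$foreperiod)
  epoch_set(data, spec$fs, spec$window[1], trials,
            channels = rownames(simulate_layout(spec$n_channels)))
}
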