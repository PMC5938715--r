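#' Construct an epoch set
#'
#' Container for single-trial multichannel EEG: a trials x channels x
#' samples array plus per-trial metadata (participant, condition,
#' foreperiod). All trials share the sampling rate, start time and channel
#' set.
#'
#' @param data Numeric array, trials x channels x samples.
#' @param fs Sampling rate (Hz).
#' @param t0 Time (s) of the first sample relative to cue onset.
#' @param trials Data frame with one row per trial; must contain columns
#'   `foreperiod` (s, positive) and `condition`; a `participant` column is
#'   added (value `1`) if missing.
#' @param channels Character vector of channel labels; defaults to
#'   `ch01 ...`.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, t0, trials, channels = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3, fs > 0)
  stopifnot(is.data.frame(trials), nrow(trials) == dim(data)[1])
  if (!all(c("foreperiod", "condition") %in% names(trials)))
    stop("trials must have columns 'foreperiod' and 'condition'", call. = FALSE)
  if (any(trials$foreperiod <= 0))
    stop("foreperiods must be positive", call. = FALSE)
  if (is.null(channels))
    channels <- sprintf("ch%02d", seq_len(dim(data)[2]))
  stopifnot(length(channels) == dim(data)[2])
  if (is.null(trials$participant)) trials$participant <- 1L
  structure(list(data = data, fs = fs, t0 = t0,
                 trials = as.data.frame(trials), channels = channels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples @ ", x$fs, " Hz, t0 = ", x$t0, " s\n", sep = "")
  cat("  conditions: ",
      paste(names(table(x$trials$condition)), table(x$trials$condition),
            sep = ":", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Sample times of an epoch set
#' @param x An `epoch_set`.
#' @return Numeric vector of sample times (s relative to cue onset).
#' @export
epoch_times <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  x$t0 + (seq_len(dim(x$data)[3]) - 1L) / x$fs
}

#' Select trials by minimum foreperiod and crop the epoch window
#'
#' Trials with foreperiods at or below `min_fp` are discarded (too little
#' pre-target signal to model), and the time axis is cut to start at
#' `crop_start` after cue onset, removing cue-evoked activity.
#'
#' @param epochs An `epoch_set`.
#' @param min_fp Minimum foreperiod (s); trials with `foreperiod <= min_fp`
#'   are dropped. Default 0.65.
#' @param crop_start New start of the time axis (s after cue), default 0.5.
#' @return A cropped `epoch_set` with metadata preserved.
#' @export
select_and_crop <- function(epochs, min_fp = 0.65, crop_start = 0.5) {
  stopifnot(inherits(epochs, "epoch_set"))
  tt <- epoch_times(epochs)
  if (crop_start < tt[1] - 1e-9 || crop_start > tt[length(tt)])
    stop("crop_start lies outside the epoch window", call. = FALSE)
  keep <- epochs$trials$foreperiod > min_fp
  if (!any(keep))
    stop("empty-selection: no trials with foreperiod above ", min_fp,
         call. = FALSE)
  s0 <- which(tt >= crop_start - 1e-9)[1]
  epochs$data <- epochs$data[keep, , s0:length(tt), drop = FALSE]
  epochs$trials <- epochs$trials[keep, , drop = FALSE]
  rownames(epochs$trials) <- NULL
  epochs$t0 <- tt[s0]
  epochs
}

#' Low-pass filter every trial and channel
#'
#' Zero-phase (two-pass) Butterworth low-pass, applied independently per
#' trial and channel; dimensions unchanged.
#'
#' @param epochs An `epoch_set`.
#' @param cutoff Cutoff frequency (Hz), default 25; must be below Nyquist.
#' @param order Filter order, default 6.
#' @return Filtered `epoch_set`.
#' @export
lowpass <- function(epochs, cutoff = 25, order = 6) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  # flatten to samples x (trials*channels) for one vectorised filter call
  x <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[3])
  y <- butter_lowpass(x, cutoff, epochs$fs, order)
  epochs$data <- aperm(array(y, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  epochs
}

#' Z-score each trial and channel over time
#'
#' Per trial and channel, subtracts the temporal mean and divides by the
#' temporal standard deviation, putting all trials on a common scale.
#' Zero-variance traces are left as all zeros and flagged.
#'
#' @param epochs An `epoch_set`.
#' @return An `epoch_set`; attribute `"zero_variance"` holds a trials x
#'   channels logical matrix of flagged (constant) traces.
#' @export
zscore_trials <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  x <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[3])
  mu <- colMeans(x)
  x <- sweep(x, 2, mu)
  sdv <- sqrt(colSums(x^2) / (d[3] - 1L))
  flat <- sdv == 0
  sdv[flat] <- 1
  x <- sweep(x, 2, sdv, "/")
  epochs$data <- aperm(array(x, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  attr(epochs, "zero_variance") <- matrix(flat, d[1], d[2])
  if (any(flat))
    warning(sum(flat), " zero-variance trial/channel trace(s) left as zeros",
            call. = FALSE)
  epochs
}

#' Zero the signal after each trial's target onset
#'
#' Temporal hazard is only defined up to the awaited event, so samples
#' strictly after target onset (cue time + foreperiod) are set to 0; the
#' sample at target onset itself is retained. A trial whose target precedes
#' the epoch window is zeroed entirely, with a warning.
#'
#' @param epochs An `epoch_set`.
#' @return An `epoch_set` with post-target samples zeroed.
#' @export
zero_after_target <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  tt <- epoch_times(epochs)
  n <- length(tt)
  for (i in seq_len(dim(epochs$data)[1])) {
    fp <- epochs$trials$foreperiod[i]
    if (fp < tt[1] - 1e-9) {
      epochs$data[i, , ] <- 0
      warning("trial ", i, ": target onset precedes the epoch window; ",
              "whole trial zeroed", call. = FALSE)
      next
    }
    after <- which(tt > fp + 1e-9)
    if (length(after)) epochs$data[i, , after[1]:n] <- 0
  }
  epochs
}

#' Full preprocessing pipeline for encoding models
#'
#' Runs, in order: trial selection and cropping, low-pass filtering,
#' per-trial z-scoring, and post-target zeroing (zeroing last, so the
#' pre-target signal keeps a common scale across trials of different
#' foreperiods).
#'
#' @inheritParams select_and_crop
#' @inheritParams lowpass
#' @param zscore_first Z-score before zeroing (default `TRUE`); set `FALSE`
#'   to zero first and z-score after.
#' @return Preprocessed `epoch_set`.
#' @export
preprocess_epochs <- function(epochs, min_fp = 0.65, crop_start = 0.5,
                              cutoff = 25, order = 6, zscore_first = TRUE) {
  e <- select_and_crop(epochs, min_fp = min_fp, crop_start = crop_start)
  e <- lowpass(e, cutoff = cutoff, order = order)
  if (zscore_first) {
    e <- zscore_trials(e)
    e <- zero_after_target(e)
  } else {
    e <- zero_after_target(e)
    e <- zscore_trials(e)
  }
  e
}

#' Write / read an epoch set container
#'
#' The pipeline's on-disk container: the epoch array and metadata are
#' serialised together (RDS), with the trial table additionally written as
#' a CSV sidecar for inspection.
#'
#' @param epochs An `epoch_set`.
#' @param path Output path (`.rds`); sidecar CSV is `path` with extension
#'   `.csv`.
#' @return `path`, invisibly (`write_epochs`); an `epoch_set`
#'   (`read_epochs`).
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  saveRDS(epochs, path)
  utils::write.csv(epochs$trials, sub("\\.rds$", ".csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  e <- readRDS(path)
  stopifnot(inherits(e, "epoch_set"))
  e
}
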