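#' Hazard function of a discrete foreperiod distribution
#'
#' The hazard at time t is the conditional probability of the event at t
#' given it has not occurred earlier, H(t) = f(t) / (1 - C(t)). Here C(t)
#' is cumulative *inclusive* of the mass at t, so the last foreperiod always
#' yields an infinite raw hazard. Non-finite entries are replaced by the
#' maximum of the remaining finite entries, and all entries are then divided
#' by that maximum, giving values in \[0, 1\] with at least one entry equal
#' to 1.
#'
#' @param dist An `fp_distribution` (see [build_foreperiod_distribution()]).
#' @param normalize Divide by the maximum finite raw hazard (default `TRUE`).
#' @return Numeric vector of hazard values, one per `dist$times`.
#' @examples
#' d <- build_foreperiod_distribution(study_conditions()$nonpredictive)
#' h <- compute_hazard(d)
#' max(h)  # 1 by construction
#' @export
compute_hazard <- function(dist, normalize = TRUE) {
  stopifnot(inherits(dist, "fp_distribution"))
  raw <- dist$probs / (1 - dist$cum)
  finite <- is.finite(raw)
  if (!any(finite))
    stop("degenerate-distribution: no finite hazard values ",
         "(single-point distribution?)", call. = FALSE)
  m <- max(raw[finite])
  raw[!finite] <- m
  if (normalize) raw <- raw / m
  raw
}

#' Resample an anchored regressor to the EEG sampling rate
#'
#' Linear interpolation of (time, value) anchors onto a uniform grid at
#' `fs` Hz over `[t_start, t_end]`. Outside the anchor range the first/last
#' anchor value is held constant: the hazard is undefined before the first
#' possible foreperiod, and a constant extension avoids spurious slopes.
#'
#' @param times,values Anchor times (s, strictly ascending) and values.
#' @param fs Sampling rate in Hz.
#' @param t_start,t_end Window (s) covered by the output, `t_start < t_end`.
#' @param kind Regressor kind: `"monotonic"`, `"modulated"` or `"envelope"`.
#' @return A `hazard_regressor`: list with `kind`, `fs`, `t0` (= `t_start`),
#'   and `values` sampled at `t_start + (0:(n-1))/fs`.
#' @export
resample_regressor <- function(times, values, fs, t_start, t_end,
                               kind = c("monotonic", "modulated", "envelope")) {
  kind <- match.arg(kind)
  if (length(times) < 2L || length(times) != length(values))
    stop("need at least two (time, value) anchor pairs", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("anchor times must be strictly ascending", call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (t_end <= t_start)
    stop("invalid-window: t_end must exceed t_start", call. = FALSE)
  grid <- seq(t_start, t_end, by = 1 / fs)
  vals <- stats::approx(times, values, xout = grid, rule = 2)$y
  new_hazard_regressor(kind, fs, t_start, vals)
}

new_hazard_regressor <- function(kind, fs, t0, values) {
  stopifnot(all(is.finite(values)))
  structure(list(kind = kind, fs = fs, t0 = t0, values = values),
            class = "hazard_regressor")
}

#' @export
print.hazard_regressor <- function(x, ...) {
  cat("<hazard_regressor> kind=", x$kind, ", fs=", x$fs, " Hz, ",
      length(x$values), " samples from t0=", x$t0, " s, range [",
      signif(min(x$values), 4), ", ", signif(max(x$values), 4), "]\n",
      sep = "")
  invisible(x)
}

#' Time axis of a hazard regressor
#' @param x A `hazard_regressor`.
#' @return Numeric vector of sample times (s).
#' @export
regressor_times <- function(x) {
  stopifnot(inherits(x, "hazard_regressor"))
  x$t0 + (seq_along(x$values) - 1L) / x$fs
}

#' Modulated hazard regressor: predictive minus monotonic
#'
#' Subtracts the monotonic (uniform-distribution) hazard from a predictive
#' hazard on the same time grid, removing the shared rise toward the end of
#' the trial and keeping the mid-trial peak as the distinctive feature. The
#' difference is then normalised by its maximum (skipped for an all-zero
#' difference, to avoid 0/0).
#'
#' @param monotonic,predictive `hazard_regressor`s with identical `fs`,
#'   `t0` and length.
#' @return A `hazard_regressor` with `kind = "modulated"`.
#' @export
make_modulated_regressor <- function(monotonic, predictive) {
  stopifnot(inherits(monotonic, "hazard_regressor"),
            inherits(predictive, "hazard_regressor"))
  if (monotonic$fs != predictive$fs || monotonic$t0 != predictive$t0 ||
      length(monotonic$values) != length(predictive$values))
    stop("alignment error: regressors are not on the same time grid",
         call. = FALSE)
  d <- predictive$values - monotonic$values
  m <- max(d)
  if (m > 0) d <- d / m
  new_hazard_regressor("modulated", monotonic$fs, monotonic$t0, d)
}

#' Build the monotonic and modulated hazard regressors of the study design
#'
#' Convenience wrapper: computes the normalised hazard of the nonpredictive
#' (monotonic) and strongly predictive distributions, resamples both to the
#' EEG rate over the analysis window, forms the modulated regressor as
#' their difference, renormalises each by its maximum over the window, and
#' low-pass filters both (25-Hz cutoff, 6th-order two-pass Butterworth) to
#' match the filtering applied to the EEG.
#'
#' @param conditions List of condition specs as from [study_conditions()].
#' @param fs EEG sampling rate (Hz), default 200.
#' @param window Analysis window (s after cue), default `c(0.5, 3.1)`.
#' @param lowpass_hz Low-pass cutoff (Hz); `NULL` to skip filtering.
#' @return List with elements `monotonic` and `modulated`
#'   (`hazard_regressor`s on the same grid).
#' @export
study_hazard_regressors <- function(conditions = study_conditions(),
                                    fs = 200, window = c(0.5, 3.1),
                                    lowpass_hz = 25) {
  d_np <- build_foreperiod_distribution(conditions$nonpredictive)
  d_sp <- build_foreperiod_distribution(conditions$strongly_predictive)
  h_np <- compute_hazard(d_np)
  h_sp <- compute_hazard(d_sp)
  mono <- resample_regressor(d_np$times, h_np, fs, window[1], window[2],
                             kind = "monotonic")
  sp <- resample_regressor(d_sp$times, h_sp, fs, window[1], window[2],
                           kind = "monotonic")
  mod <- make_modulated_regressor(mono, sp)
  # renormalise over the cropped window, then filter like the EEG
  rescale <- function(r) {
    m <- max(r$values)
    if (m > 0) r$values <- r$values / m
    r
  }
  mono <- rescale(mono)
  mod <- rescale(mod)
  if (!is.null(lowpass_hz)) {
    mono$values <- as.numeric(butter_lowpass(matrix(mono$values), lowpass_hz, fs))
    mod$values <- as.numeric(butter_lowpass(matrix(mod$values), lowpass_hz, fs))
  }
  list(monotonic = mono, modulated = mod)
}

#' Export a regressor as a two-column CSV
#'
#' @param x A `hazard_regressor`.
#' @param path Output file; columns `time_s`, `value`.
#' @return `path`, invisibly.
#' @export
write_regressor_csv <- function(x, path) {
  stopifnot(inherits(x, "hazard_regressor"))
  utils::write.csv(data.frame(time_s = regressor_times(x), value = x$values),
                   path, row.names = FALSE)
  invisible(path)
}
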