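#' Pure-tone waveform with raised-cosine onset/offset ramps
#'
#' @param freq Tone frequency (Hz), default 750.
#' @param duration Tone duration (s), default 0.05.
#' @param ramp On- and offset ramp duration (s), default 0.01.
#' @param fs_audio Audio sampling rate (Hz), default 8000.
#' @return Numeric waveform vector.
#' @export
make_tone <- function(freq = 750, duration = 0.05, ramp = 0.01,
                      fs_audio = 8000) {
  n <- round(duration * fs_audio)
  t <- (seq_len(n) - 1) / fs_audio
  w <- sin(2 * pi * freq * t)
  nr <- round(ramp * fs_audio)
  if (nr > 0) {
    r <- 0.5 * (1 - cos(pi * (seq_len(nr) - 1) / nr))
    w[seq_len(nr)] <- w[seq_len(nr)] * r
    w[n + 1 - seq_len(nr)] <- w[n + 1 - seq_len(nr)] * r
  }
  w
}

#' Target-onset envelope regressor
#'
#' Builds the acoustic-onset regressor used to validate the encoding model
#' on sensory events: the tone waveform is inserted into a vector of zeros
#' at its onset time, the envelope is taken as the magnitude of the analytic
#' signal, downsampled to the EEG rate, low-pass filtered (25-Hz cutoff,
#' 6th-order two-pass Butterworth), and reduced to its halfwave-rectified
#' first derivative so that only the onset ramp survives.
#'
#' @param tone Audio waveform (e.g. [make_tone()]).
#' @param fs_audio Audio sampling rate (Hz).
#' @param onset Tone onset (s, on the trial clock).
#' @param trial_window Length-2 numeric, trial window (s) covered by the
#'   regressor.
#' @param fs_eeg EEG sampling rate (Hz).
#' @param lowpass_hz Low-pass cutoff (Hz), default 25.
#' @return A `hazard_regressor` with `kind = "envelope"` on the EEG grid.
#' @export
build_envelope_regressor <- function(tone, fs_audio, onset, trial_window,
                                     fs_eeg, lowpass_hz = 25) {
  stopifnot(length(trial_window) == 2, trial_window[2] > trial_window[1])
  if (onset < trial_window[1] || onset > trial_window[2])
    stop("invalid-onset: tone onset lies outside the trial window",
         call. = FALSE)
  n_audio <- round((trial_window[2] - trial_window[1]) * fs_audio) + 1L
  x <- numeric(n_audio)
  i0 <- round((onset - trial_window[1]) * fs_audio) + 1L
  idx <- i0:min(n_audio, i0 + length(tone) - 1L)
  x[idx] <- tone[seq_along(idx)]
  env <- Mod(analytic_signal(x))
  # downsample by linear interpolation onto the EEG grid
  t_audio <- trial_window[1] + (seq_len(n_audio) - 1) / fs_audio
  t_eeg <- seq(trial_window[1], trial_window[2], by = 1 / fs_eeg)
  env_ds <- stats::approx(t_audio, env, xout = t_eeg, rule = 2)$y
  env_f <- as.numeric(butter_lowpass(matrix(env_ds), lowpass_hz, fs_eeg))
  d <- c(0, diff(env_f))
  d[d < 0] <- 0
  new_hazard_regressor("envelope", fs_eeg, trial_window[1], d)
}
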