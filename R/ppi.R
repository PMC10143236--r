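#' Preprocess a PPG window for peak detection
#'
#' Raw PPG is 4x upsampled (polyphase resampling, preserving peak-time
#' linearity), differenced once to suppress baseline drift and sharpen
#' systolic upstrokes, then bandpass filtered between `0.75 * f_music` and
#' `6.5 * f_music` (zero-phase Butterworth). The upper edge is clipped just
#' below Nyquist with a warning when `6.5 * f_music` exceeds it.
#'
#' @param ppg_window Raw PPG samples.
#' @param fs Sampling rate in Hz (nominal 64).
#' @param f_music Fundamental heartbeat frequency in Hz.
#' @param upsample_factor Integer upsampling factor (default 4).
#' @param band_mult Bandpass edges as multiples of `f_music`.
#' @param pre_upsampled Set when `ppg_window` has already been upsampled (at
#'   rate `fs * upsample_factor`); skips the resampling step.
#' @return A list with `signal` (filtered samples) and `fs` (upsampled rate).
#' @export
preprocess_ppg <- function(ppg_window, fs, f_music, upsample_factor = 4L,
                           band_mult = c(0.75, 6.5), pre_upsampled = FALSE) {
  up <- if (pre_upsampled) {
    as.numeric(ppg_window)
  } else {
    upsample_poly(ppg_window, upsample_factor)
  }
  fs_up <- fs * upsample_factor
  d <- diff(up)
  hi <- band_mult[2] * f_music
  if (hi >= fs_up / 2) {
    warn("preprocess_ppg: upper band edge clipped below Nyquist")
  }
  # band edges rounded to 0.5 bpm so the per-session filter cache is shared
  # across epochs with near-identical pulse rates
  lo <- round(band_mult[1] * f_music * 120) / 120
  hi <- round(min(hi, fs_up / 2 * 0.99) * 120) / 120
  list(signal = bandpass_cached(d, fs_up, lo, hi, order = 3), fs = fs_up)
}

#' Detect pulse peaks in a preprocessed PPG window
#'
#' Local maxima subject to a minimum inter-peak distance of
#' `0.5 / f_music` seconds, followed by double-peak removal: any peak whose
#' immediately preceding valley (the signal minimum between it and the
#' previous retained peak, or the window start) is above zero is discarded.
#' On the zero-mean filtered signal a genuine beat is preceded by a negative
#' trough, while the secondary bump of a double-peaked waveform rides above
#' zero.
#'
#' @param filtered Preprocessed signal from [preprocess_ppg()].
#' @param fs Sampling rate of `filtered` in Hz.
#' @param f_music Fundamental heartbeat frequency in Hz.
#' @param min_height Minimum peak amplitude (default 0: on the zero-mean
#'   filtered signal only positive excursions count as candidate beats).
#' @return Peak times in seconds from window start.
#' @export
detect_peaks <- function(filtered, fs, f_music, min_height = 0) {
  min_dist <- max(1L, round(0.5 / f_music * fs))
  idx <- find_local_peaks(filtered, min_dist, min_height)
  if (length(idx) == 0) abort("detect_peaks: no peaks found")
  keep <- logical(length(idx))
  prev <- 1L
  for (k in seq_along(idx)) {
    valley <- min(filtered[prev:idx[k]])
    if (valley <= 0) {
      keep[k] <- TRUE
      prev <- idx[k]
    }
  }
  if (!any(keep)) abort("detect_peaks: all peaks rejected by the valley rule")
  idx <- idx[keep]
  # sub-sample refinement: least-squares parabola over +/-60 ms around each
  # peak (averaging the band-limited noise that would dominate a 3-point
  # fit), shift clamped to one sample
  halfw <- max(2L, round(0.06 * fs))
  u <- -halfw:halfw
  proj <- solve(crossprod(cbind(1, u, u^2)), t(cbind(1, u, u^2)))
  n <- length(filtered)
  refine <- vapply(idx, function(i) {
    if (i - halfw < 1L || i + halfw > n) return(0)
    cf <- proj %*% filtered[(i - halfw):(i + halfw)]
    if (cf[3] >= 0) return(0)
    max(-1, min(1, -cf[2] / (2 * cf[3])))
  }, numeric(1))
  (idx + refine - 1) / fs
}

#' Validate a peak-to-peak interval series against the epoch pulse rate
#'
#' Two consistency checks against the independently estimated pulse rate:
#' the measured peak count versus the count implied by window length and
#' pulse rate, and the mean peak-to-peak interval versus the pulse-rate
#' reciprocal. If either ratio leaves `[1 - ratio, 1 + ratio]` (default
#' 0.7-1.3) the window is marked invalid and carries no HRV; invalid epochs
#' are never interpolated.
#'
#' @param peak_times Peak times in seconds from [detect_peaks()].
#' @param window_length Window length in seconds.
#' @param pulse_rate Epoch pulse rate in bpm.
#' @param ratio Validation half-width (default 0.3).
#' @return A list of class `wristhrv_ppi` with `peak_times`, `intervals`
#'   (ms), `valid` (logical) and `reason`
#'   (`"none"`, `"peak_count"` or `"mean_ppi"`).
#' @export
validate_ppi <- function(peak_times, window_length, pulse_rate, ratio = 0.3) {
  intervals <- diff(peak_times) * 1000
  expected_n <- window_length * pulse_rate / 60
  expected_ppi <- 60000 / pulse_rate
  r_count <- length(peak_times) / expected_n
  r_ppi <- if (length(intervals) > 0) mean(intervals) / expected_ppi else 0
  reason <- "none"
  if (r_count < 1 - ratio || r_count > 1 + ratio) {
    reason <- "peak_count"
  } else if (r_ppi < 1 - ratio || r_ppi > 1 + ratio) {
    reason <- "mean_ppi"
  }
  structure(
    list(peak_times = peak_times, intervals = intervals,
         valid = reason == "none", reason = reason),
    class = "wristhrv_ppi"
  )
}
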