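#' Frequency-domain signal quality index for pulse-rate estimation
#'
#' Measures how concentrated a PPG power spectrum is around its dominant
#' pulse peak. The initial pulse estimate is the maximal-density bin in the
#' 40-160 bpm band; all bins above -5 dB relative to that peak (density >
#' peak/3.16) within the search range are collected, and the index is
#' `1 - 3 * sd(bins) / range_width` (population sd, bins in bpm). A spectrum
#' with a single above-threshold bin scores exactly 1.0; broadband
#' motion-artifact energy spreads the above-threshold bins and drives the
#' index down.
#'
#' @param psd PSD tibble from [welch_psd()] (columns `frequency` in Hz,
#'   `density`).
#' @param range_bpm Length-2 target pulse range in bpm, e.g. `c(40, 160)`.
#'   The effective upper edge extends to twice the initial estimate when that
#'   exceeds `range_bpm[2]`.
#' @param init_range_bpm Band searched for the initial peak (default
#'   `c(40, 160)`).
#'
#' @return The quality index, a number `<= 1`.
#' @export
compute_sqi_pr <- function(psd, range_bpm, init_range_bpm = c(40, 160)) {
  if (range_bpm[1] <= 0 || range_bpm[1] >= range_bpm[2]) {
    abort("compute_sqi_pr: invalid search range")
  }
  bpm <- psd$frequency * 60
  dn <- psd$density
  in_init <- bpm >= init_range_bpm[1] & bpm <= init_range_bpm[2]
  if (!any(in_init)) abort("compute_sqi_pr: PSD does not cover the pulse band")
  f_init <- bpm[in_init][which.max(dn[in_init])]
  threshold <- dn[bpm == f_init][1] / 3.16
  upper <- max(range_bpm[2], 2 * f_init)
  idx <- which(dn > threshold & bpm >= range_bpm[1] & bpm <= upper)
  if (length(idx) > 1) {
    1.0 - 3.0 * pop_sd(bpm[idx]) / (upper - range_bpm[1])
  } else {
    1.0
  }
}

#' Harmonic-ratio signal quality index for HRV extraction
#'
#' Quantifies how much of a PPG window's spectral energy sits at the
#' heartbeat fundamental and its second and third harmonics versus the gaps
#' between them. Harmonic bands are `k * f_music +/- f_margin` for k = 1, 2,
#' 3; inharmonic bands are the three gaps `[0.5 f + m, f - m]`,
#' `[f + m, 2f - m]`, `[2f + m, 3f - m]`. The index is
#' `log(1 + A_harmonic / A_nonharmonic)`; a clean quasi-periodic pulse scores
#' well above 1, motion-corrupted windows fall below it. When the inharmonic
#' sum is exactly zero the index is defined as 0 (set
#' `clean_spectrum_passes` to treat a perfectly line-like spectrum as best
#' rather than worst quality).
#'
#' @param psd PSD tibble from [welch_psd()].
#' @param f_music Fundamental heartbeat frequency in Hz (from
#'   [music_pulse_rate()], divided by 60).
#' @param f_margin Harmonic half-bandwidth in Hz (default 0.1, i.e. 6 bpm).
#' @param clean_spectrum_passes If TRUE, a zero inharmonic sum returns a
#'   large constant (1e6) instead of 0.
#'
#' @return The quality index (unitless, `>= 0`).
#' @export
compute_sqi_hrv <- function(psd, f_music, f_margin = 0.1,
                            clean_spectrum_passes = FALSE) {
  if (f_music < 40 / 60 || f_music > 240 / 60) {
    abort("compute_sqi_hrv: fundamental outside 40-240 bpm")
  }
  if (f_margin >= 0.25 * f_music) {
    abort("compute_sqi_hrv: margin too wide, harmonic bands would overlap")
  }
  bin <- psd$frequency
  dn <- psd$density
  band_sum <- function(lo, hi) sum(dn[bin >= lo & bin <= hi])
  a_harm <- band_sum(f_music - f_margin, f_music + f_margin) +
    band_sum(2 * f_music - f_margin, 2 * f_music + f_margin) +
    band_sum(3 * f_music - f_margin, 3 * f_music + f_margin)
  a_inharm <- band_sum(0.5 * f_music + f_margin, f_music - f_margin) +
    band_sum(f_music + f_margin, 2 * f_music - f_margin) +
    band_sum(2 * f_music + f_margin, 3 * f_music - f_margin)
  if (a_inharm > 0) {
    log(1.0 + a_harm / a_inharm)
  } else if (clean_spectrum_passes) {
    1e6
  } else {
    0.0
  }
}
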