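#' Windowed frequency-domain HRV consistency between window lengths
#'
#' Computes LF and HF series over sliding windows of two lengths (default
#' 3 min vs 5 min) stepped at 1-minute intervals across an RR series, and
#' the Pearson correlation between the two series of each index on the
#' shared window-centre grid. Used to verify that ultra-short-term (3-min)
#' frequency-domain HRV tracks the conventional 5-min indices on stationary
#' data.
#'
#' @param rr An RR series from [generate_rr()] (or any tibble with `time`
#'   and `rr_ms` columns; beat times are taken as `time`).
#' @param short_s,long_s Window lengths in seconds (defaults 180 and 300).
#' @param step_s Window step (default 60).
#' @param segment_s Welch segment length passed to
#'   [frequency_domain_hrv()]; default 90 s so both window lengths hold at
#'   least two segments.
#' @return A list with `windows` (tibble: `center_s`, `lf_short`,
#'   `hf_short`, `lf_long`, `hf_long`) and `correlation` (named vector with
#'   `lf` and `hf` Pearson correlations).
#' @export
usthrv_window_consistency <- function(rr, short_s = 180, long_s = 300,
                                      step_s = 60, segment_s = 90) {
  t_beat <- rr$time
  ppi <- rr$rr_ms
  t_end <- max(t_beat)
  centers <- seq(long_s / 2, t_end - long_s / 2, by = step_s)
  one <- function(center, width) {
    sel <- t_beat >= center - width / 2 & t_beat < center + width / 2
    frequency_domain_hrv(c(t_beat[sel][1] - ppi[sel][1] / 1000, t_beat[sel]),
                         ppi[sel], segment_s = segment_s)
  }
  rows <- purrr::map_dfr(centers, function(ct) {
    s <- one(ct, short_s)
    l <- one(ct, long_s)
    tibble(center_s = ct, lf_short = s$lf, hf_short = s$hf,
           lf_long = l$lf, hf_long = l$hf)
  })
  ok <- complete.cases(rows)
  list(
    windows = rows,
    correlation = c(
      lf = stats::cor(rows$lf_short[ok], rows$lf_long[ok]),
      hf = stats::cor(rows$hf_short[ok], rows$hf_long[ok])
    )
  )
}

#' Time-domain HRV indices
#'
#' RMSSD (root mean square of successive differences) and SDNN (population
#' standard deviation) of a peak-to-peak interval series.
#'
#' @param ppi Intervals in ms.
#' @return A list with `rmssd` and `sdnn` (ms); both `NA` when fewer than 3
#'   intervals are available.
#' @examples
#' time_domain_hrv(c(800, 810, 790, 805))
#' @export
time_domain_hrv <- function(ppi) {
  if (length(ppi) < 3) return(list(rmssd = NA_real_, sdnn = NA_real_))
  list(
    rmssd = sqrt(mean(diff(ppi)^2)),
    sdnn = pop_sd(ppi)
  )
}

#' Frequency-domain HRV indices
#'
#' The unevenly sampled interval series is placed at its peak times, resampled
#' to a uniform grid (cubic spline, default 4 Hz), mean-detrended, and
#' analysed with Welch's method (default 90 s Blackman-Harris segments, 50%
#' overlap). Band powers are integrated over LF (0.04-0.15 Hz), HF
#' (0.15-0.40 Hz) and total power (0.0033-0.40 Hz), in ms^2.
#'
#' @param peak_times Peak times in seconds.
#' @param ppi Intervals in ms (`diff(peak_times) * 1000`).
#' @param resample_hz Uniform resampling rate (default 4).
#' @param segment_s Welch segment length in seconds (default 90).
#' @param bands List with `lf`, `hf`, `tp` band edges in Hz.
#' @return A list with `lf`, `hf`, `lf_hf`, `tp`. `lf_hf` is `NA` when the
#'   HF power is zero.
#' @export
frequency_domain_hrv <- function(peak_times, ppi,
                                 resample_hz = 4, segment_s = 90,
                                 bands = list(lf = c(0.04, 0.15),
                                              hf = c(0.15, 0.40),
                                              tp = c(0.0033, 0.40))) {
  if (length(ppi) < 3) {
    return(list(lf = NA_real_, hf = NA_real_, lf_hf = NA_real_, tp = NA_real_))
  }
  t_ppi <- peak_times[-1]
  span <- t_ppi[length(t_ppi)] - t_ppi[1]
  if (span < segment_s) {
    return(list(lf = NA_real_, hf = NA_real_, lf_hf = NA_real_, tp = NA_real_))
  }
  grid <- seq(t_ppi[1], t_ppi[length(t_ppi)], by = 1 / resample_hz)
  x <- spline(t_ppi, ppi, xout = grid, method = "natural")$y
  psd <- welch_psd(x, resample_hz, segment_s = segment_s, overlap = 0.5,
                   pad = 1, max_freq = NULL)
  df <- psd$frequency[2] - psd$frequency[1]
  band_power <- function(b) {
    sum(psd$density[psd$frequency >= b[1] & psd$frequency < b[2]]) * df
  }
  lf <- band_power(bands$lf)
  hf <- band_power(bands$hf)
  list(
    lf = lf, hf = hf,
    lf_hf = if (hf > 0) lf / hf else NA_real_,
    tp = band_power(bands$tp)
  )
}
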