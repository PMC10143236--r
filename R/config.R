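#' Pipeline configuration
#'
#' Bundles every tunable constant of the analysis pipeline with its default.
#' Values are grouped the way the pipeline consumes them: actigraphy scoring
#' and rescoring, the pulse-rate stage (Welch PSD, SQI gate, MUSIC), the
#' PPI/HRV extraction stage, and phase definitions.
#'
#' @param ... Named overrides of any default listed below. Nested lists are
#'   replaced wholesale (pass the full sub-list when overriding one of its
#'   entries).
#'
#' @details Defaults:
#' \describe{
#'   \item{scripps_weights}{Uniform 0.0064 over a symmetric window of
#'     `scripps_halfwidth = 10` epochs around the scored epoch (21 weights).}
#'   \item{scripps_threshold}{1.0; an epoch is scored sleep when the weighted
#'     activity sum falls below it.}
#'   \item{rescore}{`min_run_min = 120`, `max_gap_min = 100`,
#'     `ignore_awakening_min = 4`, `min_fragment_min = 60`,
#'     `activity_percentile = 75`.}
#'   \item{phase}{`len_min = 90` (P1, P2, P3, P5 length),
#'     `min_tst_min = 270` (participant exclusion bound).}
#'   \item{rest_activity_max}{300 device counts; awake epochs above it are
#'     non-resting and excluded from HRV.}
#'   \item{sqi_pr_threshold}{0.5; epochs below it skip MUSIC estimation.}
#'   \item{sqi_hrv_threshold}{1.0; epochs below it skip HRV extraction.}
#'   \item{welch}{`segment_s = 30`, `overlap = 0.5`, `pad = 2` (zero-padding
#'     factor giving 0.5 bpm PSD bins), `max_freq = 5.5` Hz.}
#'   \item{music}{`fs = 8` Hz working rate, `corr_dim = 64`, `order = 2`
#'     (one sinusoid pair: the fundamental; keeping harmonics out of the
#'     signal subspace suppresses octave errors), `grid_bpm = 0.25`
#'     pseudospectrum spacing.}
#'   \item{ppg_band}{0.5–5 Hz pulse-rate preprocessing band.}
#'   \item{hrv}{`f_margin_hz = 0.1` harmonic half-band, `upsample_factor = 4`,
#'     `bandpass = c(0.75, 6.5)` multiples of the fundamental,
#'     `validation_ratio = 0.3`, `resample_hz = 4`, `welch_segment_s = 90`,
#'     `clean_spectrum_passes = FALSE`.}
#'   \item{interp_window_min}{7; median interpolation window for missing
#'     pulse rates.}
#' }
#'
#' @return A named list of class `wristhrv_config`.
#' @examples
#' cfg <- wristhrv_config(sqi_pr_threshold = 0.4)
#' cfg$sqi_pr_threshold
#' @export
wristhrv_config <- function(...) {
  cfg <- list(
    scripps_weights = rep(0.0064, 21),
    scripps_halfwidth = 10L,
    scripps_threshold = 1.0,
    rescore = list(
      min_run_min = 120L,
      max_gap_min = 100L,
      ignore_awakening_min = 4L,
      min_fragment_min = 60L,
      activity_percentile = 75
    ),
    phase = list(len_min = 90L, min_tst_min = 270L),
    rest_activity_max = 300,
    sqi_pr_threshold = 0.5,
    sqi_hrv_threshold = 1.0,
    welch = list(segment_s = 30, overlap = 0.5, pad = 2, max_freq = 5.5),
    music = list(fs = 8, corr_dim = 64L, order = 2L, grid_bpm = 0.25),
    ppg_band = c(0.5, 5),
    accel_band = c(0.25, 3.0),
    pr_range_sleep = c(40, 120),
    pr_range_wake = c(40, 160),
    hrv = list(
      f_margin_hz = 0.1,
      upsample_factor = 4L,
      bandpass = c(0.75, 6.5),
      validation_ratio = 0.3,
      resample_hz = 4,
      welch_segment_s = 90,
      clean_spectrum_passes = FALSE
    ),
    bands = list(lf = c(0.04, 0.15), hf = c(0.15, 0.40), tp = c(0.0033, 0.40)),
    interp_window_min = 7L
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) {
      abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
    }
    cfg[names(overrides)] <- overrides
  }
  structure(cfg, class = "wristhrv_config")
}
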