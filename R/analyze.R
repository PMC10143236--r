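# Per-epoch pipeline: SQI-gated pulse rate and HRV extraction over the
# centred 3-minute windows of a session.

# measured pulse rate + quality index for one epoch window; window_music is
# the epoch window of the pulse-band stream already decimated to the MUSIC
# working rate
epoch_pulse <- function(psd, window_music, range_bpm, cfg, gate) {
  sqi_pr <- compute_sqi_pr(psd, range_bpm)
  pr <- NA_real_
  if (!gate || sqi_pr >= cfg$sqi_pr_threshold) {
    pr <- tryCatch(
      music_pulse_rate(window_music, cfg$music$fs, range_bpm,
                       order = cfg$music$order, corr_dim = cfg$music$corr_dim,
                       grid_bpm = cfg$music$grid_bpm, music_fs = cfg$music$fs),
      error = function(e) NA_real_
    )
  }
  list(sqi_pr = sqi_pr, pr = pr)
}

# median-filtered interpolation of missing pulse rates over a +/- half-window
fill_pulse_rate <- function(pr, window_min = 7L) {
  half <- window_min %/% 2L
  filled <- pr
  source <- ifelse(is.na(pr), NA_character_, "measured")
  for (i in which(is.na(pr))) {
    lo <- max(1L, i - half)
    hi <- min(length(pr), i + half)
    nb <- pr[lo:hi]
    nb <- nb[!is.na(nb)]
    if (length(nb) > 0) {
      filled[i] <- median(nb)
      source[i] <- "interpolated"
    }
  }
  list(pulse_rate = filled, source = source)
}

#' Per-epoch pulse-rate estimation with quality gating
#'
#' For every epoch with a full centred 3-minute window, computes the Welch
#' PSD of the 0.5-5 Hz bandpassed PPG, the pulse-rate quality index, and -
#' when the index passes its threshold (or gating is disabled) - the MUSIC
#' pulse rate within the state-dependent search range (40-120 bpm asleep,
#' 40-160 bpm awake/resting). Missing epochs are then filled by the median
#' of measured values within a 7-minute window; epochs with no measured
#' neighbour stay missing.
#'
#' @param session A `wristhrv_session`.
#' @param states Per-epoch `"sleep"`/`"awake"` vector.
#' @param activity Per-epoch activity amplitudes.
#' @param config A [wristhrv_config()].
#' @param apply_gates When `FALSE`, MUSIC runs on every epoch regardless of
#'   the quality index (used for no-gating comparisons).
#' @return A tibble with `epoch` (0-based), `state`, `rest`, `sqi_pr`,
#'   `pr_measured` (bpm), `pulse_rate` (bpm, after interpolation), `source`
#'   (`measured`/`interpolated`/`NA`).
#' @export
pulse_rate_pipeline <- function(session, states, activity,
                                config = wristhrv_config(),
                                apply_gates = TRUE) {
  rec <- epoch_records(session, states, activity, config, apply_gates,
                       with_hrv = FALSE)
  rec[, c("epoch", "state", "rest", "sqi_pr", "pr_measured", "pulse_rate",
          "source")]
}

# the shared epoch loop; with_hrv = FALSE skips the PPI/HRV stage
epoch_records <- function(session, states, activity, config, apply_gates,
                          with_hrv = TRUE) {
  fs <- session$ppg_rate
  n_ep <- n_epochs(session)
  stopifnot(length(states) >= n_ep, length(activity) >= n_ep)
  ppg_bp <- bandpass(session$ppg, fs, config$ppg_band[1], config$ppg_band[2])
  music_q <- fs / config$music$fs
  if (abs(music_q - round(music_q)) > 1e-9) {
    abort("epoch_records: PPG rate must be an integer multiple of the MUSIC rate")
  }
  ppg_music <- decimate_fast(ppg_bp, round(music_q))
  mfs <- config$music$fs
  up <- config$hrv$upsample_factor
  ppg_up <- if (with_hrv) {
    upsample_poly(session$ppg, up)
  }

  num_cols <- c("sqi_pr", "pr_measured", "sqi_hrv", "mean_ppi", "rmssd",
                "sdnn", "lf", "hf", "lf_hf", "tp")
  col <- c(
    setNames(lapply(num_cols, function(.) rep(NA_real_, n_ep)), num_cols),
    list(ppi_valid = rep(NA, n_ep), ppi_reason = rep(NA_character_, n_ep),
         n_peaks = rep(NA_integer_, n_ep), rest = rep(NA, n_ep))
  )
  for (i in seq_len(n_ep)) {
    e <- i - 1L
    rec <- list()
    rest <- states[i] == "sleep" || activity[i] <= config$rest_activity_max
    if (e >= 1L && e <= n_ep - 2L) {
      idx <- (60L * (e - 1L) * fs + 1L):(60L * (e + 2L) * fs)
      win_bp <- ppg_bp[idx]
      psd <- welch_psd(win_bp, fs,
                       segment_s = config$welch$segment_s,
                       overlap = config$welch$overlap,
                       pad = config$welch$pad,
                       max_freq = config$welch$max_freq)
      range_bpm <- if (states[i] == "sleep") config$pr_range_sleep else config$pr_range_wake
      idx_m <- (60L * (e - 1L) * mfs + 1L):(60L * (e + 2L) * mfs)
      pe <- epoch_pulse(psd, ppg_music[idx_m], range_bpm, config, apply_gates)
      rec$sqi_pr <- pe$sqi_pr
      rec$pr_measured <- pe$pr

      if (with_hrv && rest && !is.na(pe$pr)) {
        f_music <- pe$pr / 60
        rec$sqi_hrv <- tryCatch(
          compute_sqi_hrv(psd, f_music, config$hrv$f_margin_hz,
                          config$hrv$clean_spectrum_passes),
          error = function(e) NA_real_
        )
        gate_ok <- !apply_gates ||
          (!is.na(rec$sqi_hrv) && rec$sqi_hrv >= config$sqi_hrv_threshold)
        if (gate_ok) {
          hrv <- tryCatch({
            # pad the window with real neighbouring signal so filter settling
            # never touches the peaks that are kept
            fs_up <- fs * up
            pad <- min(2L * fs_up,
                       60L * (e - 1L) * fs * up,
                       length(ppg_up) - 60L * (e + 2L) * fs * up)
            pad <- max(pad, 0L)
            idx_up <- (60L * (e - 1L) * fs * up + 1L - pad):
              (60L * (e + 2L) * fs * up + pad)
            pp <- preprocess_ppg(ppg_up[idx_up], fs, f_music,
                                 config$hrv$upsample_factor,
                                 config$hrv$bandpass, pre_upsampled = TRUE)
            pk <- detect_peaks(pp$signal, pp$fs, f_music) - pad / fs_up
            pk <- pk[pk >= 0 & pk < length(idx) / fs]
            ppi <- validate_ppi(pk, length(idx) / fs, pe$pr,
                                config$hrv$validation_ratio)
            out <- list(n_peaks = length(pk), valid = ppi$valid,
                        reason = ppi$reason,
                        mean_ppi = if (length(ppi$intervals)) mean(ppi$intervals) else NA_real_)
            if (ppi$valid) {
              td <- time_domain_hrv(ppi$intervals)
              fd <- frequency_domain_hrv(pk, ppi$intervals,
                                         config$hrv$resample_hz,
                                         config$hrv$welch_segment_s,
                                         config$bands)
              out <- c(out, td, fd)
            }
            out
          }, error = function(e) NULL)
          if (!is.null(hrv)) {
            rec$ppi_valid <- hrv$valid
            rec$ppi_reason <- hrv$reason
            rec$n_peaks <- hrv$n_peaks
            rec$mean_ppi <- hrv$mean_ppi
            if (hrv$valid) {
              rec$rmssd <- hrv$rmssd; rec$sdnn <- hrv$sdnn
              rec$lf <- hrv$lf; rec$hf <- hrv$hf
              rec$lf_hf <- hrv$lf_hf; rec$tp <- hrv$tp
            }
          }
        }
      }
    }
    col$rest[i] <- rest
    for (nm in names(rec)) col[[nm]][i] <- rec[[nm]]
  }
  out <- tibble(
    epoch = seq_len(n_ep) - 1L, activity = activity[seq_len(n_ep)],
    state = states[seq_len(n_ep)], rest = col$rest,
    sqi_pr = col$sqi_pr, pr_measured = col$pr_measured,
    sqi_hrv = col$sqi_hrv, ppi_valid = col$ppi_valid,
    ppi_reason = col$ppi_reason, n_peaks = col$n_peaks,
    mean_ppi = col$mean_ppi, rmssd = col$rmssd, sdnn = col$sdnn,
    lf = col$lf, hf = col$hf, lf_hf = col$lf_hf, tp = col$tp
  )
  fill <- fill_pulse_rate(out$pr_measured, config$interp_window_min)
  out$pulse_rate <- fill$pulse_rate
  out$source <- fill$source
  out
}

#' Run the full single-session analysis
#'
#' Executes the whole pipeline on one session: per-epoch activity
#' amplitudes, sleep/wake scoring with rescoring, phase definition, gated
#' pulse-rate estimation, gated PPI/HRV extraction, and phase feature
#' aggregation.
#'
#' @param session A `wristhrv_session`.
#' @param config A [wristhrv_config()].
#' @param apply_gates Apply the SQI gates during extraction (default TRUE).
#'   With `FALSE` everything is computed and quality indices are only
#'   recorded, so gating conditions can be compared after the fact.
#' @param condition Gating condition used for the phase features, see
#'   [phase_means()].
#' @return An object of class `wristhrv_analysis`: a list with `epochs`
#'   (per-epoch tibble), `segmentation`, `phases` (tibble or `NULL` when the
#'   participant is excluded), `features` (1-row tibble of the 20 screening
#'   features or `NULL`), `excluded` (logical), `exclusion_reason`,
#'   `config`.
#' @export
analyze_session <- function(session, config = wristhrv_config(),
                            apply_gates = TRUE, condition = "with") {
  act <- activity_amplitude(session$accel, session$accel_rate,
                            config$accel_band)
  n_ep <- min(n_epochs(session), length(act))
  act <- act[seq_len(n_ep)]
  states <- score_sleep_wake(act, config$scripps_weights,
                             config$scripps_threshold)
  seg <- rescore_sleep(states, act, config)

  phases <- tryCatch(define_phases(seg, n_ep, config),
                     wristhrv_excluded = function(e) NULL)
  epochs <- epoch_records(session, seg$states, act, config, apply_gates)

  features <- NULL
  excluded <- is.null(phases)
  reason <- if (excluded) "tst_below_minimum" else NA_character_
  if (!excluded) {
    pm <- phase_means(epochs, phases, config, condition)
    features <- pm$features
    if (pm$excluded) {
      excluded <- TRUE
      reason <- "empty_phase"
      features <- NULL
    }
    counts <- pm$counts
  } else {
    counts <- NULL
  }
  structure(
    list(epochs = epochs, segmentation = seg, phases = phases,
         features = features, phase_counts = counts,
         excluded = excluded, exclusion_reason = reason, config = config,
         apply_gates = apply_gates),
    class = "wristhrv_analysis"
  )
}

#' @export
print.wristhrv_analysis <- function(x, ...) {
  cat(sprintf(
    "<wristhrv_analysis>  %d epochs, TST %d min%s\n",
    nrow(x$epochs), x$segmentation$tst,
    if (x$excluded) paste0(", EXCLUDED (", x$exclusion_reason, ")") else ""
  ))
  invisible(x)
}

#' @rdname analyze_session
#' @param x A `wristhrv_analysis`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.wristhrv_analysis <- function(x, ...) x$epochs

#' @rdname analyze_session
#' @exportS3Method generics::glance
glance.wristhrv_analysis <- function(x, ...) {
  ep <- x$epochs
  tibble(
    n_epochs = nrow(ep),
    tst_min = x$segmentation$tst,
    onset_epoch = x$segmentation$onset,
    wake_epoch = x$segmentation$wake,
    pct_pr_measured = mean(!is.na(ep$pr_measured)) * 100,
    pct_hrv_valid = mean(!is.na(ep$rmssd)) * 100,
    excluded = x$excluded
  )
}

#' Aggregate epoch HRV into phase features
#'
#' Averages per-epoch pulse rate and frequency-domain HRV over the five
#' phases to build the 20-feature screening vector (per phase: mean pulse
#' rate, mean log LF, mean log HF, mean LF/HF). An epoch contributes when it
#' falls in the phase, is resting, has a valid HRV record, is sleep-scored
#' for P2-P4 (mid-sleep wake bouts are excluded), and passes the quality
#' gates required by `condition`:
#' `"with"` gates every phase, `"without"` none, `"awake_only"` gates only
#' P1/P5, `"sleep_only"` only P2-P4. LF and HF are log-transformed (natural
#' log, 1e-12 floor) per epoch before averaging.
#'
#' @param epochs Epoch tibble from [analyze_session()]/[epoch_records].
#' @param phases Phase tibble from [define_phases()].
#' @param config A [wristhrv_config()].
#' @param condition One of `"with"`, `"without"`, `"awake_only"`,
#'   `"sleep_only"`.
#' @return A list with `features` (1-row tibble, columns `p1_pr` ..
#'   `p5_lfhf`), `counts` (tibble `phase`, `n`), `excluded` (TRUE when any
#'   phase has zero contributing epochs).
#' @export
phase_means <- function(epochs, phases, config = wristhrv_config(),
                        condition = c("with", "without", "awake_only",
                                      "sleep_only")) {
  condition <- match.arg(condition)
  feats <- list()
  counts <- numeric(5)
  for (k in seq_len(nrow(phases))) {
    ph <- phases$phase[k]
    in_ph <- epochs$epoch >= phases$start[k] & epochs$epoch < phases$end[k]
    elig <- in_ph & epochs$rest & !is.na(epochs$rmssd)
    if (ph %in% c("P2", "P3", "P4")) elig <- elig & epochs$state == "sleep"
    gated <- switch(condition,
      with = TRUE,
      without = FALSE,
      awake_only = ph %in% c("P1", "P5"),
      sleep_only = ph %in% c("P2", "P3", "P4")
    )
    if (gated) {
      elig <- elig &
        !is.na(epochs$sqi_pr) & epochs$sqi_pr >= config$sqi_pr_threshold &
        !is.na(epochs$sqi_hrv) & epochs$sqi_hrv >= config$sqi_hrv_threshold
    }
    sub <- epochs[which(elig), ]
    counts[k] <- nrow(sub)
    key <- tolower(ph)
    feats[[paste0(key, "_pr")]] <- mean(sub$pulse_rate, na.rm = TRUE)
    feats[[paste0(key, "_log_lf")]] <- mean(log(pmax(sub$lf, 1e-12)))
    feats[[paste0(key, "_log_hf")]] <- mean(log(pmax(sub$hf, 1e-12)))
    feats[[paste0(key, "_lfhf")]] <- mean(sub$lf_hf, na.rm = TRUE)
  }
  list(
    features = as_tibble(feats),
    counts = tibble(phase = phases$phase, n = as.integer(counts)),
    excluded = any(counts == 0)
  )
}
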