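# Synthetic 24 h wearable sessions with known ground truth: an RR-interval
# engine with LF/HF band modulation, a harmonic pulse-waveform PPG model,
# motion-locked artifact bursts, and a sleep/wake/rest activity schedule.

# Band-modulation component set: one deterministic tone per band plus
# n_random stochastic sinusoids clustered within +/- spread of it,
# normalised to unit band power. The narrow cluster makes the band's local
# power drift slowly (coherence time ~ 1/spread), the quasi-stationary
# behaviour short-window HRV estimation relies on.
make_band_components <- function(tone_freq, tone_frac, n_random, spread) {
  freqs <- c(tone_freq, tone_freq + runif(n_random, -spread, spread))
  phases <- c(runif(1, 0, 2 * pi), runif(n_random, 0, 2 * pi))
  pow <- c(tone_frac, rep((1 - tone_frac) / n_random, n_random))
  list(freq = freqs, phase = phases, amp = sqrt(2 * pow))
}

# Sequential beat-time generation: each interval equals the instantaneous
# RR target evaluated at the beat onset, so measured interval band powers
# match the construction directly.
step_beats <- function(duration, rr_mean_sec, lf_env, hf_env, lf_c, hf_c) {
  n_est <- ceiling(duration / (min(rr_mean_sec) / 1000) * 1.2) + 2
  beats <- numeric(n_est)
  t <- 0
  k <- 1L
  n_sec <- length(rr_mean_sec)
  while (t < duration) {
    beats[k] <- t
    s <- min(floor(t), n_sec - 1) + 1
    mod <- lf_env[s] * sum(lf_c$amp * sin(2 * pi * lf_c$freq * t + lf_c$phase)) +
      hf_env[s] * sum(hf_c$amp * sin(2 * pi * hf_c$freq * t + hf_c$phase))
    rr <- rr_mean_sec[s] + mod
    rr <- max(rr, 300)                 # physiological floor, 200 bpm
    t <- t + rr / 1000
    k <- k + 1L
  }
  beats[seq_len(k - 1L)]
}

#' Generate a synthetic RR-interval series
#'
#' Produces beat times whose successive intervals follow a mean level plus
#' narrowband LF (0.04-0.15 Hz) and HF (0.15-0.40 Hz) modulation. Each band
#' holds one deterministic tone (0.10 Hz / 0.25 Hz by default) carrying
#' `tone_frac` of the requested band power plus `n_random` random in-band
#' sinusoids carrying the rest, so the evenly resampled series has Welch
#' band powers matching `lf_power` and `hf_power`. Zero band powers give an
#' exactly constant series.
#'
#' @param duration Duration in seconds.
#' @param mean_hr Mean heart rate in bpm (40-160), or see `hr_profile`.
#' @param lf_power,hf_power Requested band powers in ms^2.
#' @param seed Integer seed; the series is deterministic given it.
#' @param hr_profile Optional per-second heart-rate vector (bpm) overriding
#'   `mean_hr`, e.g. for sweep experiments.
#' @param tone_frac Fraction of each band's power in the deterministic tone.
#' @param n_random Stochastic sinusoids per band.
#' @param band_spread Half-width (Hz) of the stochastic component cluster
#'   around each band tone; defaults `c(lf = 0.002, hf = 0.003)`.
#' @return A tibble with columns `time` (beat onset, s) and `rr_ms`
#'   (interval to the next beat), with the full beat-time vector in
#'   attribute `beat_times`.
#' @examples
#' rr <- generate_rr(600, 60, lf_power = 200, hf_power = 400, seed = 1)
#' mean(rr$rr_ms)
#' @export
generate_rr <- function(duration, mean_hr = 60, lf_power = 0, hf_power = 0,
                        seed = NULL, hr_profile = NULL, tone_frac = 0.7,
                        n_random = 5L, band_spread = c(lf = 0.002,
                                                       hf = 0.003)) {
  if (is.null(hr_profile) && (mean_hr < 40 || mean_hr > 160)) {
    abort("generate_rr: mean_hr outside the physiological 40-160 bpm range")
  }
  if (lf_power < 0 || hf_power < 0) abort("generate_rr: band powers must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n_sec <- ceiling(duration)
  rr_mean_sec <- if (is.null(hr_profile)) {
    rep(60000 / mean_hr, n_sec)
  } else {
    60000 / rep_len(hr_profile, n_sec)
  }
  lf_c <- make_band_components(0.10, tone_frac, n_random, band_spread[[1]])
  hf_c <- make_band_components(0.25, tone_frac, n_random, band_spread[[2]])
  beats <- step_beats(duration, rr_mean_sec,
                      rep(sqrt(lf_power), n_sec), rep(sqrt(hf_power), n_sec),
                      lf_c, hf_c)
  out <- tibble(
    time = beats[-length(beats)],
    rr_ms = diff(beats) * 1000
  )
  attr(out, "beat_times") <- beats
  class(out) <- c("wristhrv_rr", class(out))
  out
}

#' Synthesize a PPG waveform from beat times
#'
#' Integral pulse model: a piecewise-linear cardiac phase hits integer k at
#' beat k, and the waveform is a sum of sine harmonics of that phase with
#' relative amplitudes `harmonics` (energy at f, 2f, 3f). The sine phases
#' align the harmonics on a steep systolic-like upstroke at each beat time,
#' so the waveform has one dominant peak per beat and its derivative peaks
#' exactly at the beats. Optional slow baseline wander and white sensor
#' noise are added.
#'
#' @param beat_times Beat times in seconds (monotone increasing).
#' @param duration Output duration in seconds.
#' @param fs Sampling rate in Hz (default 64).
#' @param harmonics Relative harmonic amplitudes (default `c(1, 0.4, 0.15)`).
#' @param noise_sd White sensor noise standard deviation.
#' @param wander_amp,wander_freq Baseline wander amplitude and frequency.
#' @return Numeric vector of `duration * fs` PPG samples.
#' @export
synthesize_ppg <- function(beat_times, duration, fs = 64,
                           harmonics = c(1, 0.4, 0.15), noise_sd = 0,
                           wander_amp = 0.3, wander_freq = 0.08) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  # monotone C1 phase through (beat time, beat index): instantaneous
  # frequency varies smoothly, with no kink at the beats themselves
  pf <- stats::splinefun(beat_times, seq_along(beat_times) - 1,
                         method = "monoH.FC")
  phase <- pf(pmin(pmax(t, beat_times[1]), beat_times[length(beat_times)]))
  x <- numeric(length(t))
  for (h in seq_along(harmonics)) {
    x <- x + harmonics[h] * sin(2 * pi * h * phase)
  }
  x <- x + wander_amp * sin(2 * pi * wander_freq * t)
  if (noise_sd > 0) x <- x + rnorm(length(t), 0, noise_sd)
  x
}

# Band-limited (0.5-5 Hz) artifact noise, normalised to unit sd.
artifact_noise <- function(n, fs) {
  x <- bandpass(rnorm(n + 2 * fs), fs, 0.5, 5)[(fs + 1):(fs + n)]
  x / sd(x)
}

# Default schedule and physiology parameters of a synthetic participant.
session_defaults <- function() {
  list(
    duration_min = 1440L, sleep_onset_min = 660L, tst_min = 450L,
    pre_rest_min = 120L, post_rest_min = 90L,
    n_awakenings = 3L, awakening_min = 3L,
    hr_wake = 72, hr_sleep = 60,
    lf_wake = 1500, hf_wake = 1200, lf_sleep = 600, hf_sleep = 1000,
    artifact_rate_rest = 0.35, artifact_rate_sleep = 0.05,
    active_move_prob = 0.4,
    ppg_noise_sd = 0.03
  )
}

#' Synthesize a full wearable session with ground truth
#'
#' Builds a complete session: a sleep/wake/rest schedule, an RR series whose
#' LF/HF band powers switch between wake and sleep levels, a harmonic-pulse
#' PPG stream with motion-locked artifact bursts, and a 3-axis acceleration
#' stream whose activity matches the schedule (quiet during sleep, moderate
#' during pre/post-sleep rest, bursty while active). Artifact bursts are
#' band-limited 0.5-5 Hz noise scaled relative to the pulse amplitude and
#' always co-occur with injected acceleration activity.
#'
#' @param params Named list overriding [session_defaults()]: schedule
#'   (`duration_min`, `sleep_onset_min`, `tst_min`, `pre_rest_min`,
#'   `post_rest_min`, `n_awakenings`, `awakening_min`), physiology
#'   (`hr_wake`, `hr_sleep`, `lf_wake`, `hf_wake`, `lf_sleep`, `hf_sleep`),
#'   and noise (`artifact_rate_rest`, `artifact_rate_sleep`,
#'   `active_move_prob`, `ppg_noise_sd`).
#' @param seed Integer seed.
#' @param cohort Label stored in the ground truth (`"healthy"` or
#'   `"mdd-like"`).
#' @return A list with `session` (a [new_session()]) and `truth`, a list of
#'   class `wristhrv_truth` holding `beat_times`, `rr` (tibble), per-minute
#'   `state` (`"sleep"`/`"awake"`) and `minute_class`
#'   (`sleep`/`rest`/`active`/`awakening`), per-second `artifact_mask`,
#'   `sleep_onset_min`, `wake_min`, `tst_min`, `cohort`, `seed`, `params`.
#' @export
synthesize_session <- function(params = list(), seed = 1,
                               cohort = "healthy") {
  p <- session_defaults()
  bad <- setdiff(names(params), names(p))
  if (length(bad)) abort(paste0("unknown session params: ", paste(bad, collapse = ", ")))
  p[names(params)] <- params
  set.seed(seed)

  dur_min <- p$duration_min
  onset <- p$sleep_onset_min
  span <- p$tst_min + p$n_awakenings * p$awakening_min
  wake <- onset + span
  if (onset < p$pre_rest_min || wake + p$post_rest_min > dur_min) {
    abort("synthesize_session: sleep schedule does not fit inside the session")
  }

  # per-minute class
  mclass <- rep("active", dur_min)
  mclass[(onset - p$pre_rest_min + 1):onset] <- "rest"
  mclass[(onset + 1):wake] <- "sleep"
  mclass[(wake + 1):min(dur_min, wake + p$post_rest_min)] <- "rest"
  if (p$n_awakenings > 0) {
    slots <- seq(onset + 30L, wake - 30L - p$awakening_min)
    starts <- sort(sample(slots, p$n_awakenings))
    while (any(diff(starts) < p$awakening_min + 10L)) {
      starts <- sort(sample(slots, p$n_awakenings))
    }
    for (s in starts) mclass[(s + 1):(s + p$awakening_min)] <- "awakening"
  }
  state <- ifelse(mclass %in% c("sleep"), "sleep", "awake")

  dur_s <- dur_min * 60L
  sec_class <- rep(mclass, each = 60L)

  # HR and band-power envelopes per second, smoothed over 3 min
  asleep <- sec_class == "sleep"
  hr_sec <- ifelse(asleep, p$hr_sleep, p$hr_wake)
  lf_sec <- ifelse(asleep, p$lf_sleep, p$lf_wake)
  hf_sec <- ifelse(asleep, p$hf_sleep, p$hf_wake)
  smooth3 <- function(x) {
    as.numeric(stats::filter(c(rep(x[1], 90), x, rep(x[length(x)], 90)),
                             rep(1 / 181, 181)))[91:(90 + length(x))]
  }
  hr_sec <- smooth3(hr_sec)
  lf_sec <- smooth3(lf_sec)
  hf_sec <- smooth3(hf_sec)

  lf_c <- make_band_components(0.10, 0.7, 5L, 0.002)
  hf_c <- make_band_components(0.25, 0.7, 5L, 0.003)
  beats <- step_beats(dur_s, 60000 / hr_sec, sqrt(lf_sec), sqrt(hf_sec),
                      lf_c, hf_c)

  # artifact mask and acceleration, built minute by minute
  fs_acc <- 32L
  artifact <- logical(dur_s)
  art_mult <- numeric(dur_s)
  acc_env <- numeric(dur_s)            # per-second movement amplitude, counts
  base_sd <- c(sleep = 0.02, rest = 0.05, active = 0.3, awakening = 0.1)

  for (m in seq_len(dur_min)) {
    sec0 <- (m - 1L) * 60L
    cls <- mclass[m]
    if (cls == "active") {
      mv <- runif(60) < p$active_move_prob
      acc_env[sec0 + which(mv)] <- runif(sum(mv), 40, 140)
      artifact[sec0 + which(mv)] <- TRUE
      art_mult[sec0 + which(mv)] <- runif(sum(mv), 3, 6)
    } else if (cls == "rest") {
      if (runif(1) < p$artifact_rate_rest) {
        len <- round(runif(1, 20, 55))
        st <- sample.int(60 - 5, 1)
        sec <- sec0 + st + seq_len(min(len, 60 - st))
        acc_env[sec] <- runif(1, 2, 6)
        artifact[sec] <- TRUE
        art_mult[sec] <- runif(1, 1, 2.5)
      }
      # small fidgets keeping the rest period awake-scored
      fid <- sample.int(60, 4)
      acc_env[sec0 + fid] <- pmax(acc_env[sec0 + fid], runif(4, 8, 20))
    } else if (cls == "awakening") {
      # quiet wakefulness: little wrist movement, but enough micro-motion
      # to corrupt the PPG
      sec <- sec0 + seq_len(60)
      acc_env[sec] <- runif(60, 0.8, 1.5)
      artifact[sec] <- TRUE
      art_mult[sec] <- runif(1, 1, 2)
    } else if (cls == "sleep") {
      if (runif(1) < p$artifact_rate_sleep) {
        len <- round(runif(1, 10, 30))
        st <- sample.int(60 - 5, 1)
        sec <- sec0 + st + seq_len(min(len, 60 - st))
        # small wrist twitches: clearly above sensor noise but far below
        # the activity scale that would wake-score the epoch
        acc_env[sec] <- runif(1, 0.3, 1.2)
        artifact[sec] <- TRUE
        art_mult[sec] <- runif(1, 1, 2.5)
      }
    }
  }

  # acceleration stream: gravity on z + class noise + 1.5-2.5 Hz movement
  n_acc <- dur_s * fs_acc
  t_acc <- seq(0, dur_s - 1 / fs_acc, by = 1 / fs_acc)
  sd_sec <- base_sd[sec_class]
  noise_sd_samp <- rep(sd_sec, each = fs_acc)
  env_samp <- rep(acc_env, each = fs_acc)
  move <- env_samp * sin(2 * pi * runif(1, 1.5, 2.5) * t_acc)
  accel <- cbind(
    rnorm(n_acc, 0, noise_sd_samp) + 0.5 * move,
    rnorm(n_acc, 0, noise_sd_samp) + 0.8 * move,
    64 + rnorm(n_acc, 0, noise_sd_samp) + 0.3 * move
  )

  # PPG stream with artifacts where the mask is set
  fs_ppg <- 64L
  ppg <- synthesize_ppg(beats, dur_s, fs_ppg, noise_sd = p$ppg_noise_sd)
  if (any(artifact)) {
    pulse_sd <- sqrt(sum(c(1, 0.4, 0.15)^2) / 2)
    art_sec <- which(artifact)
    noise <- artifact_noise(length(art_sec) * fs_ppg, fs_ppg)
    mult_samp <- rep(art_mult[art_sec], each = fs_ppg)
    samp_idx <- rep((art_sec - 1L) * fs_ppg, each = fs_ppg) +
      rep(seq_len(fs_ppg), times = length(art_sec))
    ppg[samp_idx] <- ppg[samp_idx] + noise * mult_samp * pulse_sd
  }

  session <- new_session(ppg, accel, fs_ppg, fs_acc, start_time = 0)
  truth <- structure(
    list(
      beat_times = beats,
      rr = tibble(time = beats[-length(beats)], rr_ms = diff(beats) * 1000),
      state = state, minute_class = mclass,
      artifact_mask = artifact,
      sleep_onset_min = onset, wake_min = wake, tst_min = p$tst_min,
      cohort = cohort, seed = seed, params = p
    ),
    class = "wristhrv_truth"
  )
  list(session = session, truth = truth)
}

#' Ground-truth per-epoch HRV reference values
#'
#' Computes, from the true beat times, the quantities the pipeline estimates
#' per epoch: mean RR, RMSSD and heart rate over the same centred 3-minute
#' windows the pipeline uses. First and last epochs, which lack a full
#' window, are `NA`.
#'
#' @param truth A `wristhrv_truth` from [synthesize_session()].
#' @param n_epochs Number of epochs to cover.
#' @return A tibble with `epoch` (0-based), `mean_rr_ms`, `rmssd_ms`,
#'   `hr_bpm`.
#' @export
truth_epoch_hrv <- function(truth, n_epochs) {
  beats <- truth$beat_times
  out <- purrr::map_dfr(seq_len(n_epochs) - 1L, function(e) {
    if (e < 1L || e > n_epochs - 2L) {
      return(tibble(epoch = e, mean_rr_ms = NA_real_, rmssd_ms = NA_real_,
                    hr_bpm = NA_real_))
    }
    w <- beats[beats >= 60 * (e - 1) & beats < 60 * (e + 2)]
    if (length(w) < 4) {
      return(tibble(epoch = e, mean_rr_ms = NA_real_, rmssd_ms = NA_real_,
                    hr_bpm = NA_real_))
    }
    iv <- diff(w) * 1000
    tibble(epoch = e, mean_rr_ms = mean(iv),
           rmssd_ms = sqrt(mean(diff(iv)^2)), hr_bpm = 60000 / mean(iv))
  })
  out
}

#' Synthesize a two-group cohort
#'
#' Generates `n_healthy` healthy-like and `n_mdd` depressed-like sessions.
#' The group effect follows the clinical direction of nocturnal HRV in
#' depression: the mdd-like group has its sleep-period HF power scaled by
#' `hf_ratio`, LF by `lf_ratio` (so LF/HF rises when `lf_ratio > hf_ratio`)
#' and heart rate shifted by `hr_shift` bpm; wake-period powers get the
#' square root of the same ratios. Per-participant variation is lognormal on
#' band powers (`sd_log`) and Gaussian on heart rate.
#'
#' @param n_healthy,n_mdd Group sizes.
#' @param effect_params List with `hf_ratio` (default 0.4), `lf_ratio`
#'   (default 0.7), `hr_shift` (default 3), `sd_log` (default 0.35).
#' @param seed Integer seed for the whole cohort.
#' @param session_params Overrides passed to every [synthesize_session()]
#'   call; the cohort default session is 690 min with sleep onset at minute
#'   120, long enough to hold all five phases.
#' @return A tibble with columns `id`, `label` (`healthy`/`mdd`), `session`
#'   and `truth` (list columns).
#' @export
synthesize_cohort <- function(n_healthy = 20, n_mdd = 20,
                              effect_params = list(), seed = 1,
                              session_params = list()) {
  ep <- list(hf_ratio = 0.4, lf_ratio = 0.7, hr_shift = 3, sd_log = 0.35)
  ep[names(effect_params)] <- effect_params
  set.seed(seed)
  base <- list(duration_min = 690L, sleep_onset_min = 120L,
               pre_rest_min = 90L, post_rest_min = 90L)
  base[names(session_params)] <- session_params
  labels <- c(rep("healthy", n_healthy), rep("mdd", n_mdd))
  seeds <- sample.int(.Machine$integer.max %/% 2, length(labels))
  person_lf <- exp(rnorm(length(labels), 0, ep$sd_log))
  person_hf <- exp(rnorm(length(labels), 0, ep$sd_log))
  person_hr <- rnorm(length(labels), 0, 2.5)

  rows <- purrr::map(seq_along(labels), function(i) {
    d <- session_defaults()
    mdd <- labels[i] == "mdd"
    p <- base
    p$lf_sleep <- d$lf_sleep * person_lf[i] * if (mdd) ep$lf_ratio else 1
    p$hf_sleep <- d$hf_sleep * person_hf[i] * if (mdd) ep$hf_ratio else 1
    p$lf_wake <- d$lf_wake * person_lf[i] * if (mdd) sqrt(ep$lf_ratio) else 1
    p$hf_wake <- d$hf_wake * person_hf[i] * if (mdd) sqrt(ep$hf_ratio) else 1
    p$hr_sleep <- d$hr_sleep + person_hr[i] + if (mdd) ep$hr_shift else 0
    p$hr_wake <- d$hr_wake + person_hr[i] + if (mdd) ep$hr_shift else 0
    out <- synthesize_session(p, seed = seeds[i],
                              cohort = if (mdd) "mdd-like" else "healthy")
    tibble(id = sprintf("S%02d", i), label = labels[i],
           session = list(out$session), truth = list(out$truth))
  })
  bind_rows(rows)
}
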