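# Independent brute-force oracles and small fixture builders shared across
# test files. The oracles deliberately re-implement the published pseudocode
# literally (index loops, no shared helpers) so they stay independent of the
# package's vectorised implementations.

# literal pulse-rate SQI pseudocode: dn/bin over the whole PSD, restriction
# of the initial peak to 40-160 bpm, -5 dB threshold, population sd
brute_sqi_pr <- function(bin_bpm, dn, f_min, f_max) {
  init_idx <- 0L
  best <- -Inf
  for (i in seq_along(dn)) {
    if (bin_bpm[i] >= 40 && bin_bpm[i] <= 160 && dn[i] > best) {
      best <- dn[i]
      init_idx <- i
    }
  }
  f_init <- bin_bpm[init_idx]
  threshold <- dn[init_idx] / 3.16
  upper <- max(f_max, 2.0 * f_init)
  idx_array <- c()
  for (i in seq_along(dn)) {
    if (dn[i] > threshold && bin_bpm[i] >= f_min && bin_bpm[i] <= upper) {
      idx_array <- c(idx_array, i)
    }
  }
  if (length(idx_array) > 1) {
    vals <- bin_bpm[idx_array]
    m <- sum(vals) / length(vals)
    bin_std <- sqrt(sum((vals - m)^2) / length(vals))
    1.0 - 3.0 * bin_std / (upper - f_min)
  } else {
    1.0
  }
}

# literal harmonic-ratio SQI pseudocode: six band index sets, two sums
brute_sqi_hrv <- function(bin_hz, dn, f_music, f_margin) {
  in_range <- function(lo, hi) which(bin_hz >= lo & bin_hz <= hi)
  idx_h1 <- in_range(f_music - f_margin, f_music + f_margin)
  idx_h2 <- in_range(2 * f_music - f_margin, 2 * f_music + f_margin)
  idx_h3 <- in_range(3 * f_music - f_margin, 3 * f_music + f_margin)
  idx_i1 <- in_range(0.5 * f_music + f_margin, f_music - f_margin)
  idx_i2 <- in_range(f_music + f_margin, 2 * f_music - f_margin)
  idx_i3 <- in_range(2 * f_music + f_margin, 3 * f_music - f_margin)
  a_h <- sum(dn[idx_h1]) + sum(dn[idx_h2]) + sum(dn[idx_h3])
  a_i <- sum(dn[idx_i1]) + sum(dn[idx_i2]) + sum(dn[idx_i3])
  if (a_i > 0) log(1.0 + a_h / a_i) else 0.0
}

# random PSD-like spectra over 0-5.5 Hz on a 1 bpm grid
random_spectrum <- function() {
  freq <- seq(0, 5.5, by = 1 / 60)
  dens <- stats::rexp(length(freq))
  # occasionally concentrate power like a real pulse spectrum
  if (stats::runif(1) < 0.5) {
    f0 <- stats::runif(1, 0.7, 2.6)
    dens <- dens + 50 * stats::dnorm(freq, f0, 0.03) +
      8 * stats::dnorm(freq, 2 * f0, 0.03)
  }
  tibble::tibble(frequency = freq, density = dens)
}

# brute-force confusion-matrix metrics
brute_metrics <- function(truth, pred) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] && pred[i]) tp <- tp + 1
    if (!truth[i] && !pred[i]) tn <- tn + 1
    if (!truth[i] && pred[i]) fp <- fp + 1
    if (truth[i] && !pred[i]) fn <- fn + 1
  }
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    mcc = if (den > 0) (tp * tn - fp * fn) / den else 0
  )
}

# a tiny valid session: constant-HR pulse plus quiet acceleration
tiny_session <- function(minutes = 12, hr = 72, fs_ppg = 64, fs_acc = 32) {
  dur <- minutes * 60
  beats <- seq(0, dur + 2, by = 60 / hr)
  ppg <- synthesize_ppg(beats, dur, fs_ppg, noise_sd = 0.01)
  acc <- cbind(matrix(rnorm(dur * fs_acc * 2, 0, 0.02), ncol = 2),
               64 + rnorm(dur * fs_acc, 0, 0.02))
  new_session(ppg, acc, fs_ppg, fs_acc, start_time = 1600000000)
}

# clean (artifact-free) synthetic session used by several fidelity tests;
# the default schedule clears the 270-min sleep-time requirement
clean_session <- function(seed = 11, duration_min = 540L, tst_min = 320L,
                          post_rest_min = 40L) {
  synthesize_session(
    list(duration_min = duration_min, sleep_onset_min = 120L,
         pre_rest_min = 90L, post_rest_min = post_rest_min,
         tst_min = tst_min, n_awakenings = 0L, artifact_rate_rest = 0,
         artifact_rate_sleep = 0),
    seed = seed
  )
}
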