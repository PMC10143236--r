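#' Per-epoch activity amplitude from wrist acceleration
#'
#' The 3-axis acceleration is reduced to its vector magnitude, bandpass
#' filtered (Butterworth order 3, 0.25-3.0 Hz, zero phase) to remove gravity
#' and high-frequency sensor noise, and summarised per 1-minute epoch as the
#' sum of per-second maxima of the absolute filtered signal. Units are device
#' counts (1/64 g for the E4).
#'
#' @param accel 3-column acceleration matrix (device counts).
#' @param accel_rate Sampling rate in Hz (nominal 32).
#' @param band Bandpass edges in Hz.
#' @return Numeric vector of activity amplitudes, one per whole epoch.
#' @export
activity_amplitude <- function(accel, accel_rate = 32, band = c(0.25, 3.0)) {
  accel <- as.matrix(accel)
  per_epoch <- 60 * accel_rate
  n_ep <- floor(nrow(accel) / per_epoch)
  if (n_ep < 1) abort("activity_amplitude: stream shorter than one epoch")
  mag <- sqrt(rowSums(accel^2))
  filt <- abs(bandpass(mag, accel_rate, band[1], band[2], order = 3))
  n_sec <- n_ep * 60L
  filt <- filt[seq_len(n_sec * accel_rate)]
  sec_max <- apply(matrix(filt, nrow = accel_rate), 2, max)
  as.numeric(colSums(matrix(sec_max, nrow = 60L)))
}

#' Sleep/wake scoring from activity amplitudes
#'
#' Actigraphic scoring in the Scripps Clinic style: an epoch is scored sleep
#' when the weighted sum of activity over a symmetric window of neighbouring
#' epochs falls below a threshold. Boundary epochs use only the neighbours
#' that exist (missing terms contribute zero).
#'
#' @param activity Per-epoch activity vector from [activity_amplitude()].
#' @param weights Symmetric weight vector of odd length centred on the scored
#'   epoch; default uniform 0.0064 over +/-10 epochs.
#' @param threshold Score threshold (default 1.0).
#' @return Character vector, `"sleep"` or `"awake"` per epoch.
#' @export
score_sleep_wake <- function(activity, weights = rep(0.0064, 21),
                             threshold = 1.0) {
  if (length(weights) %% 2 != 1) {
    abort("score_sleep_wake: weight vector must have odd length")
  }
  h <- (length(weights) - 1L) %/% 2L
  n <- length(activity)
  padded <- c(numeric(h), activity, numeric(h))
  score <- vapply(seq_len(n), function(i) {
    sum(weights * padded[i:(i + 2L * h)])
  }, numeric(1))
  ifelse(score < threshold, "sleep", "awake")
}

# one pass of the three rescoring rules; returns possibly-modified states
rescore_pass <- function(states, activity, rc) {
  n <- length(states)
  q75 <- quantile(activity, rc$activity_percentile / 100, names = FALSE)

  # Rule 1: sleep runs shorter than min_run_min flanked on both sides by
  # epochs whose activity exceeds the percentile -> awake.
  runs <- true_runs(states == "sleep")
  for (k in seq_len(nrow(runs))) {
    s <- runs$start[k]; e <- runs$end[k]
    if (e - s + 1L < rc$min_run_min && s > 1L && e < n &&
        activity[s - 1L] > q75 && activity[e + 1L] > q75) {
      states[s:e] <- "awake"
    }
  }

  # Rule 2: connect sleep fragments across wake gaps of at most max_gap_min;
  # keep only the segment with the most sleep epochs.
  runs <- true_runs(states == "sleep")
  if (nrow(runs) > 0) {
    seg_id <- integer(nrow(runs))
    seg_id[1] <- 1L
    if (nrow(runs) > 1) {
      for (k in 2:nrow(runs)) {
        gap <- runs$start[k] - runs$end[k - 1L] - 1L
        seg_id[k] <- if (gap <= rc$max_gap_min) seg_id[k - 1L] else seg_id[k - 1L] + 1L
      }
    }
    sleep_per_seg <- tapply(runs$end - runs$start + 1L, seg_id, sum)
    best <- as.integer(names(sleep_per_seg))[which.max(sleep_per_seg)]
    for (k in seq_len(nrow(runs))) {
      if (seg_id[k] != best) states[runs$start[k]:runs$end[k]] <- "awake"
    }
  }

  # Rule 3: within the retained region, find the longest consecutive-sleep
  # fragment when awakenings shorter than ignore_awakening_min are ignored;
  # sleep fragments shorter than min_fragment_min strictly outside its ends
  # -> awake.
  runs <- true_runs(states == "sleep")
  if (nrow(runs) > 0) {
    relaxed <- states == "sleep"
    wruns <- true_runs(states == "awake")
    for (k in seq_len(nrow(wruns))) {
      if (wruns$end[k] - wruns$start[k] + 1L < rc$ignore_awakening_min) {
        relaxed[wruns$start[k]:wruns$end[k]] <- TRUE
      }
    }
    # candidate core fragments must contain at least one true sleep epoch
    cores <- true_runs(relaxed)
    cores <- cores[vapply(seq_len(nrow(cores)), function(k) {
      any(states[cores$start[k]:cores$end[k]] == "sleep")
    }, logical(1)), ]
    core <- cores[which.max(cores$end - cores$start), ]
    for (k in seq_len(nrow(runs))) {
      len <- runs$end[k] - runs$start[k] + 1L
      if (len < rc$min_fragment_min &&
          (runs$end[k] < core$start || runs$start[k] > core$end)) {
        states[runs$start[k]:runs$end[k]] <- "awake"
      }
    }
  }
  states
}

#' Rescore a sleep/wake sequence and extract the main sleep segment
#'
#' Applies three conservative corrections to an actigraphic sleep/wake
#' sequence, each converting only sleep to awake: (1) short sleep runs
#' (< 120 min) bracketed by high-activity epochs (above the 75th percentile
#' of all epochs' activity) become awake; (2) sleep fragments connected
#' across wake gaps of up to 100 min are grouped and only the largest group
#' is retained; (3) sleep fragments shorter than 60 min lying beyond either
#' end of the longest consecutive-sleep core (awakenings under 4 min
#' ignored) become awake. The pass is iterated to a fixed point, so the
#' operation is idempotent.
#'
#' @param states Character vector of `"sleep"`/`"awake"` per epoch.
#' @param activity Per-epoch activity amplitudes (same length).
#' @param config A [wristhrv_config()]; only its `rescore` block is used.
#'
#' @return A list of class `wristhrv_segmentation` with elements `states`
#'   (rescored), `onset` and `wake` (0-based epoch indices bounding the main
#'   sleep segment, half-open), and `tst` (minutes scored sleep inside it).
#'   When no sleep remains, `onset` and `wake` are `NA` and `tst` is 0.
#' @export
rescore_sleep <- function(states, activity, config = wristhrv_config()) {
  stopifnot(length(states) == length(activity))
  rc <- config$rescore
  repeat {
    new <- rescore_pass(states, activity, rc)
    if (identical(new, states)) break
    states <- new
  }
  idx <- which(states == "sleep")
  if (length(idx) == 0) {
    seg <- list(states = states, onset = NA_integer_, wake = NA_integer_,
                tst = 0L)
  } else {
    onset <- min(idx) - 1L            # 0-based
    wake <- max(idx)                  # half-open upper bound, 0-based
    seg <- list(states = states, onset = onset, wake = wake,
                tst = length(idx))
  }
  structure(seg, class = "wristhrv_segmentation")
}

#' @export
print.wristhrv_segmentation <- function(x, ...) {
  cat(sprintf(
    "<wristhrv_segmentation>  main sleep [%s, %s), TST %d min\n",
    x$onset, x$wake, x$tst
  ))
  invisible(x)
}

#' Define the five sleep-anchored analysis phases
#'
#' Phases are 90-min intervals anchored on sleep onset and final wake: P1 is
#' the awake period immediately before onset, P2 and P3 the first and second
#' 90 min of sleep, P4 the remainder of the sleep period (variable length),
#' and P5 the first 90 min after wake. A participant needs at least 270 min
#' of total sleep time; shorter records raise an exclusion error. When the
#' recording margin before onset or after wake is shorter than 90 min, P1 or
#' P5 is truncated with a warning.
#'
#' @param seg A `wristhrv_segmentation` from [rescore_sleep()].
#' @param n_epochs Total epoch count of the record.
#' @param config A [wristhrv_config()]; uses `phase$len_min` and
#'   `phase$min_tst_min`.
#'
#' @return A tibble with columns `phase` (`"P1"`..`"P5"`), `start`, `end`
#'   (0-based half-open epoch bounds).
#' @export
define_phases <- function(seg, n_epochs, config = wristhrv_config()) {
  len <- config$phase$len_min
  if (is.na(seg$onset) || seg$tst < config$phase$min_tst_min) {
    abort(
      sprintf("participant excluded: total sleep time %d min below %d min",
              seg$tst, config$phase$min_tst_min),
      class = "wristhrv_excluded"
    )
  }
  onset <- seg$onset
  wake <- seg$wake
  p1_start <- onset - len
  p5_end <- wake + len
  if (p1_start < 0) {
    warn("recording starts less than 90 min before sleep onset; P1 truncated")
    p1_start <- 0L
  }
  if (p5_end > n_epochs) {
    warn("recording ends less than 90 min after wake; P5 truncated")
    p5_end <- n_epochs
  }
  if (wake - onset < 2L * len) {
    abort("define_phases: sleep segment shorter than P2 + P3")
  }
  tibble(
    phase = c("P1", "P2", "P3", "P4", "P5"),
    start = as.integer(c(p1_start, onset, onset + len, onset + 2L * len, wake)),
    end = as.integer(c(onset, onset + len, onset + 2L * len, wake, p5_end))
  )
}
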