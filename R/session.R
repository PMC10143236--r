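#' Construct a wearable session
#'
#' A session holds the two raw streams of a wrist recording on a shared clock:
#' PPG (blood volume pulse, nominally 64 Hz) and 3-axis acceleration
#' (nominally 32 Hz, device counts of 1/64 g). Both streams start at
#' `start_time`; the session duration is set by the shorter stream.
#'
#' @param ppg Numeric vector of PPG samples (arbitrary units).
#' @param accel Numeric matrix with 3 columns (x, y, z) of acceleration
#'   samples in device counts (1/64 g).
#' @param ppg_rate,accel_rate Sampling rates in Hz.
#' @param start_time Session start, seconds since the Unix epoch.
#'
#' @return An object of class `wristhrv_session` with fields `ppg`, `accel`,
#'   `ppg_rate`, `accel_rate`, `start_time`, `duration` (seconds).
#' @examples
#' s <- new_session(sin(2 * pi * 1.2 * seq(0, 60, by = 1 / 64)),
#'                  matrix(0, 60 * 32, 3), 64, 32)
#' s$duration
#' @export
new_session <- function(ppg, accel, ppg_rate = 64, accel_rate = 32,
                        start_time = 0) {
  if (!is.numeric(ppg) || length(ppg) == 0) {
    abort("session: PPG stream must be a non-empty numeric vector")
  }
  accel <- as.matrix(accel)
  if (nrow(accel) == 0 || ncol(accel) != 3) {
    abort("session: acceleration must be a non-empty 3-column matrix")
  }
  if (ppg_rate <= 0 || accel_rate <= 0) {
    abort("session: sample rates must be positive")
  }
  duration <- min(length(ppg) / ppg_rate, nrow(accel) / accel_rate)
  structure(
    list(
      ppg = as.numeric(ppg), accel = accel,
      ppg_rate = ppg_rate, accel_rate = accel_rate,
      start_time = as.numeric(start_time), duration = duration
    ),
    class = "wristhrv_session"
  )
}

#' @export
print.wristhrv_session <- function(x, ...) {
  cat(sprintf(
    "<wristhrv_session>  %.1f min, PPG %g Hz (%d samples), ACC %g Hz (%d samples)\n",
    x$duration / 60, x$ppg_rate, length(x$ppg), x$accel_rate, nrow(x$accel)
  ))
  invisible(x)
}

#' Number of whole 1-minute epochs in a session
#'
#' Epoch `i` (0-based) covers the half-open interval `[60*i, 60*(i+1))`
#' seconds from session start; a trailing partial epoch is dropped.
#'
#' @param session A `wristhrv_session`.
#' @return Integer epoch count.
#' @export
n_epochs <- function(session) {
  as.integer(floor(session$duration / 60))
}

read_e4_csv <- function(path, ncol_expected) {
  if (!file.exists(path)) {
    abort(sprintf("format error: missing file '%s'", path))
  }
  raw <- read.csv(path, header = FALSE)
  if (nrow(raw) < 3) abort(sprintf("format error: '%s' has no samples", path))
  start <- as.numeric(raw[1, 1])
  rate <- as.numeric(raw[2, 1])
  if (is.na(rate) || rate <= 0) {
    abort(sprintf("format error: non-positive sample rate in '%s'", path))
  }
  samples <- as.matrix(raw[-(1:2), seq_len(ncol_expected), drop = FALSE])
  storage.mode(samples) <- "double"
  list(start = start, rate = rate, samples = samples)
}

#' Read an E4-dialect session directory
#'
#' Reads `BVP.csv` (PPG) and `ACC.csv` (3-axis acceleration) written in the
#' Empatica E4 CSV dialect: row 1 is the Unix start timestamp, row 2 the
#' sample rate in Hz, remaining rows one sample each. The two files may start
#' at different clock times; the streams are trimmed to their common time
#' window and the later start becomes the session start.
#'
#' @param path Directory containing `BVP.csv` and `ACC.csv`.
#' @return A [new_session()] object covering the overlap of the two streams.
#' @export
read_session <- function(path) {
  bvp <- read_e4_csv(file.path(path, "BVP.csv"), 1L)
  acc <- read_e4_csv(file.path(path, "ACC.csv"), 3L)

  start <- max(bvp$start, acc$start)
  end <- min(
    bvp$start + nrow(bvp$samples) / bvp$rate,
    acc$start + nrow(acc$samples) / acc$rate
  )
  if (end - start < 600) {
    abort("insufficient data: stream overlap shorter than 10 minutes")
  }
  trim <- function(s, from, to) {
    i0 <- round((from - s$start) * s$rate) + 1
    i1 <- round((to - s$start) * s$rate)
    s$samples[i0:i1, , drop = FALSE]
  }
  new_session(
    ppg = trim(bvp, start, end)[, 1],
    accel = trim(acc, start, end),
    ppg_rate = bvp$rate, accel_rate = acc$rate,
    start_time = start
  )
}

#' Write a session as E4-dialect CSV files
#'
#' Writes `BVP.csv` and `ACC.csv` readable by [read_session()]. Numeric
#' values are written at full precision, so a write/read round trip
#' reproduces the session exactly up to stream-overlap trimming.
#'
#' @param session A `wristhrv_session`.
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "wristhrv_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_one <- function(file, start, rate, samples) {
    con <- file(file.path(path, file), "w")
    on.exit(close(con))
    nc <- ncol(samples)
    writeLines(paste(rep(format(start, scientific = FALSE), nc), collapse = ","), con)
    writeLines(paste(rep(format(rate, scientific = FALSE), nc), collapse = ","), con)
    write.table(
      format(samples, digits = 15, trim = TRUE, scientific = FALSE),
      con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE
    )
  }
  write_one("BVP.csv", session$start_time, session$ppg_rate,
            matrix(session$ppg, ncol = 1))
  write_one("ACC.csv", session$start_time, session$accel_rate, session$accel)
  invisible(path)
}
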