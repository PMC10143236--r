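# Small shared helpers: windows, filters, run-length utilities.

# 4-term Blackman-Harris window (periodic form is irrelevant at these lengths;
# symmetric coefficients as in standard DSP references).
blackman_harris <- function(n) {
  if (n == 1) return(1)
  k <- seq_len(n) - 1
  a <- c(0.35875, 0.48829, 0.14128, 0.01168)
  a[1] - a[2] * cos(2 * pi * k / (n - 1)) +
    a[3] * cos(4 * pi * k / (n - 1)) - a[4] * cos(6 * pi * k / (n - 1))
}

# Zero-phase ARMA filtering (forward-backward) on the compiled IIR kernel,
# with odd-reflection extension at both ends so narrow-band filters settle
# inside the extension instead of ringing into the data.
filtfilt_fast <- function(bf, x, ext = NULL) {
  n <- length(x)
  if (is.null(ext)) ext <- 3 * max(length(bf$a), length(bf$b))
  ext <- min(ext, n - 1L)
  xe <- c(2 * x[1] - x[(ext + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - ext)])
  y <- cpp_iir(bf$b, bf$a, xe)
  y <- rev(cpp_iir(bf$b, bf$a, rev(y)))
  y[(ext + 1L):(ext + n)]
}

# Zero-phase Butterworth bandpass. Edges in Hz, clipped below Nyquist.
bandpass <- function(x, fs, lo, hi, order = 3) {
  nyq <- fs / 2
  hi <- min(hi, nyq * 0.99)
  if (lo >= hi) abort("bandpass: lower edge at or above upper edge")
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  filtfilt_fast(bf, x - mean(x), ext = round(2 * fs / lo))
}

# Polyphase sinc upsampling by an integer factor (kernel identical to
# signal::resample's order-5 windowed sinc, applied per phase in bulk).
upsample_poly <- function(x, L, order = 5) {
  if (L == 1) return(x)
  n <- length(x)
  sinc <- function(u) ifelse(u == 0, 1, sin(pi * u) / (pi * u))
  xp <- c(rep(x[1], order), x, rep(x[n], order))
  m_total <- n * L - (L - 1L)
  y <- numeric(m_total)
  for (j in 0:(L - 1L)) {
    u <- j / L - (-order:order)
    w <- sinc(u) * (0.5 + 0.5 * cos(pi * u / (order + 0.5)))
    w <- w / sum(w)                   # preserve constants exactly
    acc <- numeric(n)
    for (i in -order:order) {
      acc <- acc + xp[(1:n) + i + order] * w[i + order + 1L]
    }
    pos <- seq(j + 1L, m_total, by = L)
    y[pos] <- acc[seq_along(pos)]
  }
  y
}

# Decimation by an integer factor: cached FIR anti-alias lowpass (cutoff at
# 80% of the output Nyquist) then subsampling.
.decim_cache <- new.env(parent = emptyenv())
decimate_fast <- function(x, q) {
  key <- as.character(q)
  h <- .decim_cache[[key]]
  if (is.null(h)) {
    h <- signal::fir1(64, 0.8 / q)
    .decim_cache[[key]] <- h
  }
  as.numeric(cpp_fir_decim(h, x, as.integer(q)))
}

# Maximal runs of TRUE in a logical vector -> tibble(start, end) 1-based,
# end inclusive. Zero-row tibble when no TRUE present.
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep])
}

# Population standard deviation (n denominator), the convention of the
# SQI definitions.
pop_sd <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Local-maximum peak picking with a minimum-distance constraint: candidates
# are strict-left/weak-right local maxima above min_height; conflicts within
# min_dist are resolved in favour of the taller peak (the semantics of the
# usual find_peaks implementations). Returns sorted sample indices.
find_local_peaks <- function(x, min_dist = 1L, min_height = -Inf) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] > min_height]
  if (length(cand) == 0) return(integer(0))
  ord <- cand[order(-x[cand])]
  keep <- logical(n)
  blocked <- logical(n)
  for (i in ord) {
    if (!blocked[i]) {
      keep[i] <- TRUE
      blocked[max(1L, i - min_dist):min(n, i + min_dist)] <- TRUE
    }
  }
  which(keep)
}

# Butterworth bandpass with a per-session design cache (the HRV stage asks
# for nearly identical bands epoch after epoch).
.filter_cache <- new.env(parent = emptyenv())
bandpass_cached <- function(x, fs, lo, hi, order = 3) {
  nyq <- fs / 2
  hi <- min(hi, nyq * 0.99)
  if (lo >= hi) abort("bandpass: lower edge at or above upper edge")
  key <- paste(fs, order, round(lo, 4), round(hi, 4))
  bf <- .filter_cache[[key]]
  if (is.null(bf)) {
    bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
    .filter_cache[[key]] <- bf
  }
  filtfilt_fast(bf, x - mean(x), ext = round(2 * fs / lo))
}
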