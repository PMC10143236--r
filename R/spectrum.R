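#' Welch power spectral density
#'
#' Averaged-periodogram PSD over overlapping Blackman-Harris-windowed
#' segments, the spectral front end shared by the pulse-rate quality gate and
#' the harmonic-ratio HRV quality gate. Segments are zero-padded by `pad` to
#' refine the bin grid (the gates need roughly 1 bpm bin spacing in the
#' pulse band).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param segment_s Segment length in seconds (default 30).
#' @param overlap Fractional segment overlap (default 0.5).
#' @param pad Zero-padding factor for the segment FFT (default 2).
#' @param max_freq Highest frequency retained (Hz); `NULL` keeps the full
#'   one-sided spectrum up to Nyquist.
#' @param detrend Remove each segment's mean before windowing (default TRUE).
#'
#' @return A tibble with columns `frequency` (Hz, strictly increasing bin
#'   centers) and `density` (one-sided PSD, signal units squared per Hz).
#' @examples
#' fs <- 64
#' x <- sin(2 * pi * 1.2 * seq(0, 180 - 1 / fs, by = 1 / fs))
#' psd <- welch_psd(x, fs)
#' psd$frequency[which.max(psd$density)]
#' @export
welch_psd <- function(x, fs, segment_s = 30, overlap = 0.5, pad = 2,
                      max_freq = 5.5, detrend = TRUE) {
  nseg <- round(segment_s * fs)
  if (length(x) < nseg) {
    abort("welch_psd: signal shorter than one Welch segment")
  }
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- blackman_harris(nseg)
  u <- sum(w^2)
  nfft <- nseg * pad
  acc <- numeric(nfft)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    if (detrend) seg <- seg - mean(seg)
    padded <- c(seg * w, numeric(nfft - nseg))
    acc <- acc + Mod(fft(padded))^2
  }
  p <- acc / (length(starts) * fs * u)
  nh <- floor(nfft / 2)
  freq <- (0:nh) / nfft * fs
  dens <- p[1:(nh + 1)]
  # fold negative frequencies into the one-sided density
  dens[2:(nh + if (nfft %% 2 == 0) 0 else 1)] <-
    2 * dens[2:(nh + if (nfft %% 2 == 0) 0 else 1)]
  out <- tibble(frequency = freq, density = dens)
  if (!is.null(max_freq)) out <- out[out$frequency <= max_freq, ]
  out
}

.steering_cache <- new.env(parent = emptyenv())

# MUSIC pseudospectrum over a bpm grid. x is assumed bandpassed to the pulse
# band; it is decimated to the low working rate before the eigendecomposition
# of the sample autocorrelation matrix.
music_pseudospectrum <- function(x, fs, range_bpm, order = 2L, corr_dim = 64L,
                                 grid_bpm = 0.25, music_fs = 8) {
  if (pop_sd(x) < 1e-10) abort("music: constant input, no spectral peak")
  if (fs > music_fs) {
    q <- fs / music_fs
    if (abs(q - round(q)) > 1e-9) {
      abort("music: sampling rate must be an integer multiple of the working rate")
    }
    x <- decimate_fast(x, round(q))
  } else {
    music_fs <- fs
  }
  m <- corr_dim
  n <- length(x)
  if (n < 2 * m) abort("music: window too short for the autocorrelation dimension")
  # Hankel data matrix of lagged snapshots (stride 2: adjacent snapshots are
  # nearly redundant and the autocorrelation estimate is unchanged)
  starts <- seq(1L, n - m + 1L, by = 2L)
  idx <- outer(starts - 1L, seq_len(m), `+`)
  X <- matrix(x[idx], nrow = length(starts))
  R <- crossprod(X) / nrow(X)
  ev <- eigen(R, symmetric = TRUE)
  bpm <- seq(range_bpm[1], range_bpm[2], by = grid_bpm)
  key <- paste(range_bpm[1], range_bpm[2], grid_bpm, m, music_fs)
  A <- .steering_cache[[key]]
  if (is.null(A)) {
    A <- exp(-2i * pi * outer(0:(m - 1L), bpm / 60 / music_fs))
    .steering_cache[[key]] <- A
  }
  # noise-subspace power via the signal-subspace complement:
  # |E_n^H a|^2 = m - |E_s^H a|^2 since the eigenbasis is orthonormal
  sig <- ev$vectors[, seq_len(order), drop = FALSE]
  proj <- crossprod(sig, A)
  denom <- m - colSums(Mod(proj)^2)
  tibble(bpm = bpm, pseudospectrum = 1 / pmax(denom, .Machine$double.eps))
}

#' MUSIC pulse-rate estimate
#'
#' Estimates the pulse rate of a PPG window as the location of the maximal
#' peak of the MUSIC pseudospectrum within a search range. MUSIC projects a
#' steering vector onto the noise subspace of the sample autocorrelation
#' matrix, giving much finer frequency resolution than an FFT of the same
#' window. The window must already be bandpass-filtered to the pulse band
#' (0.5-5 Hz); it is decimated to `music_fs` Hz internally.
#'
#' @param ppg_window Numeric PPG samples (typically the 3-minute epoch
#'   window).
#' @param fs Sampling rate of `ppg_window` in Hz.
#' @param range_bpm Length-2 search range in bpm (40-120 asleep, 40-160
#'   awake/resting).
#' @param order Signal-subspace dimension (default 2: the fundamental pair
#'   only, which keeps pulse harmonics in the noise subspace and prevents
#'   octave errors on very clean signals).
#' @param corr_dim Autocorrelation matrix dimension (default 64).
#' @param grid_bpm Pseudospectrum grid spacing in bpm (default 0.25).
#' @param music_fs Working sample rate after decimation (default 8 Hz; its
#'   Nyquist of 240 bpm covers the full awake search range).
#'
#' @return Pulse rate in bpm (a single number).
#' @export
music_pulse_rate <- function(ppg_window, fs, range_bpm, order = 2L,
                             corr_dim = 64L, grid_bpm = 0.25, music_fs = 8) {
  ps <- music_pseudospectrum(ppg_window, fs, range_bpm, order, corr_dim,
                             grid_bpm, music_fs)
  ps$bpm[which.max(ps$pseudospectrum)]
}
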