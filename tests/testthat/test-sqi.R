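# pulse-rate quality index ---------------------------------------------------

spec_tbl <- function(bpm, dens) {
  tibble::tibble(frequency = bpm / 60, density = dens)
}

test_that("a single above-threshold bin scores exactly 1.0", {
  bpm <- seq(30, 330, by = 1)
  dens <- rep(1e-6, length(bpm))
  dens[bpm == 72] <- 1
  expect_identical(compute_sqi_pr(spec_tbl(bpm, dens), c(40, 160)), 1.0)
})

test_that("uniform spread approaches the closed-form floor", {
  # all bins above threshold across [40, 160]: sd -> width/sqrt(12), so
  # the index -> 1 - 3/sqrt(12) = 0.134
  bpm <- seq(40, 160, by = 0.25)
  dens <- rep(1, length(bpm))
  # unique argmax at 60 bpm keeps the search ceiling at 160 bpm
  dens[bpm == 60] <- 1.01
  v <- compute_sqi_pr(spec_tbl(bpm, dens), c(40, 160))
  expect_equal(v, 1 - 3 * (120 / sqrt(12)) / 120, tolerance = 0.02)
})

test_that("two adjacent hot bins stay close to 1", {
  bpm <- seq(30, 330, by = 1)
  dens <- rep(1e-6, length(bpm))
  dens[bpm %in% c(72, 73)] <- c(1, 0.9)
  v <- compute_sqi_pr(spec_tbl(bpm, dens), c(40, 160))
  expect_lt(v, 1)
  expect_gt(v, 0.9)
})

test_that("the index never exceeds 1 and degrades monotonically with noise", {
  bpm <- seq(30, 330, by = 1)
  base <- rep(0, length(bpm))
  base[bpm == 80] <- 1
  set.seed(7)
  noise_shape <- runif(length(bpm))
  prev <- Inf
  for (amp in c(0, 0.05, 0.1, 0.2, 0.4, 0.8)) {
    v <- compute_sqi_pr(spec_tbl(bpm, base + amp * noise_shape), c(40, 160))
    expect_lte(v, 1.0)
    expect_lte(v, prev + 1e-12)
    prev <- v
  }
})

test_that("implementation matches the brute-force pseudocode oracle", {
  set.seed(123)
  for (k in 1:200) {
    ps <- random_spectrum()
    rng <- if (runif(1) < 0.5) c(40, 160) else c(40, 120)
    got <- compute_sqi_pr(ps, rng)
    want <- brute_sqi_pr(ps$frequency * 60, ps$density, rng[1], rng[2])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

# HRV quality index -----------------------------------------------------------

test_that("degenerate and forced values follow the definition", {
  freq <- seq(0, 5.5, by = 1 / 60)
  dens <- rep(0, length(freq))
  f0 <- 1.21   # band boundaries fall between grid points
  harm <- abs(freq - f0) <= 0.1 | abs(freq - 2 * f0) <= 0.1 |
    abs(freq - 3 * f0) <= 0.1
  dens[harm] <- 1
  ps <- tibble::tibble(frequency = freq, density = dens)
  # zero inharmonic power -> 0.0 as printed
  expect_identical(compute_sqi_hrv(ps, f0), 0.0)
  # config switch treats a line spectrum as perfect quality instead
  expect_gt(compute_sqi_hrv(ps, f0, clean_spectrum_passes = TRUE), 100)
  # equal harmonic and inharmonic sums -> log 2
  gap <- freq >= 0.5 * f0 + 0.1 & freq <= 3 * f0 - 0.1 & !harm
  dens2 <- dens
  dens2[gap] <- sum(dens[harm]) / sum(gap)
  ps2 <- tibble::tibble(frequency = freq, density = dens2)
  expect_equal(compute_sqi_hrv(ps2, f0), log(2), tolerance = 1e-9)
})

test_that("clean pulse spectra score high and noisy ones low", {
  fs <- 64
  bt <- seq(0, 200, by = 1)
  clean <- synthesize_ppg(bt, 180, fs, noise_sd = 0.02)
  ps <- welch_psd(bandpass(clean, fs, 0.5, 5), fs)
  expect_gt(compute_sqi_hrv(ps, 1.0), 1.0)
  set.seed(2)
  noisy <- clean + 3 * bandpass(rnorm(length(clean)), fs, 0.5, 5) /
    sd(bandpass(rnorm(length(clean)), fs, 0.5, 5))
  ps2 <- welch_psd(bandpass(noisy, fs, 0.5, 5), fs)
  expect_lt(compute_sqi_hrv(ps2, 1.0), 1.0)
})

test_that("the index is scale-invariant and monotone in gap power", {
  set.seed(11)
  ps <- random_spectrum()
  v <- compute_sqi_hrv(ps, 1.3)
  for (c in c(1e-6, 0.37, 42, 1e8)) {
    ps2 <- ps
    ps2$density <- ps2$density * c
    expect_equal(compute_sqi_hrv(ps2, 1.3), v, tolerance = 1e-12)
  }
  # adding power strictly inside a gap band strictly decreases the index
  gap_bin <- which.min(abs(ps$frequency - 1.5 * 1.3))
  prev <- v
  for (extra in c(1, 5, 25)) {
    ps3 <- ps
    ps3$density[gap_bin] <- ps3$density[gap_bin] + extra
    v3 <- compute_sqi_hrv(ps3, 1.3)
    expect_lt(v3, prev)
    prev <- v3
  }
})

test_that("implementation matches the brute-force band-sum oracle", {
  set.seed(321)
  for (k in 1:200) {
    ps <- random_spectrum()
    f0 <- runif(1, 0.8, 2.2)
    got <- compute_sqi_hrv(ps, f0)
    want <- brute_sqi_hrv(ps$frequency, ps$density, f0, 0.1)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("invalid fundamentals and margins are rejected", {
  ps <- random_spectrum()
  expect_error(compute_sqi_hrv(ps, 0.5), "40-240")
  expect_error(compute_sqi_hrv(ps, 1.0, f_margin = 0.3), "margin")
})
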