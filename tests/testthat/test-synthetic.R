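test_that("zero band powers give an exactly constant RR series", {
  rr <- generate_rr(600, mean_hr = 75, lf_power = 0, hf_power = 0, seed = 1)
  expect_equal(rr$rr_ms, rep(60000 / 75, nrow(rr)), tolerance = 1e-9)
})

test_that("generate_rr is deterministic under a fixed seed", {
  a <- generate_rr(600, 60, 300, 500, seed = 9)
  b <- generate_rr(600, 60, 300, 500, seed = 9)
  expect_identical(a$rr_ms, b$rr_ms)
  c <- generate_rr(600, 60, 300, 500, seed = 10)
  expect_false(identical(a$rr_ms, c$rr_ms))
})

test_that("requested band powers are realised within 20%", {
  rr <- generate_rr(7200, 60, lf_power = 400, hf_power = 200, seed = 3)
  bt <- attr(rr, "beat_times")
  fd <- frequency_domain_hrv(bt, rr$rr_ms, segment_s = 300)
  expect_lt(abs(fd$lf - 400) / 400, 0.2)
  expect_lt(abs(fd$hf - 200) / 200, 0.2)
  expect_lt(abs(fd$lf_hf - 2.0) / 2.0, 0.2)
})

test_that("non-physiological inputs are rejected", {
  expect_error(generate_rr(60, mean_hr = 30), "40-160")
  expect_error(generate_rr(60, 60, lf_power = -1), ">= 0")
})

test_that("clean PPG has one peak per ground-truth beat", {
  bt <- seq(0, 200, by = 60 / 72)
  ppg <- synthesize_ppg(bt, 180, 64, noise_sd = 0)
  pp <- preprocess_ppg(ppg, 64, 72 / 60)
  pk <- detect_peaks(pp$signal, pp$fs, 72 / 60)
  expect_lte(abs(length(pk) - sum(bt < 180)), 1)
})

test_that("scheduled sleep has lower acceleration activity than wake", {
  out <- synthesize_session(
    list(duration_min = 240L, sleep_onset_min = 120L, tst_min = 80L,
         pre_rest_min = 60L, post_rest_min = 30L, n_awakenings = 0L),
    seed = 4
  )
  act <- activity_amplitude(out$session$accel, 32)
  tr <- out$truth
  asleep <- tr$state == "sleep"
  expect_lt(mean(act[asleep]), mean(act[!asleep]))
})

test_that("artifact bursts are motion-locked", {
  out <- synthesize_session(
    list(duration_min = 200L, sleep_onset_min = 100L, tst_min = 60L,
         pre_rest_min = 60L, post_rest_min = 30L, n_awakenings = 0L,
         artifact_rate_sleep = 0.8),
    seed = 5
  )
  tr <- out$truth
  mag <- sqrt(rowSums(out$session$accel^2))
  mag <- mag - stats::median(mag)
  sec_rms <- sqrt(colMeans(matrix(mag^2, nrow = 32)))
  # within sleep, artifact seconds carry injected movement and quiet
  # seconds carry only sensor noise
  sleep_sec <- rep(tr$minute_class, each = 60) == "sleep"
  expect_gt(mean(sec_rms[sleep_sec & tr$artifact_mask]),
            3 * mean(sec_rms[sleep_sec & !tr$artifact_mask]))
})

test_that("session synthesis is deterministic and schedule-checked", {
  p <- list(duration_min = 120L, sleep_onset_min = 60L, tst_min = 30L,
            pre_rest_min = 30L, post_rest_min = 20L, n_awakenings = 0L)
  a <- synthesize_session(p, seed = 2)
  b <- synthesize_session(p, seed = 2)
  expect_identical(a$session$ppg, b$session$ppg)
  expect_identical(a$truth$beat_times, b$truth$beat_times)
  expect_error(
    synthesize_session(list(duration_min = 100L, sleep_onset_min = 60L,
                            tst_min = 60L), seed = 1),
    "schedule"
  )
})

test_that("cohort generation applies the group effect to sleep HRV", {
  co <- synthesize_cohort(4, 4, effect_params = list(hf_ratio = 0.5),
                          seed = 3,
                          session_params = list(duration_min = 240L,
                                                sleep_onset_min = 120L,
                                                tst_min = 90L,
                                                pre_rest_min = 60L,
                                                post_rest_min = 20L))
  hf <- vapply(co$truth, function(t) t$params$hf_sleep, numeric(1))
  ratio <- mean(hf[co$label == "mdd"]) / mean(hf[co$label == "healthy"])
  # per-participant lognormal variation around the 0.5 construction
  expect_lt(ratio, 0.9)
  co2 <- synthesize_cohort(4, 4, effect_params = list(hf_ratio = 0.5),
                           seed = 3,
                           session_params = list(duration_min = 240L,
                                                 sleep_onset_min = 120L,
                                                 tst_min = 90L,
                                                 pre_rest_min = 60L,
                                                 post_rest_min = 20L))
  expect_identical(co$truth[[1]]$beat_times, co2$truth[[1]]$beat_times)
})

test_that("an identity effect leaves the two groups exchangeable", {
  co <- synthesize_cohort(
    8, 8, effect_params = list(hf_ratio = 1, lf_ratio = 1, hr_shift = 0),
    seed = 6,
    session_params = list(duration_min = 240L, sleep_onset_min = 120L,
                          tst_min = 90L, pre_rest_min = 60L,
                          post_rest_min = 20L)
  )
  hf <- vapply(co$truth, function(t) t$params$hf_sleep, numeric(1))
  p <- stats::wilcox.test(hf[co$label == "mdd"],
                          hf[co$label == "healthy"])$p.value
  expect_gt(p, 0.01)
})
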