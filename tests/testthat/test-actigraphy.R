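test_that("gravity-only acceleration yields zero activity", {
  acc <- cbind(0, 0, rep(64, 32 * 300))
  act <- activity_amplitude(acc, 32)
  expect_equal(length(act), 5L)
  expect_true(all(act < 1e-6))
})

test_that("a single movement burst registers only in its own epoch", {
  n <- 32 * 300
  t <- seq(0, 300 - 1 / 32, by = 1 / 32)
  burst <- ifelse(t >= 150 & t < 156, 10 * sin(2 * pi * 1 * t), 0)
  acc <- cbind(burst, 0, 64)
  act <- activity_amplitude(acc, 32)
  expect_gt(act[3], 10 * act[1])
  expect_gt(act[3], 10 * act[5])
})

test_that("stream shorter than one epoch is rejected", {
  expect_error(activity_amplitude(matrix(0, 100, 3), 32), "epoch")
})

test_that("scoring matches a hand-computed weighted sum", {
  act <- c(0.3, 0.2, 0.8, 0.1, 0.4)
  w <- rep(1, 3)   # unit weights over +/-1 epoch
  states <- score_sleep_wake(act, weights = w, threshold = 1.0)
  # manual sums with zero padding: 0.5, 1.3, 1.1, 1.3, 0.5
  expect_equal(states, c("sleep", "awake", "awake", "awake", "sleep"))
})

test_that("all-quiet scores sleep and all-active scores awake", {
  expect_true(all(score_sleep_wake(rep(0, 50)) == "sleep"))
  expect_true(all(score_sleep_wake(rep(1e5, 50)) == "awake"))
})

# --- rescoring rules on constructed sequences -------------------------------

mk_states <- function(spec) {
  # spec: list of c(state, minutes)
  unlist(lapply(spec, function(p) rep(p[[1]], p[[2]])))
}

test_that("an uninterrupted main sleep block is left unchanged", {
  states <- mk_states(list(c("awake", 300), c("sleep", 480), c("awake", 300)))
  act <- ifelse(states == "sleep", 1, 500)
  seg <- rescore_sleep(states, act)
  expect_equal(seg$tst, 480L)
  expect_equal(seg$onset, 300L)
  expect_equal(seg$wake, 780L)
  expect_identical(seg$states, states)
})

test_that("only the largest connected sleep segment is retained", {
  # 100 min block, 150 min wake gap (> 100), 400 min block
  states <- mk_states(list(c("awake", 100), c("sleep", 100), c("awake", 150),
                           c("sleep", 400), c("awake", 100)))
  act <- ifelse(states == "sleep", 1, 200)
  seg <- rescore_sleep(states, act)
  expect_equal(seg$tst, 400L)
  expect_equal(seg$onset, 350L)
  expect_true(all(seg$states[101:200] == "awake"))
})

test_that("a short detached fragment near the main block is removed", {
  # 30 min fragment, 180 min gap, 7 h block: outside the core and < 60 min
  states <- mk_states(list(c("awake", 60), c("sleep", 30), c("awake", 180),
                           c("sleep", 420), c("awake", 60)))
  act <- ifelse(states == "sleep", 1, 200)
  seg <- rescore_sleep(states, act)
  expect_true(all(seg$states[61:90] == "awake"))
  expect_equal(seg$tst, 420L)
})

test_that("short sleep runs bracketed by high activity become awake", {
  # the 80-min wake gap keeps both blocks in one connected segment, so only
  # the bracketing rule can remove the 60-min run
  states <- mk_states(list(c("awake", 200), c("sleep", 60), c("awake", 80),
                           c("sleep", 400), c("awake", 100)))
  act <- ifelse(states == "sleep", 1, 50)
  act[200] <- 1e4   # awake epoch immediately before the run
  act[261] <- 1e4   # awake epoch immediately after it
  seg <- rescore_sleep(states, act)
  expect_true(all(seg$states[201:260] == "awake"))
  expect_equal(seg$tst, 400L)
  # without the high-activity flanks the run survives inside the segment
  act2 <- ifelse(states == "sleep", 1, 50)
  seg2 <- rescore_sleep(states, act2)
  expect_equal(seg2$tst, 460L)
})

test_that("rescoring is idempotent and never converts awake to sleep", {
  set.seed(42)
  for (k in 1:25) {
    n <- 400
    states <- ifelse(runif(n) < 0.45, "sleep", "awake")
    act <- ifelse(states == "sleep", runif(n, 0, 30), runif(n, 50, 1000))
    seg1 <- rescore_sleep(states, act)
    seg2 <- rescore_sleep(seg1$states, act)
    expect_identical(seg2$states, seg1$states)
    expect_equal(seg2$tst, seg1$tst)
    # conservative: sleep may only shrink
    expect_true(all(states[seg1$states == "sleep"] == "sleep"))
  }
})

test_that("a record with no surviving sleep yields zero TST", {
  states <- rep("awake", 200)
  seg <- rescore_sleep(states, runif(200, 100, 500))
  expect_equal(seg$tst, 0L)
  expect_true(is.na(seg$onset))
})

# --- phase arithmetic -------------------------------------------------------

mk_seg <- function(onset, wake, tst = wake - onset) {
  structure(list(states = NULL, onset = onset, wake = wake, tst = tst),
            class = "wristhrv_segmentation")
}

test_that("phase bounds follow the stated arithmetic", {
  ph <- define_phases(mk_seg(500L, 950L), n_epochs = 1440L)
  expect_equal(ph$start, c(410L, 500L, 590L, 680L, 950L))
  expect_equal(ph$end, c(500L, 590L, 680L, 950L, 1040L))
  expect_equal(ph$end[4] - ph$start[4], 270L)
})

test_that("the 270-minute sleep requirement is enforced exactly", {
  expect_error(define_phases(mk_seg(500L, 950L, tst = 269L), 1440L),
               class = "wristhrv_excluded")
  expect_silent(define_phases(mk_seg(500L, 950L, tst = 270L), 1440L))
})

test_that("a minimal sleep segment leaves a 90-epoch P4", {
  ph <- define_phases(mk_seg(500L, 770L), n_epochs = 1440L)
  expect_equal(ph$start[4], 680L)
  expect_equal(ph$end[4], 770L)
})

test_that("insufficient margins truncate P1/P5 with a warning", {
  expect_warning(ph <- define_phases(mk_seg(50L, 400L), 1440L), "P1")
  expect_equal(ph$start[1], 0L)
  expect_warning(ph2 <- define_phases(mk_seg(500L, 1400L), 1440L), "P5")
  expect_equal(ph2$end[5], 1440L)
})
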