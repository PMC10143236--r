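test_that("VIF matches closed forms on constructed designs", {
  set.seed(1)
  n <- 100
  # orthonormalized columns -> VIF exactly 1
  raw <- matrix(rnorm(n * 3), n)
  q <- qr.Q(qr(cbind(1, raw)))[, 2:4]
  vs <- vif_screen(as.data.frame(q))
  expect_equal(vs$vif$vif, rep(1, 3), tolerance = 1e-9)
  # duplicated column -> infinite VIF, flagged
  dup <- data.frame(a = raw[, 1], b = raw[, 1], c = raw[, 2])
  vs2 <- vif_screen(dup)
  expect_true(is.infinite(vs2$vif$vif[1]))
  expect_false(vs2$vif$retained[1])
  # empirical correlation exactly 0.95 -> VIF = 1/(1-0.95^2)
  x1 <- scale(raw[, 1])[, 1]
  resid <- stats::residuals(lm(raw[, 2] ~ x1))
  x2 <- 0.95 * x1 + sqrt(1 - 0.95^2) * scale(resid)[, 1] *
    sqrt(var(x1) / var(scale(resid)[, 1]))
  vs3 <- vif_screen(data.frame(x1, x2))
  expect_equal(vs3$vif$vif, rep(1 / (1 - 0.95^2), 2), tolerance = 1e-6)
})

test_that("the screener fits separable data and shrinks with the penalty", {
  x <- data.frame(f = c(rnorm(20, -3), rnorm(20, 3)))
  y <- rep(c("healthy", "mdd"), each = 20)
  fit <- fit_screener(x, y, C = 1e6)
  expect_equal(mean(predict(fit, x, type = "class") == y), 1)
  # C -> 0: coefficients -> 0, predictions -> majority class probability
  fit0 <- fit_screener(x, y, C = 1e-8)
  expect_lt(abs(tidy(fit0)$estimate[2]), 1e-3)
  expect_true(all(abs(predict(fit0, x, type = "prob") - 0.5) < 0.01))
  expect_error(fit_screener(x, rep("mdd", 40)), "single class")
})

test_that("coefficients recover a known boundary direction", {
  set.seed(3)
  n <- 4000
  x <- matrix(rnorm(2 * n), ncol = 2)
  # true boundary normal (2, 1)/sqrt(5)
  p <- plogis(2 * x[, 1] + 1 * x[, 2])
  y <- ifelse(runif(n) < p, "mdd", "healthy")
  fit <- fit_screener(as.data.frame(x), y, C = 100)
  b <- tidy(fit)$estimate[2:3]
  ang <- acos(sum(b * c(2, 1)) / sqrt(sum(b^2) * 5)) * 180 / pi
  expect_lt(ang, 10)
})

test_that("metrics match brute-force confusion counts on random pairs", {
  set.seed(9)
  for (k in 1:100) {
    n <- sample(20:60, 1)
    truth <- runif(n) < runif(1, 0.2, 0.8)
    pred <- runif(n) < runif(1, 0.2, 0.8)
    got <- classification_metrics(truth, pred)
    want <- brute_metrics(truth, pred)
    for (m in names(want)) expect_equal(got[[m]], want[[m]], tolerance = 1e-12)
    if (!anyNA(c(got$precision, got$sensitivity)) &&
        got$precision + got$sensitivity > 0) {
      expect_equal(got$f1,
                   2 * got$precision * got$sensitivity /
                     (got$precision + got$sensitivity),
                   tolerance = 1e-12)
    }
  }
})

test_that("cross-validation is deterministic under a fixed seed", {
  set.seed(4)
  x <- data.frame(a = rnorm(30), b = rnorm(30))
  y <- rep(c("healthy", "mdd"), 15)
  r1 <- cross_validate(x, y, C_grid = c(0.1, 1), n_repeats = 3, seed = 7)
  r2 <- cross_validate(x, y, C_grid = c(0.1, 1), n_repeats = 3, seed = 7)
  expect_equal(r1$summary, r2$summary)
  expect_equal(r1$scores$mean_logit, r2$scores$mean_logit)
})

test_that("test-fold rows never influence training", {
  set.seed(6)
  x <- data.frame(a = rnorm(20), b = rnorm(20))
  y <- rep(c("healthy", "mdd"), 10)
  base <- cross_validate(x, y, C_grid = 1, n_repeats = 1, n_folds = 2,
                         seed = 11)
  x2 <- x
  x2[3, ] <- x2[3, ] * 1000          # wildly rescale one row
  mod <- cross_validate(x2, y, C_grid = 1, n_repeats = 1, n_folds = 2,
                        seed = 11)
  changed <- abs(base$scores$mean_logit - mod$scores$mean_logit) > 1e-8
  # rows sharing a test fold with row 3 see a model trained without it and
  # keep identical predictions; only the other fold (and row 3) may change
  expect_lte(sum(changed), 11)
  expect_false(changed[which(!changed)[1]])
})

test_that("fold counts shrink with a warning for small classes", {
  x <- data.frame(a = rnorm(12))
  y <- rep(c("healthy", "mdd"), 6)
  expect_warning(
    r <- cross_validate(x, y, C_grid = 1, n_repeats = 2, seed = 1),
    "folds"
  )
  expect_equal(r$n_folds, 6)
})

test_that("pure-noise features give chance-level screening", {
  set.seed(10)
  x <- as.data.frame(matrix(rnorm(40 * 5), 40))
  y <- rep(c("healthy", "mdd"), each = 20)
  r <- cross_validate(x, y, C_grid = c(0.01, 1), n_repeats = 20, seed = 2)
  acc <- r$summary$mean[r$summary$metric == "accuracy"]
  mcc <- r$summary$mean[r$summary$metric == "mcc"]
  expect_lt(abs(acc - 0.5), 0.15)
  expect_lt(abs(mcc), 0.2)
})
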