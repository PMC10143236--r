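# L2-regularized logistic screening with repeated stratified CV.

#' Variance inflation factors with a retention screen
#'
#' Computes the VIF of every feature by regressing it on all others with
#' ordinary least squares (`VIF = 1 / (1 - R^2)`). Exactly collinear
#' features get an infinite VIF. Features at or above the cutoff are
#' flagged for removal.
#'
#' @param features Data frame / tibble of numeric feature columns.
#' @param cutoff Retention bound (default 10).
#' @return A list with `vif` (tibble `feature`, `vif`, `retained`) and
#'   `retained` (character vector of feature names below the cutoff).
#' @export
vif_screen <- function(features, cutoff = 10) {
  x <- as.data.frame(features)
  stopifnot(ncol(x) >= 2, nrow(x) > ncol(x))
  vifs <- vapply(seq_along(x), function(j) {
    fit <- lm(x[[j]] ~ ., data = x[-j])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tab <- tibble(feature = names(x), vif = vifs, retained = vifs < cutoff)
  list(vif = tab, retained = tab$feature[tab$retained])
}

# glmnet requires at least two predictor columns; a constant zero column
# changes nothing (its coefficient is exactly zero)
pad_single_column <- function(x) {
  if (ncol(x) == 1) cbind(x, .pad = 0) else x
}

# z-score scaler learned on training rows only
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[sdev == 0] <- 1
  list(mu = mu, sd = sdev)
}
apply_scaler <- function(x, sc) sweep(sweep(x, 2, sc$mu), 2, sc$sd, "/")

#' Fit the L2 logistic screener
#'
#' Standardizes features (z-score, parameters learned from the supplied
#' rows) and fits a logistic regression with an L2 penalty of strength `C`
#' (larger `C` = weaker penalty, as in the common machine-learning
#' convention; the ridge path is solved by glmnet with
#' `lambda = 1 / (n * C)`).
#'
#' @param features Numeric feature data frame or matrix.
#' @param labels Factor or character vector with two classes; the positive
#'   class is `positive`.
#' @param C Inverse regularization strength.
#' @param positive Positive-class label (default `"mdd"`).
#' @return An object of class `wristhrv_screener` with the scaler, glmnet
#'   fit, `C` and class labels.
#' @export
fit_screener <- function(features, labels, C = 1, positive = "mdd") {
  x <- pad_single_column(as.matrix(features))
  y <- as.integer(labels == positive)
  if (length(unique(y)) < 2) abort("fit_screener: a single class was supplied")
  sc <- fit_scaler(x)
  xs <- apply_scaler(x, sc)
  fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = 0,
                        lambda = 1 / (nrow(x) * C), standardize = FALSE,
                        thresh = 1e-10)
  negative <- setdiff(unique(as.character(labels)), positive)[1]
  structure(list(scaler = sc, fit = fit, C = C, positive = positive,
                 negative = negative, features = colnames(x)),
            class = "wristhrv_screener")
}

#' @rdname fit_screener
#' @param object A `wristhrv_screener`.
#' @param newdata Feature rows to score.
#' @param type `"logit"`, `"prob"` or `"class"`.
#' @param ... Unused.
#' @export
predict.wristhrv_screener <- function(object, newdata,
                                      type = c("prob", "logit", "class"),
                                      ...) {
  type <- match.arg(type)
  xs <- apply_scaler(pad_single_column(as.matrix(newdata)), object$scaler)
  logit <- as.numeric(predict(object$fit, xs, type = "link"))
  switch(type,
    logit = logit,
    prob = 1 / (1 + exp(-logit)),
    class = ifelse(logit > 0, object$positive, object$negative)
  )
}

#' @rdname fit_screener
#' @param x A `wristhrv_screener`.
#' @exportS3Method generics::tidy
tidy.wristhrv_screener <- function(x, ...) {
  cf <- as.matrix(coef(x$fit))
  tibble(term = rownames(cf), estimate = cf[, 1])
}

#' Binary classification metrics from labels and predictions
#'
#' @param truth Logical or 0/1 vector of true positives.
#' @param pred Logical or 0/1 vector of predicted positives.
#' @return A named list: `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `npv`, `f1`, `mcc`. Ratios with zero denominators are
#'   `NA`; an MCC with any zero marginal is 0 by convention.
#' @export
classification_metrics <- function(truth, pred) {
  truth <- as.logical(truth); pred <- as.logical(pred)
  tp <- sum(truth & pred); tn <- sum(!truth & !pred)
  fp <- sum(!truth & pred); fn <- sum(truth & !pred)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  prec <- safe(tp, tp + fp)
  sens <- safe(tp, tp + fn)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    accuracy = (tp + tn) / length(truth),
    sensitivity = sens,
    specificity = safe(tn, tn + fp),
    precision = prec,
    npv = safe(tn, tn + fn),
    f1 = if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn),
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  )
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin to folds
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# inner grid search on a training subset: mean inner-CV accuracy per C
select_C <- function(x, y, C_grid, inner_k = 5) {
  lam <- 1 / (nrow(x) * C_grid)
  fold <- stratified_folds(y, inner_k)
  correct <- matrix(0, inner_k, length(C_grid))
  counts <- integer(inner_k)
  for (f in seq_len(inner_k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2 || sum(!tr) == 0) next
    sc <- fit_scaler(x[tr, , drop = FALSE])
    fit <- glmnet::glmnet(apply_scaler(x[tr, , drop = FALSE], sc), y[tr],
                          family = "binomial", alpha = 0,
                          lambda = sort(lam, decreasing = TRUE),
                          standardize = FALSE)
    pr <- predict(fit, apply_scaler(x[!tr, , drop = FALSE], sc),
                  type = "response", s = lam, exact = FALSE)
    correct[f, ] <- colSums((pr > 0.5) == (y[!tr] == 1))
    counts[f] <- sum(!tr)
  }
  acc <- colSums(correct) / sum(counts)
  # ties favour the stronger penalty (smaller C)
  C_grid[order(-acc, C_grid)[1]]
}

#' Repeated stratified cross-validation of the screener
#'
#' Runs `n_repeats` rounds of stratified `n_folds`-fold cross-validation
#' with reshuffled folds. The L2 strength `C` is grid-searched inside every
#' training fold (nested inner CV), the scaler is learned from training
#' rows only, and per-repeat metrics are computed from the pooled
#' out-of-fold predictions at a 0.5 probability threshold; AUC is the
#' pooled out-of-fold ROC per repeat. Summary means carry normal 95%
#' confidence intervals over repeats.
#'
#' @param features Numeric feature data frame (no missing cells).
#' @param labels Two-class label vector.
#' @param C_grid Grid of inverse regularization strengths (default
#'   logarithmic `10^-3 .. 10^3`, 13 points).
#' @param n_repeats CV repetitions (default 100).
#' @param n_folds Folds (default 10; reduced with a warning when a class has
#'   fewer members).
#' @param seed Integer seed controlling every reshuffle.
#' @param positive Positive-class label (default `"mdd"`).
#' @return An object of class `wristhrv_screening`: list with `summary`
#'   (tibble of metric means and CIs), `per_repeat` (tibble of per-repeat
#'   metrics), `scores` (per-participant mean out-of-fold logit),
#'   `chosen_C` (table of selected strengths), `n_folds`, `n_repeats`,
#'   `seed`.
#' @export
cross_validate <- function(features, labels, C_grid = 10^seq(-3, 3, by = 0.5),
                           n_repeats = 100, n_folds = 10, seed = 1,
                           positive = "mdd") {
  x <- pad_single_column(as.matrix(features))
  y <- as.integer(labels == positive)
  stopifnot(nrow(x) == length(y), !anyNA(x))
  min_class <- min(table(y))
  if (min_class < n_folds) {
    warn(sprintf("smallest class has %d members; using %d folds", min_class,
                 min_class))
    n_folds <- min_class
  }
  set.seed(seed)
  reps <- vector("list", n_repeats)
  score_sum <- numeric(nrow(x))
  chosen <- character(0)
  for (r in seq_len(n_repeats)) {
    fold <- stratified_folds(y, n_folds)
    prob <- numeric(nrow(x))
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      C_best <- if (length(C_grid) > 1) {
        select_C(x[tr, , drop = FALSE], y[tr], C_grid)
      } else C_grid
      chosen <- c(chosen, format(C_best))
      sc <- fit_scaler(x[tr, , drop = FALSE])
      fit <- glmnet::glmnet(apply_scaler(x[tr, , drop = FALSE], sc), y[tr],
                            family = "binomial", alpha = 0,
                            lambda = 1 / (sum(tr) * C_best),
                            standardize = FALSE, thresh = 1e-10)
      prob[!tr] <- as.numeric(predict(fit,
                                      apply_scaler(x[!tr, , drop = FALSE], sc),
                                      type = "response"))
    }
    m <- classification_metrics(y == 1, prob > 0.5)
    m$auc <- as.numeric(pROC::auc(pROC::roc(y, prob, quiet = TRUE,
                                            direction = "<", levels = c(0, 1))))
    reps[[r]] <- as_tibble(m)
    score_sum <- score_sum + log(pmax(prob, 1e-12) / pmax(1 - prob, 1e-12))
  }
  per_repeat <- bind_rows(reps, .id = "repeat_id")
  metrics <- setdiff(names(per_repeat), "repeat_id")
  summary <- purrr::map_dfr(metrics, function(mn) {
    v <- per_repeat[[mn]]
    tibble(metric = mn, mean = mean(v, na.rm = TRUE),
           ci_lo = mean(v, na.rm = TRUE) - 1.96 * sd(v, na.rm = TRUE),
           ci_hi = mean(v, na.rm = TRUE) + 1.96 * sd(v, na.rm = TRUE))
  })
  structure(
    list(summary = summary, per_repeat = per_repeat,
         scores = tibble(row = seq_len(nrow(x)), label = labels,
                         mean_logit = score_sum / n_repeats),
         chosen_C = sort(table(chosen), decreasing = TRUE),
         n_folds = n_folds, n_repeats = n_repeats, seed = seed),
    class = "wristhrv_screening"
  )
}

#' @export
print.wristhrv_screening <- function(x, ...) {
  cat(sprintf("<wristhrv_screening>  %d x %d-fold CV\n", x$n_repeats,
              x$n_folds))
  print(x$summary)
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `wristhrv_screening`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.wristhrv_screening <- function(x, ...) x$summary

#' @rdname cross_validate
#' @exportS3Method generics::glance
glance.wristhrv_screening <- function(x, ...) {
  wide <- setNames(as.list(x$summary$mean), x$summary$metric)
  as_tibble(c(wide, list(n_repeats = x$n_repeats, n_folds = x$n_folds)))
}

#' Compare quality-gating conditions on a cohort
#'
#' Processes every session of a synthetic cohort once with all quantities
#' computed and gates only recorded, then builds the screening feature
#' matrix under four gating conditions (gates applied everywhere, nowhere,
#' awake phases only, sleep phases only) and cross-validates each under
#' identical seeds. Participants excluded under any condition (an empty
#' phase) are dropped from all four so the CV cohorts are identical.
#'
#' @param cohort Cohort tibble from [synthesize_cohort()] (columns `id`,
#'   `label`, `session`), or a list of analyses from a previous call (see
#'   `analyses`).
#' @param config A [wristhrv_config()].
#' @param conditions Conditions to evaluate.
#' @param n_repeats,C_grid,seed Passed to [cross_validate()].
#' @param analyses Optional pre-computed list of `wristhrv_analysis` objects
#'   (with `apply_gates = FALSE`), to avoid re-processing.
#' @return A list with `reports` (named list of `wristhrv_screening`),
#'   `summary` (tibble: one row per condition with mean metrics),
#'   `features` (named list of feature tibbles), `analyses`.
#' @export
compare_sqi_conditions <- function(cohort, config = wristhrv_config(),
                                   conditions = c("with", "without",
                                                  "awake_only", "sleep_only"),
                                   n_repeats = 100,
                                   C_grid = 10^seq(-3, 3, by = 0.5),
                                   seed = 1, analyses = NULL) {
  if (is.null(analyses)) {
    analyses <- purrr::map(cohort$session, analyze_session, config = config,
                           apply_gates = FALSE)
  }
  feat_tabs <- purrr::map(conditions, function(cond) {
    rows <- purrr::map(seq_along(analyses), function(i) {
      a <- analyses[[i]]
      if (is.null(a$phases)) return(NULL)
      pm <- phase_means(a$epochs, a$phases, config, cond)
      if (pm$excluded) return(NULL)
      dplyr::bind_cols(tibble(id = cohort$id[i], label = cohort$label[i]),
                       pm$features)
    })
    bind_rows(rows)
  })
  names(feat_tabs) <- conditions
  keep <- Reduce(intersect, purrr::map(feat_tabs, "id"))
  feat_tabs <- purrr::map(feat_tabs, ~ .x[.x$id %in% keep, ])
  reports <- purrr::map(feat_tabs, function(ft) {
    cross_validate(ft[, setdiff(names(ft), c("id", "label"))], ft$label,
                   C_grid = C_grid, n_repeats = n_repeats, seed = seed)
  })
  summary <- purrr::map_dfr(conditions, function(cond) {
    dplyr::bind_cols(tibble(condition = cond), glance(reports[[cond]]))
  })
  list(reports = reports, summary = summary, features = feat_tabs,
       analyses = analyses)
}
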