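# Splits, confusion metrics, AUC machinery and fold aggregation.

test_that("stratified holdout uses the floor rule and reproduces the 11/12/81 composition", {
  ids <- sprintf("x%03d", 1:262)
  strata <- rep(c("case", "benign", "healthy"), c(28, 30, 204))
  plan <- stratified_holdout(ids, strata, test_frac = 0.40, seed = 7)
  comp <- table(plan$strata[plan$test_ids])
  expect_identical(as.integer(comp[c("case", "benign", "healthy")]),
                   c(11L, 12L, 81L))
  expect_length(intersect(plan$test_ids, plan$train_ids), 0)
  # determinism and input-order invariance
  plan2 <- stratified_holdout(rev(ids), rev(strata), test_frac = 0.40, seed = 7)
  expect_identical(plan$test_ids, plan2$test_ids)
  # frac 0 -> empty test set; bad frac -> error
  expect_length(stratified_holdout(ids, strata, 0, seed = 1)$test_ids, 0)
  expect_error(stratified_holdout(ids, strata, 1, seed = 1), "test_frac")
})

test_that("stratified k-fold partitions with per-stratum balance", {
  ids <- sprintf("s%02d", 1:50)
  strata <- rep(c("pos", "neg"), c(10, 40))
  folds <- stratified_kfold(ids, strata, k = 5, seed = 3)
  val_sets <- lapply(folds, `[[`, "val_ids")
  # exact divisibility: every fold validates on 2 pos / 8 neg
  for (v in val_sets) {
    expect_identical(sum(v %in% ids[1:10]), 2L)
    expect_length(v, 10)
  }
  # partition: union = cohort, pairwise disjoint
  expect_setequal(unlist(val_sets), ids)
  expect_identical(anyDuplicated(unlist(val_sets)), 0L)
  # train/val complementary within each fold
  for (f in folds) expect_setequal(c(f$train_ids, f$val_ids), ids)
  # determinism
  expect_identical(stratified_kfold(ids, strata, k = 5, seed = 3), folds)
  expect_error(stratified_kfold(ids, strata, k = 1, seed = 1), "k must be")
  # tiny stratum triggers merge warning
  expect_warning(stratified_kfold(ids, rep(c("a", "b"), c(3, 47)), k = 5, seed = 1),
                 "merging")
})

test_that("confusion metrics match hand counts and the printed worked examples", {
  # TP=3 FP=1 FN=1 TN=5
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  s <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.3, 0.2, 0.1, 0.1, 0.1)
  cm <- confusion_metrics(y, s)
  expect_identical(c(cm$tp, cm$fp, cm$fn, cm$tn), c(3L, 1L, 1L, 5L))
  expect_equal(cm$sensitivity, 0.75)
  expect_equal(cm$specificity, 5 / 6, tolerance = 1e-4)
  expect_equal(cm$balanced_accuracy, (0.75 + 5 / 6) / 2)
  expect_equal(cm$precision, 0.75)
  expect_identical(cm$recall, cm$sensitivity)
  # sarcoma-style arithmetic: sens 0.94, spec 0.79 -> balanced accuracy 87%
  expect_identical(percent_round((0.94 + 0.79) / 2), 87)
  # perfect classifier
  cp <- confusion_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2))
  expect_true(all(unlist(cp[c("sensitivity", "specificity", "balanced_accuracy",
                              "precision", "recall")]) == 1))
  expect_error(confusion_metrics(y, s * 2), "\\[0, 1\\]")
  expect_error(confusion_metrics(rep(1, 4), runif(4)), "both classes")
})

test_that("balanced accuracy and implied precision are internally consistent", {
  set.seed(12)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.4))
    s <- round(runif(n), 2)
    cm <- confusion_metrics(y, s)
    expect_identical(cm$balanced_accuracy, (cm$sensitivity + cm$specificity) / 2)
    if (cm$tp + cm$fp > 0) {
      expect_equal(cm$precision,
                   implied_precision(cm$sensitivity, cm$specificity,
                                     sum(y == 1), sum(y == 0)),
                   tolerance = 1e-12)
    }
  }
})

test_that("specificity at full sensitivity matches brute force over thresholds", {
  expect_equal(specificity_at_full_sensitivity(
    c(1, 1, 0, 0, 0, 0), c(0.6, 0.2, 0.1, 0.3, 0.5, 0.7)), 0.25)
  # perfectly separated
  expect_equal(specificity_at_full_sensitivity(
    c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  # a case holds the global minimum -> 0
  expect_equal(specificity_at_full_sensitivity(
    c(1, 0, 0), c(0.05, 0.4, 0.9)), 0)
  # brute force: best specificity among thresholds with sensitivity 1
  set.seed(13)
  for (i in 1:50) {
    n <- sample(4:16, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 2)
    brute <- max(vapply(c(s, 0), function(t) {
      cs <- sum(s >= t & y == 1) / sum(y == 1)
      if (cs < 1) return(-1)
      sum(s < t & y == 0) / sum(y == 0)
    }, 0))
    expect_equal(specificity_at_full_sensitivity(y, s), brute)
  }
})

test_that("roc_auc equals the brute-force pair oracle and handles ties", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  set.seed(14)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # ties likely
    expect_equal(roc_auc(y, s), oracle_auc(y, s), tolerance = 1e-12)
  }
  expect_error(roc_auc(rep(1, 3), runif(3)), "both classes")
})

test_that("roc_points form a staircase whose trapezoid area is the AUC", {
  set.seed(15)
  for (i in 1:20) {
    n <- sample(6:24, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 1)
    pts <- roc_points(y, s)
    expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
    expect_identical(c(pts$fpr[1], pts$tpr[1]), c(0, 0))
    expect_identical(c(tail(pts$fpr, 1), tail(pts$tpr, 1)), c(1, 1))
    area <- platimg:::trapezoid_area(pts$fpr, pts$tpr)
    expect_equal(area, roc_auc(y, s), tolerance = 1e-9)
    # reversed scores mirror the curve
    expect_equal(platimg:::trapezoid_area(roc_points(y, -s + 1)$fpr,
                                          roc_points(y, -s + 1)$tpr),
                 1 - area, tolerance = 1e-9)
  }
  # perfect scores pass through (0, 1)
  pp <- roc_points(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_true(any(pp$fpr == 0 & pp$tpr == 1))
})

test_that("cv_auc averages fold AUCs and its influence-curve SE tracks a bootstrap SE", {
  # degenerate: every fold AUC 1 -> cvAUC 1, zero-width CI
  perfect <- lapply(1:3, function(i) {
    list(y_true = c(1, 1, 0, 0), scores = c(0.9, 0.8, 0.2, 0.1))
  })
  cvp <- cv_auc(perfect)
  expect_equal(cvp$cvauc, 1)
  expect_equal(diff(cvp$ci), 0)
  # mean of fold AUCs
  mk <- function(auc_target, seed) {
    set.seed(seed)
    y <- rep(c(1, 0), each = 20)
    s <- ifelse(y == 1, rnorm(40, auc_target, 0.3), rnorm(40, 0, 0.3))
    list(y_true = y, scores = pmin(pmax(s, 0), 1))
  }
  folds <- lapply(1:5, function(i) mk(0.8, 100 + i))
  cv <- cv_auc(folds)
  expect_equal(cv$cvauc, mean(cv$fold_aucs))
  expect_true(cv$ci[1] <= cv$cvauc && cv$cvauc <= cv$ci[2])

  # influence-curve SE within 20% of a bootstrap SE on a seeded toy
  set.seed(16)
  folds2 <- lapply(1:5, function(i) {
    y <- rep(c(1, 0), each = 20)
    s <- plogis(rnorm(40, ifelse(y == 1, 1, 0), 1))
    list(y_true = y, scores = s)
  })
  ic_se <- cv_auc(folds2)$se
  boot <- replicate(400, {
    mean(vapply(folds2, function(f) {
      idx <- sample(length(f$y_true), replace = TRUE)
      if (length(unique(f$y_true[idx])) < 2) return(NA_real_)
      roc_auc(f$y_true[idx], f$scores[idx])
    }, 0), na.rm = TRUE)
  })
  expect_lt(abs(ic_se - sd(boot)) / sd(boot), 0.2)

  # single-class folds dropped with warning; all dropped -> error
  bad <- list(list(y_true = rep(1, 4), scores = runif(4)))
  expect_error(suppressWarnings(cv_auc(c(bad, bad))), "folds")
})

test_that("aggregate_over_folds reports mean, SD and CI per metric", {
  r1 <- list(sensitivity = 0.9, specificity = 0.8, balanced_accuracy = 0.85,
             precision = 0.7, recall = 0.9,
             specificity_at_full_sensitivity = 0.6, auc = 0.87)
  # identical folds -> SD 0, degenerate CI
  agg0 <- aggregate_over_folds(list(r1, r1, r1))
  expect_true(all(agg0$sd == 0))
  expect_equal(agg0$ci_lo, agg0$mean)
  # two-point aggregation: balanced accuracies {0.87, 0.96} -> mean 0.915
  r2 <- r1; r2$balanced_accuracy <- 0.96
  r1b <- r1; r1b$balanced_accuracy <- 0.87
  agg <- aggregate_over_folds(list(r1b, r2))
  ba <- agg[agg$metric == "balanced_accuracy", ]
  expect_equal(ba$mean, 0.915)
  expect_equal(ba$sd, sd(c(0.87, 0.96)))
  # TEP aggregate over fold scores is the arithmetic mean
  expect_equal(mean(c(0.2, 0.4, 0.6, 0.8, 1.0)), 0.6)
})

test_that("metric suite and json serialization carry the seven reported metrics", {
  y <- rep(c(1, 0), each = 10)
  set.seed(17)
  s <- plogis(rnorm(20, ifelse(y == 1, 1.5, -1.5), 1))
  ms <- metric_suite(y, s)
  expect_named(ms, c("sensitivity", "specificity", "balanced_accuracy",
                     "precision", "recall",
                     "specificity_at_full_sensitivity", "auc"))
  agg <- aggregate_over_folds(list(ms, ms))
  path <- tempfile(fileext = ".json")
  write_metrics_json(agg, path, extra = list(cv_auc = list(cvauc = 0.9)))
  parsed <- jsonlite::read_json(path)
  expect_true(all(names(ms) %in% names(parsed)))
  expect_equal(parsed$auc$mean, ms$auc)
})
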