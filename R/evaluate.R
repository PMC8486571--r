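# Validation harness: stratified hold-out and k-fold splits, confusion
# metrics, specificity at full sensitivity, Mann-Whitney AUC, cross-validated
# AUC with influence-curve confidence intervals, and fold aggregation.

#' Stratified hold-out split
#'
#' Draws `floor(test_frac * n)` samples per stratum, without replacement,
#' from a seeded stream. Ids are sorted before seeding so the plan is
#' invariant to input ordering. With strata of sizes 28/30/204 and a 40%
#' fraction this yields an 11/12/81 test set.
#'
#' @param ids Sample identifiers.
#' @param strata Stratum label per sample (e.g. case / benign / healthy).
#' @param test_frac Fraction held out per stratum, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A `split_plan` with `test_ids` and `train_ids` (the non-test
#'   cohort), plus the strata lookup.
#' @export
stratified_holdout <- function(ids, strata, test_frac = 0.40, seed = 1) {
  if (test_frac < 0 || test_frac >= 1) stopf("test_frac must be in [0, 1)")
  if (length(ids) != length(strata)) stopf("ids and strata lengths differ")
  ord <- order(ids)
  ids <- ids[ord]; strata <- as.character(strata)[ord]
  test_ids <- with_seed(seed, {
    unlist(lapply(sort(unique(strata)), function(s) {
      pool <- ids[strata == s]
      n_test <- floor(test_frac * length(pool))
      if (n_test == 0) character(0) else sample(pool, n_test)
    }), use.names = FALSE)
  })
  plan <- list(test_ids = sort(test_ids),
               train_ids = setdiff(ids, test_ids),
               strata = stats::setNames(strata, ids),
               test_frac = test_frac, seed = seed)
  class(plan) <- "split_plan"
  plan
}

#' Stratified k-fold assignment
#'
#' Shuffles each stratum with a seeded stream and deals its members
#' round-robin across `k` folds, so every sample sits in exactly one
#' validation subgroup and stratum proportions are preserved within one
#' sample. Strata smaller than `k` are merged into a single pooled stratum
#' with a warning.
#'
#' @param ids Sample identifiers (typically the non-test cohort).
#' @param strata Stratum label per sample.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of `k` folds, each a list with `train_ids` and `val_ids`.
#' @export
stratified_kfold <- function(ids, strata, k = 5, seed = 1) {
  if (k < 2) stopf("k must be >= 2")
  if (length(ids) != length(strata)) stopf("ids and strata lengths differ")
  ord <- order(ids)
  ids <- ids[ord]; strata <- as.character(strata)[ord]
  sizes <- table(strata)
  small <- names(sizes)[sizes < k]
  if (length(small) > 0) {
    warnf("strata %s have fewer than %d samples; merging into one pooled stratum",
          paste(small, collapse = ", "), k)
    strata[strata %in% small] <- ".pooled"
  }
  fold_of <- with_seed(seed, {
    out <- integer(length(ids)); names(out) <- ids
    for (s in sort(unique(strata))) {
      pool <- ids[strata == s]
      out[sample(pool)] <- rep_len(seq_len(k), length(pool))
    }
    out
  })
  lapply(seq_len(k), function(f) {
    list(fold = f,
         train_ids = sort(names(fold_of)[fold_of != f]),
         val_ids = sort(names(fold_of)[fold_of == f]))
  })
}

#' Confusion-matrix metrics at a fixed threshold
#'
#' Calls a sample positive when its score is at or above `threshold`, then
#' reports sensitivity, specificity, balanced accuracy (their mean),
#' precision (0 with a log note when no positive calls) and recall
#' (= sensitivity).
#'
#' @param y_true Binary 0/1 vector.
#' @param scores Scores in `[0, 1]`.
#' @param threshold Decision threshold; score >= threshold is a positive call.
#' @return List with the confusion counts and metrics.
#' @export
confusion_metrics <- function(y_true, scores, threshold = 0.5) {
  y_true <- as.integer(y_true)
  if (length(unique(y_true)) < 2) stopf("both classes must be present in y_true")
  if (any(scores < 0 | scores > 1)) stopf("scores must lie in [0, 1]")
  call_pos <- scores >= threshold
  tp <- sum(call_pos & y_true == 1); fn <- sum(!call_pos & y_true == 1)
  fp <- sum(call_pos & y_true == 0); tn <- sum(!call_pos & y_true == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  if (tp + fp == 0) {
    pl_log("INFO", "confusion_metrics: no positive calls; precision reported as 0")
    prec <- 0
  } else {
    prec <- tp / (tp + fp)
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = sens, specificity = spec,
       balanced_accuracy = (sens + spec) / 2,
       precision = prec, recall = sens, threshold = threshold)
}

#' Specificity at full sensitivity
#'
#' The specificity at the most permissive threshold that still calls every
#' true case positive: with `t* = min(case scores)` and positive calls at
#' `score >= t*`, returns `TN / (TN + FP)`.
#'
#' @param y_true Binary 0/1 vector (>= 1 case and >= 1 control).
#' @param scores Scores in `[0, 1]`.
#' @return Specificity at sensitivity 1, in `[0, 1]`.
#' @export
specificity_at_full_sensitivity <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  if (!any(y_true == 1) || !any(y_true == 0)) {
    stopf("need at least one case and one control")
  }
  t_star <- min(scores[y_true == 1])
  ctrl <- scores[y_true == 0]
  sum(ctrl < t_star) / length(ctrl)
}

#' Mann-Whitney AUC
#'
#' Area under the ROC curve computed as the two-sample U statistic:
#' (concordant case-control pairs + half the tied pairs) divided by the
#' number of pairs.
#'
#' @param y_true Binary 0/1 vector.
#' @param scores Numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Monotone staircase of (FPR, TPR) points from (0,0) to (1,1), one step
#' per distinct score; tied scores produce diagonal segments, so the
#' trapezoidal area equals the Mann-Whitney AUC.
#'
#' @param y_true Binary 0/1 vector.
#' @param scores Numeric scores.
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y_true == 1) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & y_true == 0) / n0, 0)
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Influence curve of the AUC U-statistic for one fold (LeDell-style):
# cases contribute (F0(s_i) - auc)/p, controls ((1 - F1(s_j)) - auc)/q.
auc_influence <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  n <- length(y_true)
  case <- y_true == 1
  p <- mean(case); q <- 1 - p
  auc <- roc_auc(y_true, scores)
  s1 <- scores[case]; s0 <- scores[!case]
  g1 <- vapply(s1, function(s) mean(s0 < s) + 0.5 * mean(s0 == s), 0)
  g0 <- vapply(s0, function(s) mean(s1 > s) + 0.5 * mean(s1 == s), 0)
  ic <- numeric(n)
  ic[case] <- (g1 - auc) / p
  ic[!case] <- (g0 - auc) / q
  ic
}

#' Cross-validated AUC with influence-curve confidence interval
#'
#' cvAUC is the mean of the per-fold AUCs. Its standard error pools the
#' per-observation influence curves across folds (variance = mean of the
#' fold-wise influence-curve variances, divided by the total sample count);
#' the 95% CI is `cvAUC +/- 1.96 SE`, clipped to `[0, 1]`. A fold-SD normal
#' approximation is available as a fallback.
#'
#' @param folds List of per-fold lists, each with `y_true` and `scores`.
#' @param conf_level Confidence level (default 0.95).
#' @param method `"influence"` (default) or `"fold_sd"`.
#' @return List with `cvauc`, `fold_aucs`, `se`, `ci` (length-2), `method`.
#' @export
cv_auc <- function(folds, conf_level = 0.95, method = c("influence", "fold_sd")) {
  method <- match.arg(method)
  ok <- vapply(folds, function(f) {
    length(unique(as.integer(f$y_true))) == 2
  }, TRUE)
  if (any(!ok)) {
    warnf("dropping %d fold(s) with a single class", sum(!ok))
    folds <- folds[ok]
  }
  if (length(folds) < 2) stopf("need >= 2 usable folds")
  aucs <- vapply(folds, function(f) roc_auc(f$y_true, f$scores), 0)
  cvauc <- mean(aucs)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (method == "influence") {
    n_total <- sum(vapply(folds, function(f) length(f$y_true), 0L))
    fold_vars <- vapply(folds, function(f) {
      ic <- auc_influence(f$y_true, f$scores)
      mean(ic^2)
    }, 0)
    se <- sqrt(mean(fold_vars) / n_total)
  } else {
    se <- stats::sd(aucs) / sqrt(length(aucs))
  }
  ci <- pmin(pmax(cvauc + c(-1, 1) * z * se, 0), 1)
  list(cvauc = cvauc, fold_aucs = aucs, se = se, ci = ci, method = method)
}

#' Full metric suite for one evaluation
#'
#' Combines the thresholded confusion metrics with the threshold-free AUC
#' and specificity at full sensitivity — the seven reported quantities.
#'
#' @inheritParams confusion_metrics
#' @return Named list of metrics (proportions in `[0, 1]`).
#' @export
metric_suite <- function(y_true, scores, threshold = 0.5) {
  cm <- confusion_metrics(y_true, scores, threshold)
  c(cm[c("sensitivity", "specificity", "balanced_accuracy",
         "precision", "recall")],
    list(specificity_at_full_sensitivity =
           specificity_at_full_sensitivity(y_true, scores),
         auc = roc_auc(y_true, scores)))
}

#' Precision implied by sensitivity, specificity and class counts
#'
#' Under expected confusion counts `TP = sens * P` and `FP = (1 - spec) * N`,
#' precision equals `TP / (TP + FP)`. Used to check that reported rates are
#' mutually consistent with the cohort composition.
#'
#' @param sensitivity,specificity Rates in `[0, 1]`.
#' @param n_pos,n_neg Class counts.
#' @return Implied precision in `[0, 1]`.
#' @export
implied_precision <- function(sensitivity, specificity, n_pos, n_neg) {
  tp <- sensitivity * n_pos
  fp <- (1 - specificity) * n_neg
  tp / (tp + fp)
}

#' Aggregate per-fold metric reports
#'
#' Each fold's model is evaluated on the same fixed independent test set;
#' this aggregates the resulting per-fold metric lists into mean, sample SD
#' and a normal-approximation 95% CI (mean +/- 1.96 SD/sqrt(k), clipped to
#' `[0, 1]`) per metric.
#'
#' @param fold_reports List of per-fold metric lists (from [metric_suite()]).
#' @return A `metrics_report`: data.frame with one row per metric and
#'   columns mean, sd, ci_lo, ci_hi, plus the per-fold values as an
#'   attribute.
#' @export
aggregate_over_folds <- function(fold_reports) {
  if (length(fold_reports) < 1) stopf("need >= 1 fold report")
  metrics <- names(fold_reports[[1]])
  per_fold <- vapply(fold_reports, function(r) unlist(r[metrics]),
                     numeric(length(metrics)))
  per_fold <- matrix(per_fold, nrow = length(metrics),
                     dimnames = list(metrics, NULL))
  k <- ncol(per_fold)
  mean_ <- rowMeans(per_fold)
  sd_ <- apply(per_fold, 1, stats::sd)
  half <- 1.96 * sd_ / sqrt(k)
  rep_ <- data.frame(metric = metrics, mean = mean_, sd = sd_,
                     ci_lo = pmin(pmax(mean_ - half, 0), 1),
                     ci_hi = pmin(pmax(mean_ + half, 0), 1),
                     row.names = NULL)
  attr(rep_, "per_fold") <- per_fold
  class(rep_) <- c("metrics_report", "data.frame")
  rep_
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Metrics over folds (mean [95% CI], rounded to whole percent):\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-34s %3d%%  [%d-%d%%]  (sd %.3f)\n", x$metric[i],
                percent_round(x$mean[i]), percent_round(x$ci_lo[i]),
                percent_round(x$ci_hi[i]), x$sd[i]))
  }
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @param extra Optional named list merged into the JSON root (e.g. cvAUC).
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path, extra = list()) {
  per_fold <- attr(report, "per_fold")
  body <- lapply(seq_len(nrow(report)), function(i) {
    list(mean = report$mean[i], sd = report$sd[i],
         ci = c(report$ci_lo[i], report$ci_hi[i]),
         per_fold = as.numeric(per_fold[report$metric[i], ]),
         mean_percent_rounded = percent_round(report$mean[i]))
  })
  names(body) <- report$metric
  jsonlite::write_json(c(body, extra), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
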