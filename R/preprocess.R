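# Preprocessing: sample read-depth filter, annotation-driven gene-name
# mapping, median-of-ratios size factors and a closed-form negative-binomial
# variance-stabilizing transformation under a fitted dispersion-mean trend.

#' Drop samples with insufficient sequencing depth
#'
#' Removes samples whose total read count is strictly below `min_total`
#' (a sample at exactly the threshold is retained). Removed sample ids are
#' logged at INFO level.
#'
#' @param counts Integer feature-by-sample matrix (see [validate_counts()]).
#' @param min_total Minimum total reads per sample; default 100000.
#' @return The count matrix restricted to retained samples, order preserved.
#' @export
filter_samples <- function(counts, min_total = 100000) {
  validate_counts(counts)
  totals <- colSums(counts)
  keep <- totals >= min_total
  if (!any(keep)) {
    stopf("empty cohort: all %d samples have < %s total reads",
          ncol(counts), format(min_total, big.mark = ","))
  }
  if (any(!keep)) {
    pl_log("INFO", sprintf(
      "filter_samples: removed %d/%d samples below %s reads: %s",
      sum(!keep), ncol(counts), format(min_total, big.mark = ","),
      paste(colnames(counts)[!keep], collapse = ", ")))
  }
  counts[, keep, drop = FALSE]
}

#' Collapse annotated features to gene symbols
#'
#' Keeps only features whose annotation status is `"known"`. When several
#' source identifiers map to one gene name, the row with the smallest
#' annotation level wins (level 1 preferred); at equal level the row with
#' the larger total count is kept. Features absent from the annotation are
#' dropped with a logged count.
#'
#' @param counts Integer feature-by-sample matrix keyed by source id.
#' @param annot Annotation data.frame (see [read_annotation_tsv()]).
#' @return Count matrix keyed by gene name.
#' @export
map_genes <- function(counts, annot) {
  validate_counts(counts)
  validate_annotation(annot)
  idx <- match(rownames(counts), annot$source_id)
  unresolved <- is.na(idx)
  if (any(unresolved)) {
    pl_log("INFO", sprintf("map_genes: dropped %d features absent from annotation",
                           sum(unresolved)))
  }
  keep <- !unresolved
  ann <- annot[idx[keep], , drop = FALSE]
  known <- ann$status == "known"
  if (any(!known)) {
    pl_log("INFO", sprintf("map_genes: dropped %d features with status != known",
                           sum(!known)))
  }
  mat <- counts[keep, , drop = FALSE][known, , drop = FALSE]
  ann <- ann[known, , drop = FALSE]
  if (nrow(mat) == 0) stopf("no features survive gene mapping")

  # duplicate resolution: smallest level, then largest total count
  ord <- order(ann$gene_name, ann$level, -rowSums(mat))
  first <- !duplicated(ann$gene_name[ord])
  pick <- ord[first]
  n_dup <- nrow(mat) - length(pick)
  if (n_dup > 0) {
    pl_log("INFO", sprintf(
      "map_genes: resolved %d duplicate gene-name rows (smallest level, then largest total)",
      n_dup))
  }
  pick <- sort(pick)                    # preserve original row order
  out <- mat[pick, , drop = FALSE]
  rownames(out) <- ann$gene_name[pick]
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization constants following the median-of-ratios
#' convention: the reference set is the genes with no zero count in any
#' sample; each sample's factor is the median over reference genes of the
#' ratio of its count to the gene's geometric mean across samples.
#'
#' @param counts Integer feature-by-sample matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  validate_counts(counts)
  ref <- rowSums(counts == 0) == 0
  if (!any(ref)) {
    stopf(paste0("no gene has positive counts in every sample; ",
                 "cannot form a median-of-ratios reference ",
                 "(pseudo-reference fallback is disabled by default)"))
  }
  refc <- counts[ref, , drop = FALSE]
  geo <- exp(rowMeans(log(refc)))
  sf <- apply(refc / geo, 2, stats::median)
  names(sf) <- colnames(counts)
  sf
}

#' Fit a parametric dispersion-mean trend
#'
#' Computes per-gene method-of-moments dispersions on size-factor-normalized
#' counts, `alpha_g = max(0, (s2_g - mu_g) / mu_g^2)`, then fits the trend
#' `alpha(mu) = a0 + a1/mu` by iteratively reweighted least squares of
#' `alpha_g` on `1/mu_g` over genes with positive dispersion. After an
#' initial fit, genes whose dispersion lies more than 2 natural-log units
#' from the fitted trend are excluded once. `a0` is floored at 1e-4 and
#' `a1` at 0.
#'
#' @param counts Integer feature-by-sample matrix.
#' @param sf Size factors from [size_factors()].
#' @param min_genes Warn when fewer genes than this enter the fit.
#' @return Object of class `dispersion_trend`: list with `a0`, `a1`,
#'   `per_gene_dispersion` and the number of genes used.
#' @export
fit_dispersion_trend <- function(counts, sf, min_genes = 50) {
  validate_counts(counts)
  if (ncol(counts) < 2) stopf("need >= 2 samples to estimate dispersions")
  u <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(u)
  s2 <- apply(u, 1, stats::var)
  alpha <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)

  use <- alpha > 0 & mu > 0 & is.finite(alpha)
  if (sum(use) < min_genes) {
    warnf("dispersion trend fitted on only %d genes (< %d recommended)",
          sum(use), min_genes)
  }
  if (sum(use) < 2) {
    # essentially Poisson data: no information beyond the floor
    trend <- list(a0 = 1e-4, a1 = 0, per_gene_dispersion = alpha,
                  n_used = sum(use))
    class(trend) <- "dispersion_trend"
    return(trend)
  }

  y <- alpha[use]
  x <- 1 / mu[use]
  fit_once <- function(y, x, w) {
    X <- cbind(1, x)
    cf <- stats::lm.wfit(X, y, w)$coefficients
    c(a0 = unname(cf[1]), a1 = unname(cf[2]))
  }
  cf <- fit_once(y, x, rep(1, length(y)))
  fitted <- pmax(cf[1] + cf[2] * x, 1e-8)
  # one-shot outlier exclusion: > 2 log-units from the trend
  ok <- abs(log(y) - log(fitted)) <= 2
  y <- y[ok]; x <- x[ok]
  # IRLS with gamma-like weights 1/fitted^2
  cf_prev <- cf
  for (it in seq_len(25)) {
    fitted <- pmax(cf[1] + cf[2] * x, 1e-8)
    cf <- fit_once(y, x, 1 / fitted^2)
    if (!all(is.finite(cf))) break
    if (max(abs(cf - cf_prev) / pmax(abs(cf_prev), 1e-8)) < 1e-6) break
    cf_prev <- cf
  }
  if (!all(is.finite(cf))) {
    stopf("degenerate dispersion-trend fit (coefficients %s); %d genes used",
          paste(signif(cf, 3), collapse = ", "), length(y))
  }
  trend <- list(a0 = max(cf[["a0"]], 1e-4), a1 = max(cf[["a1"]], 0),
                per_gene_dispersion = alpha, n_used = length(y))
  class(trend) <- "dispersion_trend"
  trend
}

#' @export
print.dispersion_trend <- function(x, ...) {
  cat(sprintf("dispersion trend: alpha(mu) = %.4g + %.4g/mu  (%d genes)\n",
              x$a0, x$a1, x$n_used))
  invisible(x)
}

#' Evaluate the fitted dispersion trend
#' @param trend A `dispersion_trend`.
#' @param mu Positive mean values.
#' @return Fitted dispersions `a0 + a1/mu`.
#' @export
trend_dispersion <- function(trend, mu) trend$a0 + trend$a1 / mu

#' Variance-stabilizing transformation
#'
#' Closed-form VST for negative-binomial counts under the parametric trend
#' `alpha(mu) = a0 + a1/mu`. With `u` the size-factor-normalized count,
#' the transformed value is
#' `log2((1 + a1 + 2*a0*u + 2*sqrt(a0*u*(1 + a1 + a0*u))) / (4*a0))`,
#' which is strictly increasing in `u`, finite for `u >= 0`, and approaches
#' `log2(u)` for large counts.
#'
#' @param counts Integer feature-by-sample matrix.
#' @param sf Size factors.
#' @param trend A `dispersion_trend`.
#' @return Numeric matrix of transformed expression, same dimnames.
#' @export
vst_transform <- function(counts, sf, trend) {
  validate_counts(counts)
  u <- sweep(counts, 2, sf, "/")
  vst_value(u, trend$a0, trend$a1)
}

vst_value <- function(u, a0, a1) {
  log2((1 + a1 + 2 * a0 * u + 2 * sqrt(a0 * u * (1 + a1 + a0 * u))) / (4 * a0))
}

#' Run the full preprocessing chain
#'
#' `filter_samples` then `map_genes` then size factors, dispersion trend and
#' VST. Size factors are per-sample quantities computed for every retained
#' sample; the dispersion trend can be estimated on a subset of samples
#' (e.g. the training split, to avoid information leakage) and is then
#' applied to all.
#'
#' @param counts Raw feature-by-sample count matrix.
#' @param annot Annotation table.
#' @param min_total Sample read-depth threshold.
#' @param fit_samples Optional character vector of sample ids on which to
#'   fit the dispersion trend (default: all retained samples).
#' @return List with `normalized` (gene-by-sample matrix), `size_factors`,
#'   `trend`, and a `qc` list (dropped sample ids, feature counts).
#' @export
preprocess_counts <- function(counts, annot, min_total = 100000,
                              fit_samples = NULL) {
  validate_counts(counts)
  totals <- colSums(counts)
  filtered <- filter_samples(counts, min_total)
  dropped_samples <- setdiff(colnames(counts), colnames(filtered))
  mapped <- map_genes(filtered, annot)
  sf <- size_factors(mapped)
  fit_ids <- fit_samples %||% colnames(mapped)
  fit_ids <- intersect(fit_ids, colnames(mapped))
  if (length(fit_ids) < 2) stopf("fewer than 2 fit samples after filtering")
  trend <- fit_dispersion_trend(mapped[, fit_ids, drop = FALSE], sf[fit_ids])
  normalized <- vst_transform(mapped, sf, trend)
  list(
    normalized = normalized,
    size_factors = sf,
    trend = trend,
    qc = list(
      n_samples_in = ncol(counts),
      dropped_samples = dropped_samples,
      sample_totals = totals,
      n_features_in = nrow(counts),
      n_genes_out = nrow(mapped),
      fit_samples = fit_ids
    )
  )
}
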