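# Orchestration: the end-to-end study harness (stratified hold-out,
# stratified k-fold cross-validation, per-fold training, independent-test
# aggregation) and the YAML-configured subcommand functions behind the
# command-line front-end.

#' Run the full train/evaluate study on one cohort
#'
#' Implements the validation design end to end: depth filter and gene
#' mapping, a stratified 40% hold-out, size factors and a dispersion trend
#' fitted on the non-test cohort (leakage-safe default), VST, panel pruning,
#' a global intensity scaler fitted on the non-test cohort, stratified
#' k-fold cross-validation with one network trained per fold (the held-in
#' fold serving as validation monitor), and evaluation of every fold model
#' on the fixed independent test set. The reported TEP score of a test
#' sample is the mean of its fold-model scores.
#'
#' @param counts Raw feature-by-sample count matrix.
#' @param annot Annotation table.
#' @param labels Named 0/1 vector (1 = case).
#' @param strata Named stratum labels (e.g. case/benign/healthy).
#' @param panel A `pathway_panel`.
#' @param min_total Sample read-depth threshold.
#' @param test_frac Hold-out fraction (default 0.40).
#' @param k Number of CV folds (default 5).
#' @param spec A [network_spec()]; its seed is re-derived per fold.
#' @param cfg A [train_config()]; its seed is re-derived per fold.
#' @param vst_fit `"train"` (default) fits the dispersion trend on non-test
#'   samples only; `"all"` uses the full cohort.
#' @param threshold Decision threshold for class calls.
#' @param seed Master seed driving the splits and the per-fold training
#'   streams.
#' @return A `study_result` list: split plan, folds, per-fold histories and
#'   test scores, TEP scores, aggregated `metrics_report`, cvAUC, frozen
#'   preprocessing state (`bundle`) for later prediction.
#' @export
run_study <- function(counts, annot, labels, strata, panel,
                      min_total = 100000, test_frac = 0.40, k = 5,
                      spec = network_spec(), cfg = train_config(),
                      vst_fit = c("train", "all"), threshold = 0.5,
                      seed = 1) {
  vst_fit <- match.arg(vst_fit)
  filtered <- filter_samples(counts, min_total)
  mapped <- map_genes(filtered, annot)
  ids <- colnames(mapped)
  labels <- labels[ids]; strata <- strata[ids]
  if (anyNA(labels) || anyNA(strata)) stopf("labels/strata missing for some samples")

  plan <- stratified_holdout(ids, strata, test_frac, seed = child_seed(seed, 1))
  sf <- size_factors(mapped)
  fit_ids <- if (vst_fit == "train") plan$train_ids else ids
  trend <- fit_dispersion_trend(mapped[, fit_ids, drop = FALSE], sf[fit_ids])
  normalized <- vst_transform(mapped, sf, trend)

  pruned <- prune_panel(panel, rownames(normalized))
  panel_genes <- unique(unlist(pruned$genes))
  scaler <- fit_scaler(normalized[panel_genes, plan$train_ids, drop = FALSE])
  images <- build_image_set(normalized, pruned, scaler, labels)
  dims <- panel_image_dims(pruned)
  pl_log("INFO", sprintf("run_study: %d samples, images %d x %d",
                         length(ids), dims[["height"]], dims[["width"]]))

  folds <- stratified_kfold(plan$train_ids, plan$strata[plan$train_ids],
                            k = k, seed = child_seed(seed, 2))
  idx_of <- stats::setNames(seq_along(images$sample_ids), images$sample_ids)
  test_idx <- idx_of[plan$test_ids]
  y_test <- as.integer(labels[plan$test_ids])

  fold_models <- vector("list", k)
  fold_scores <- matrix(NA_real_, nrow = length(test_idx), ncol = k,
                        dimnames = list(plan$test_ids, paste0("fold", seq_len(k))))
  fold_reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- idx_of[folds[[f]]$train_ids]
    va <- idx_of[folds[[f]]$val_ids]
    spec_f <- spec; spec_f$seed <- as.integer(child_seed(seed, 100 + f))
    cfg_f <- cfg; cfg_f$seed <- as.integer(child_seed(seed, 200 + f))
    model <- build_network(dims[["height"]], dims[["width"]], spec_f)
    model <- train_network(
      model,
      images$images[tr, , , drop = FALSE],
      labels[folds[[f]]$train_ids],
      cfg = cfg_f,
      validation = list(images = images$images[va, , , drop = FALSE],
                        labels = labels[folds[[f]]$val_ids]))
    sc <- predict_scores(model, images$images[test_idx, , , drop = FALSE])
    fold_scores[, f] <- sc
    fold_reports[[f]] <- metric_suite(y_test, sc, threshold)
    fold_models[[f]] <- model
    pl_log("INFO", sprintf("fold %d/%d: test AUC %.3f", f, k,
                           fold_reports[[f]]$auc))
  }

  report <- aggregate_over_folds(fold_reports)
  cv <- cv_auc(lapply(seq_len(k), function(f) {
    list(y_true = y_test, scores = fold_scores[, f])
  }))
  tep <- rowMeans(fold_scores)

  structure(list(
    plan = plan, folds = folds, labels = labels, strata = strata,
    image_dims = dims, report = report, cv = cv,
    fold_scores = fold_scores, tep_scores = tep, y_test = y_test,
    fold_models = fold_models, threshold = threshold,
    bundle = list(panel = pruned, scaler = scaler, trend = trend,
                  ref_loggeomeans = reference_loggeomeans(mapped),
                  gene_names = rownames(mapped), spec = spec, cfg = cfg,
                  models = fold_models, threshold = threshold)
  ), class = "study_result")
}

# frozen median-of-ratios reference: per-gene log geometric means over the
# genes with no zero count (used to size-factor new samples consistently)
reference_loggeomeans <- function(counts) {
  ref <- rowSums(counts == 0) == 0
  rowMeans(log(counts[ref, , drop = FALSE]))
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study: %d test samples, %d folds, cvAUC %.3f [%.3f, %.3f]\n",
              length(x$y_test), ncol(x$fold_scores),
              x$cv$cvauc, x$cv$ci[1], x$cv$ci[2]))
  print(x$report)
  invisible(x)
}

#' Score new samples with a frozen study bundle
#'
#' Applies the frozen panel, scaler, dispersion trend and fold models to a
#' new count matrix: genes are mapped with the supplied annotation, size
#' factors are computed against the bundle's median-of-ratios reference,
#' and each sample receives its per-fold scores and their mean (the TEP
#' score). Panel genes missing from the new cohort abort when their
#' fraction exceeds `missing_tolerance`; below it they render as black
#' pixels.
#'
#' @param bundle The `bundle` element of a [run_study()] result.
#' @param counts New raw count matrix.
#' @param annot Annotation table.
#' @param missing_tolerance Maximum tolerated fraction of missing panel
#'   genes (default 0).
#' @return data.frame with sample_id, per-fold scores and `tep_score`.
#' @export
predict_cohort <- function(bundle, counts, annot, missing_tolerance = 0) {
  mapped <- map_genes(counts, annot)
  ref <- bundle$ref_loggeomeans
  common_ref <- intersect(names(ref), rownames(mapped))
  if (length(common_ref) < 2) stopf("new cohort shares too few reference genes")
  logc <- log(mapped[common_ref, , drop = FALSE])  # zero counts -> -Inf, dropped below
  sf <- apply(logc, 2, function(col) {
    exp(stats::median((col - ref[common_ref])[is.finite(col)]))
  })
  panel_genes <- unique(unlist(bundle$panel$genes))
  missing <- setdiff(panel_genes, rownames(mapped))
  frac_missing <- length(missing) / length(panel_genes)
  if (frac_missing > missing_tolerance) {
    stopf("%.1f%% of panel genes missing from new cohort (tolerance %.1f%%)",
          100 * frac_missing, 100 * missing_tolerance)
  }
  normalized <- vst_transform(mapped, sf, bundle$trend)
  if (length(missing) > 0) {
    pad <- matrix(bundle$scaler$v_min, nrow = length(missing),
                  ncol = ncol(normalized),
                  dimnames = list(missing, colnames(normalized)))
    normalized <- rbind(normalized, pad)
  }
  images <- build_image_set(normalized, bundle$panel, bundle$scaler)
  scores <- vapply(bundle$models, function(m) predict_scores(m, images),
                   numeric(length(images$sample_ids)))
  scores <- matrix(scores, nrow = length(images$sample_ids),
                   dimnames = list(images$sample_ids,
                                   paste0("fold", seq_along(bundle$models))))
  data.frame(sample_id = rownames(scores), scores,
             tep_score = rowMeans(scores), row.names = NULL,
             check.names = FALSE)
}

# Run configuration ---------------------------------------------------------

#' Default run configuration
#'
#' Nested list mirroring the YAML schema of the command-line front-end.
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    workdir = ".",
    paths = list(counts = "counts.tsv", annotation = "annotation.tsv",
                 labels = "labels.tsv", panel = "panel.gmt"),
    preprocess = list(min_total = 100000, vst_fit = "train"),
    panel = list(scaling = "global"),
    network = list(conv_filters = 4, kernel = 3,
                   dense_units = c(256, 64, 16, 4),
                   dropout_rates = c(0.25, 0.25)),
    train = list(epochs = 50, batch_size = 32, learning_rate = 1.0,
                 rho = 0.95, epsilon = 1e-7, positive_class_scale = 1.0),
    split = list(test_frac = 0.40, k = 5),
    threshold = 0.5,
    synth = list(n_case = 60, n_control = 60, n_genes = 2000,
                 n_cancer = 4, n_signaling = 10, n_metabolism = 6,
                 n_signal = 2, log2_fc = 2.0, overlap_frac = 0.2),
    export_png = FALSE
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a YAML run configuration
#'
#' Unspecified keys fall back to [default_run_config()].
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  cfg
}

config_paths <- function(config) {
  lapply(config$paths, function(p) {
    if (grepl("^/", p)) p else file.path(config$workdir, p)
  })
}

write_provenance <- function(config, step, outputs, inputs = character(0)) {
  prov <- list(
    step = step,
    package_version = as.character(utils::packageVersion("platimg")),
    seed = config$seed,
    config_hash = config_hash(config),
    inputs = lapply(stats::setNames(as.list(inputs), basename(inputs)),
                    function(f) unname(tools::md5sum(f)))
  )
  path <- file.path(config$workdir, paste0("provenance_", step, ".json"))
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Hash a run configuration
#' @param config Configuration list.
#' @return MD5 hex string of the canonicalized config.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

# Subcommands ---------------------------------------------------------------

#' Generate a complete demo cohort on disk
#'
#' Writes counts, annotation, labels and a fixture panel (plus a checksum
#' manifest) into the configured workdir, deterministic under the config
#' seed.
#'
#' @param config Run configuration (see [read_run_config()]).
#' @return Named list of file paths, invisibly.
#' @export
cmd_make_fixtures <- function(config = default_run_config()) {
  s <- config$synth
  dir.create(config$workdir, showWarnings = FALSE, recursive = TRUE)
  pool <- synth_gene_pool(s$n_genes)
  panel <- make_fixture_panel(s$n_cancer, s$n_signaling, s$n_metabolism,
                              pool, overlap_frac = s$overlap_frac,
                              seed = child_seed(config$seed, 11))
  signal <- panel$pathway_id[seq_len(min(s$n_signal, length(panel)))]
  cfg <- simulation_config(s$n_case, s$n_control, n_genes = s$n_genes,
                           signal_pathways = signal, log2_fc = s$log2_fc,
                           seed = child_seed(config$seed, 12))
  cohort <- simulate_counts(cfg, panel)
  paths <- write_cohort(cohort, panel, config$workdir)
  write_provenance(config, "make_fixtures", character(0))
  pl_log("INFO", sprintf("cmd_make_fixtures: wrote %d files to %s",
                         length(paths), config$workdir))
  invisible(paths)
}

#' Preprocess a cohort from disk
#'
#' Reads counts and annotation, applies the depth filter, gene mapping,
#' size factors and VST, and writes `normalized.tsv` plus a QC report.
#'
#' @param config Run configuration.
#' @return The [preprocess_counts()] result, invisibly.
#' @export
cmd_preprocess <- function(config = default_run_config()) {
  p <- config_paths(config)
  counts <- read_counts_tsv(p$counts)
  annot <- read_annotation_tsv(p$annotation)
  res <- preprocess_counts(counts, annot,
                           min_total = config$preprocess$min_total)
  out <- file.path(config$workdir, "normalized.tsv")
  write_matrix_tsv(round(res$normalized, 6), out, id_col = "gene_name")
  qc <- list(
    n_samples_in = res$qc$n_samples_in,
    n_samples_out = ncol(res$normalized),
    dropped_samples = res$qc$dropped_samples,
    n_features_in = res$qc$n_features_in,
    n_genes_out = res$qc$n_genes_out,
    size_factors = as.list(res$size_factors),
    dispersion_trend = list(a0 = res$trend$a0, a1 = res$trend$a1)
  )
  jsonlite::write_json(qc, file.path(config$workdir, "qc.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(config, "preprocess", character(0),
                   inputs = c(p$counts, p$annotation))
  invisible(res)
}

#' Build the image container from a preprocessed cohort
#'
#' Prunes the panel against the expressed genes, fits the global intensity
#' scaler (on the training subset when a split file is present; set
#' `panel$scaler_fit: all` to use every sample) and writes the image
#' container, optionally exporting one PNG per sample.
#'
#' @param config Run configuration.
#' @return The `image_set`, invisibly.
#' @export
cmd_build_images <- function(config = default_run_config()) {
  p <- config_paths(config)
  counts <- read_counts_tsv(p$counts)
  annot <- read_annotation_tsv(p$annotation)
  labels_df <- read_labels_tsv(p$labels)
  res <- preprocess_counts(counts, annot,
                           min_total = config$preprocess$min_total)
  panel <- read_panel(p$panel)
  pruned <- prune_panel(panel, rownames(res$normalized))
  panel_genes <- unique(unlist(pruned$genes))
  scaler_fit <- config$panel$scaler_fit %||% "all"
  split_file <- file.path(config$workdir, "splits.tsv")
  fit_ids <- colnames(res$normalized)
  if (identical(scaler_fit, "train")) {
    if (!file.exists(split_file)) {
      stopf("scaler_fit = 'train' requires %s (run cmd_train_eval first)",
            split_file)
    }
    sp <- utils::read.delim(split_file)
    fit_ids <- intersect(sp$sample_id[sp$subset != "test"], fit_ids)
  }
  scaler <- fit_scaler(res$normalized[panel_genes, fit_ids, drop = FALSE])
  labels <- stats::setNames(labels_df$label, labels_df$sample_id)
  images <- build_image_set(res$normalized, pruned, scaler, labels)
  write_image_container(images, file.path(config$workdir, "images.rds"))
  write_scaler(scaler, file.path(config$workdir, "scaler.json"))
  if (isTRUE(config$export_png)) {
    png_dir <- file.path(config$workdir, "png")
    dir.create(png_dir, showWarnings = FALSE)
    for (s in seq_along(images$sample_ids)) {
      img <- list(sample_id = images$sample_ids[s], grid = images$images[s, , ])
      class(img) <- "sample_image"
      export_png(img, file.path(png_dir, paste0(images$sample_ids[s], ".png")))
    }
  }
  write_provenance(config, "build_images", character(0),
                   inputs = c(p$counts, p$annotation, p$labels, p$panel))
  invisible(images)
}

#' Train and evaluate on a cohort from disk
#'
#' Runs [run_study()] on the configured inputs and writes the metrics
#' report (JSON), ROC points (TSV), split plan (TSV), TEP scores (TSV) and
#' the frozen model bundle (RDS).
#'
#' @param config Run configuration.
#' @return The `study_result`, invisibly.
#' @export
cmd_train_eval <- function(config = default_run_config()) {
  p <- config_paths(config)
  counts <- read_counts_tsv(p$counts)
  annot <- read_annotation_tsv(p$annotation)
  labels_df <- read_labels_tsv(p$labels)
  panel <- read_panel(p$panel)
  labels <- stats::setNames(labels_df$label, labels_df$sample_id)
  strata <- stats::setNames(labels_df$stratum, labels_df$sample_id)
  n <- config$network
  spec <- network_spec(conv_filters = n$conv_filters, kernel = n$kernel,
                       dense_units = n$dense_units,
                       dropout_rates = n$dropout_rates,
                       seed = config$seed)
  t <- config$train
  cfg <- train_config(epochs = t$epochs, batch_size = t$batch_size,
                      learning_rate = t$learning_rate, rho = t$rho,
                      epsilon = t$epsilon,
                      positive_class_scale = t$positive_class_scale,
                      seed = config$seed)
  study <- run_study(counts, annot, labels, strata, panel,
                     min_total = config$preprocess$min_total,
                     test_frac = config$split$test_frac, k = config$split$k,
                     spec = spec, cfg = cfg,
                     vst_fit = config$preprocess$vst_fit,
                     threshold = config$threshold, seed = config$seed)

  wd <- config$workdir
  dir.create(wd, showWarnings = FALSE, recursive = TRUE)
  write_metrics_json(study$report, file.path(wd, "metrics.json"),
                     extra = list(cv_auc = list(cvauc = study$cv$cvauc,
                                                se = study$cv$se,
                                                ci = study$cv$ci,
                                                fold_aucs = study$cv$fold_aucs)))
  roc <- roc_points(study$y_test, study$tep_scores)
  utils::write.table(roc, file.path(wd, "roc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  splits <- rbind(
    data.frame(sample_id = study$plan$test_ids, subset = "test", fold = NA),
    do.call(rbind, lapply(study$folds, function(f) {
      data.frame(sample_id = f$val_ids, subset = "cv", fold = f$fold)
    })))
  utils::write.table(splits, file.path(wd, "splits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tep <- data.frame(sample_id = names(study$tep_scores),
                    label = study$y_test,
                    stratum = study$strata[names(study$tep_scores)],
                    study$fold_scores,
                    tep_score = study$tep_scores,
                    row.names = NULL, check.names = FALSE)
  utils::write.table(tep, file.path(wd, "tep_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  saveRDS(study$bundle, file.path(wd, "model_bundle.rds"))
  write_provenance(config, "train_eval", character(0),
                   inputs = c(p$counts, p$annotation, p$labels, p$panel))
  invisible(study)
}

#' Score a new cohort with a frozen bundle from disk
#'
#' @param config Run configuration (`paths$counts` points at the new
#'   cohort; `paths$annotation` at its annotation).
#' @param bundle_path Path to `model_bundle.rds` from [cmd_train_eval()].
#' @param out Output TSV path (default `tep_predictions.tsv` in workdir).
#' @return The prediction data.frame, invisibly.
#' @export
cmd_predict <- function(config = default_run_config(),
                        bundle_path = file.path(config$workdir, "model_bundle.rds"),
                        out = file.path(config$workdir, "tep_predictions.tsv")) {
  p <- config_paths(config)
  bundle <- readRDS(bundle_path)
  counts <- read_counts_tsv(p$counts)
  annot <- read_annotation_tsv(p$annotation)
  pred <- predict_cohort(bundle, counts, annot,
                         missing_tolerance = config$missing_gene_tolerance %||% 0)
  utils::write.table(pred, out, sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(config, "predict", character(0),
                   inputs = c(p$counts, p$annotation))
  invisible(pred)
}
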