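# Synthetic platelet-like cohorts: negative-binomial counts with a
# dispersion-mean trend, log-normal library sizes, pathway-structured class
# effects with alternating sign, and decoy annotation rows that exercise
# the gene-mapping rules. Fixture pathway panels emulate the categorized
# KEGG-style panel at reduced size.

#' Simulation configuration
#'
#' Defaults emulate the count structure the preprocessing stage assumes:
#' baseline means log-normal(ln 50, 1), dispersion trend
#' `alpha(mu) = 0.05 + 2/mu`, library-size factors log-normal(0, 0.2), and
#' a class effect of `log2_fc` applied to every gene of every signal
#' pathway with alternating sign (up/down) so the image signal is textural
#' rather than a brightness offset.
#'
#' @param n_case,n_control Cohort sizes.
#' @param n_genes Number of genes (default 2000).
#' @param signal_pathways Pathway ids carrying the class effect.
#' @param log2_fc Effect size on the log2 scale (default 1).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline mean law.
#' @param a0,a1 Dispersion trend coefficients.
#' @param libsize_sdlog Log-sd of the library-size factors.
#' @param decoy_frac Fraction of genes receiving decoy annotation rows
#'   (level-2 duplicates and unknown-status features).
#' @param seed Integer seed.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(n_case, n_control, n_genes = 2000,
                              signal_pathways = character(0), log2_fc = 1.0,
                              baseline_meanlog = log(50), baseline_sdlog = 1,
                              a0 = 0.05, a1 = 2.0, libsize_sdlog = 0.2,
                              decoy_frac = 0.02, seed = 1) {
  if (n_case < 1 || n_control < 1 || n_genes < 1) stopf("all sizes must be >= 1")
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_genes = as.integer(n_genes),
              signal_pathways = as.character(signal_pathways),
              log2_fc = log2_fc, baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog, a0 = a0, a1 = a1,
              libsize_sdlog = libsize_sdlog, decoy_frac = decoy_frac,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Synthetic gene pool
#'
#' @param n Number of genes.
#' @return Character vector of synthetic gene symbols.
#' @export
synth_gene_pool <- function(n) sprintf("SG%04d", seq_len(n))

#' Build a fixture pathway panel
#'
#' Draws pathway lengths uniformly from `len_range` and fills gene lists
#' from `gene_pool`; a fraction `overlap_frac` of each pathway's genes is
#' re-drawn from genes already used by earlier pathways (when available),
#' guaranteeing genes with pixel multiplicity >= 2. Deterministic under
#' `seed`.
#'
#' @param n_cancer,n_signaling,n_metabolism Pathways per category.
#' @param gene_pool Candidate gene symbols.
#' @param overlap_frac Fraction of genes shared with earlier pathways.
#' @param len_range Min/max pathway length (default 10-80).
#' @param seed Integer seed.
#' @return A `pathway_panel` in canonical category order.
#' @export
make_fixture_panel <- function(n_cancer, n_signaling, n_metabolism,
                               gene_pool, overlap_frac = 0.2,
                               len_range = c(10, 80), seed = 1) {
  n_path <- n_cancer + n_signaling + n_metabolism
  if (n_path < 1) stopf("need at least one pathway")
  if (overlap_frac < 0 || overlap_frac >= 1) stopf("overlap_frac must be in [0, 1)")
  max_fresh <- n_path * len_range[2]
  if (length(gene_pool) < len_range[2]) {
    stopf("gene_pool too small: longest pathway may need %d genes", len_range[2])
  }
  cats <- rep(.panel_categories, c(n_cancer, n_signaling, n_metabolism))
  with_seed(seed, {
    used <- character(0)
    genes <- vector("list", n_path)
    for (i in seq_len(n_path)) {
      len <- sample(len_range[1]:len_range[2], 1)
      n_shared <- if (i == 1) 0 else min(round(overlap_frac * len), length(used))
      shared <- if (n_shared > 0) sample(used, n_shared) else character(0)
      fresh_pool <- setdiff(gene_pool, shared)
      if (length(fresh_pool) < len - n_shared) {
        stopf("gene_pool exhausted at pathway %d", i)
      }
      fresh <- sample(fresh_pool, len - n_shared)
      g <- sample(c(shared, fresh))         # shuffle within-pathway order
      genes[[i]] <- g
      used <- union(used, g)
    }
    ids <- sprintf("path%02d_%s", seq_len(n_path), cats)
    new_pathway_panel(ids, ids, cats, genes)
  })
}

#' Simulate a platelet-like cohort
#'
#' Draws counts `NB(mean = s_j * mu_g * 2^(+/- log2_fc)`, dispersion
#' `a0 + a1/mu_g)`, the fold-change applied only in cases and only to genes
#' of the configured signal pathways, with sign alternating along each
#' pathway. The annotation table marks every real gene status `known`,
#' level 1, and adds decoy rows — level-2 duplicate ids (with low counts)
#' and unknown-status features — to exercise the mapping rules. Controls
#' are split into `healthy` and `benign` strata for stratified designs.
#'
#' @param cfg A [simulation_config()].
#' @param panel A `pathway_panel` whose genes index into the simulated
#'   gene set (ids beyond `n_genes` are ignored).
#' @return List with `counts` (feature-by-sample integer matrix keyed by
#'   source id), `labels` (named 0/1), `strata` (named character),
#'   `annotation` (data.frame) and `signal_genes`.
#' @export
simulate_counts <- function(cfg, panel = NULL) {
  if (length(cfg$signal_pathways) > 0) {
    if (is.null(panel)) stopf("signal pathways requested but no panel given")
    missing <- setdiff(cfg$signal_pathways, panel$pathway_id)
    if (length(missing) > 0) {
      stopf("signal pathways not in panel: %s", paste(missing, collapse = ", "))
    }
  }
  genes <- synth_gene_pool(cfg$n_genes)
  n <- cfg$n_case + cfg$n_control
  with_seed(cfg$seed, {
    mu <- stats::rlnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)
    names(mu) <- genes
    sf <- stats::rlnorm(n, 0, cfg$libsize_sdlog)
    labels <- c(rep(1L, cfg$n_case), rep(0L, cfg$n_control))
    sample_ids <- sprintf("S%03d", seq_len(n))
    names(labels) <- sample_ids
    # controls split roughly 85/15 into healthy and benign subtypes
    n_benign <- max(1L, round(0.15 * cfg$n_control))
    strata <- c(rep("case", cfg$n_case),
                rep(c("benign", "healthy"),
                    c(n_benign, cfg$n_control - n_benign)))
    names(strata) <- sample_ids

    # per-gene signed log2 effect, alternating along each signal pathway
    effect <- numeric(cfg$n_genes)
    names(effect) <- genes
    signal_genes <- character(0)
    for (pid in cfg$signal_pathways) {
      g <- intersect(panel$genes[[match(pid, panel$pathway_id)]], genes)
      signs <- rep_len(c(1, -1), length(g))
      effect[g] <- signs * cfg$log2_fc
      signal_genes <- union(signal_genes, g)
    }

    alpha <- cfg$a0 + cfg$a1 / mu
    mean_mat <- outer(mu, sf)                       # genes x samples
    case_cols <- which(labels == 1L)
    if (length(case_cols) > 0 && any(effect != 0)) {
      mean_mat[, case_cols] <- mean_mat[, case_cols] * 2^effect
    }
    counts <- matrix(
      stats::rnbinom(cfg$n_genes * n, mu = mean_mat, size = rep(1 / alpha, n)),
      nrow = cfg$n_genes, dimnames = list(genes, sample_ids))

    # annotation: real genes as level-1 'known' rows keyed by source ids
    src <- sprintf("SRC%05d", seq_len(cfg$n_genes))
    annotation <- data.frame(source_id = src, gene_name = genes,
                             status = "known", level = 1L,
                             stringsAsFactors = FALSE)
    rownames(counts) <- src

    n_decoy <- round(cfg$decoy_frac * cfg$n_genes)
    if (n_decoy > 0) {
      dup_genes <- sample(seq_len(cfg$n_genes), n_decoy)       # level-2 duplicates
      nov <- seq_len(n_decoy)                                   # unknown-status rows
      dup_src <- sprintf("SRC%05d", cfg$n_genes + seq_len(n_decoy))
      nov_src <- sprintf("SRCNOV%04d", nov)
      annotation <- rbind(
        annotation,
        data.frame(source_id = dup_src, gene_name = genes[dup_genes],
                   status = "known", level = 2L, stringsAsFactors = FALSE),
        data.frame(source_id = nov_src,
                   gene_name = sprintf("NOVG%04d", nov),
                   status = "novel", level = 1L, stringsAsFactors = FALSE))
      decoy_counts <- matrix(
        stats::rpois(2 * n_decoy * n, lambda = 1), nrow = 2 * n_decoy,
        dimnames = list(c(dup_src, nov_src), sample_ids))
      counts <- rbind(counts, decoy_counts)
    }
    storage.mode(counts) <- "integer"
    list(counts = counts, labels = labels, strata = strata,
         annotation = annotation, signal_genes = signal_genes,
         size_factors_true = stats::setNames(sf, sample_ids),
         baseline_mu = mu)
  })
}

#' Write a simulated cohort to interchange files
#'
#' Emits the TSV/GMT dialects consumed by the readers: counts.tsv,
#' annotation.tsv, labels.tsv and panel.gmt, plus a manifest with MD5
#' checksums.
#'
#' @param cohort Result of [simulate_counts()].
#' @param panel A `pathway_panel`.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_cohort <- function(cohort, panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    counts = file.path(dir, "counts.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    labels = file.path(dir, "labels.tsv"),
    panel = file.path(dir, "panel.gmt"),
    manifest = file.path(dir, "manifest.json")
  )
  write_matrix_tsv(cohort$counts, paths$counts)
  utils::write.table(cohort$annotation, paths$annotation, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  labels_df <- data.frame(sample_id = names(cohort$labels),
                          label = as.integer(cohort$labels),
                          stratum = cohort$strata[names(cohort$labels)],
                          stringsAsFactors = FALSE)
  utils::write.table(labels_df, paths$labels, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_panel_gmt(panel, paths$panel)
  files <- unlist(paths[c("counts", "annotation", "labels", "panel")])
  manifest <- list(files = lapply(stats::setNames(as.list(files), names(files)),
                                  function(f) list(path = basename(f),
                                                   md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE)
  invisible(paths)
}
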