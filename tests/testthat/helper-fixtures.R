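# Shared fixture builders. Everything is generated in code, seeded.

suppressMessages(options(platimg.log_level = "WARN"))

# small integer count matrix with dimnames
toy_counts <- function(nrow = 6, ncol = 4, seed = 1, lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(nrow * ncol, lambda), nrow,
              dimnames = list(sprintf("F%02d", seq_len(nrow)),
                              sprintf("S%02d", seq_len(ncol))))
  storage.mode(m) <- "integer"
  m
}

# identity annotation: every feature known, level 1, name = id prefixed G
toy_annotation <- function(feature_ids) {
  data.frame(source_id = feature_ids,
             gene_name = sub("^F", "G", feature_ids),
             status = "known", level = 1L, stringsAsFactors = FALSE)
}

# brute-force median-of-ratios, written independently of size_factors()
oracle_size_factors <- function(counts) {
  ref <- apply(counts, 1, function(r) all(r > 0))
  geo <- apply(counts[ref, , drop = FALSE], 1,
               function(r) prod(r)^(1 / length(r)))
  vapply(seq_len(ncol(counts)), function(j) {
    median(counts[ref, j] / geo)
  }, 0)
}

# brute-force pairwise AUC
oracle_auc <- function(y, s) {
  cases <- s[y == 1]; ctrls <- s[y == 0]
  tot <- 0
  for (a in cases) for (b in ctrls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(ctrls))
}

# write a small GMT panel file
write_toy_gmt <- function(lines, path = tempfile(fileext = ".gmt")) {
  writeLines(lines, path)
  path
}

# compact simulated cohort + panel for mid-weight tests
toy_cohort <- function(n_case = 15, n_control = 15, n_genes = 300,
                       log2_fc = 2, seed = 42) {
  pool <- synth_gene_pool(n_genes)
  panel <- make_fixture_panel(2, 3, 2, pool, overlap_frac = 0.2,
                              len_range = c(8, 20), seed = seed)
  cfg <- simulation_config(n_case, n_control, n_genes = n_genes,
                           signal_pathways = panel$pathway_id[1:2],
                           log2_fc = log2_fc, seed = seed + 1)
  cohort <- simulate_counts(cfg, panel)
  list(cohort = cohort, panel = panel, cfg = cfg)
}
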