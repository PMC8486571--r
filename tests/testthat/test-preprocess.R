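# Sample filtering, gene mapping, size factors, dispersion trend and VST.

test_that("filter_samples enforces the strict read-depth boundary and is idempotent", {
  counts <- matrix(0L, nrow = 2, ncol = 3,
                   dimnames = list(c("F1", "F2"), c("low", "edge", "high")))
  counts[, 1] <- c(49999L, 50000L)   # total 99,999 -> excluded
  counts[, 2] <- c(50000L, 50000L)   # total exactly 100,000 -> retained
  counts[, 3] <- c(70000L, 80000L)
  out <- filter_samples(counts)
  expect_identical(colnames(out), c("edge", "high"))
  expect_identical(filter_samples(out), out)           # idempotent
  # all totals above threshold -> identity
  expect_identical(filter_samples(counts, min_total = 0), counts)
  # all removed -> empty-cohort error
  expect_error(filter_samples(counts, min_total = 1e9), "empty cohort")
})

test_that("map_genes applies status and level rules", {
  counts <- toy_counts(5, 3)
  annot <- data.frame(
    source_id = c("F01", "F02", "F03", "F04", "F05"),
    gene_name = c("GA", "GA", "GB", "GC", "GD"),
    status    = c("known", "known", "known", "novel", "known"),
    level     = c(2L, 1L, 1L, 1L, 3L),
    stringsAsFactors = FALSE)
  out <- map_genes(counts, annot)
  # duplicate GA: level-1 row (F02) wins over level-2 (F01)
  expect_identical(out["GA", ], counts["F02", ])
  # novel status dropped
  expect_false("GC" %in% rownames(out))
  expect_setequal(rownames(out), c("GA", "GB", "GD"))
})

test_that("map_genes tie at equal level keeps the larger-total row, bijective map renames only", {
  counts <- matrix(c(10L, 10L, 100L, 100L, 5L, 5L), nrow = 3, byrow = TRUE,
                   dimnames = list(c("F1", "F2", "F3"), c("S1", "S2")))
  annot <- data.frame(source_id = c("F1", "F2", "F3"),
                      gene_name = c("GX", "GX", "GY"),
                      status = "known", level = 1L, stringsAsFactors = FALSE)
  out <- map_genes(counts, annot)
  expect_identical(out["GX", ], counts["F2", ])        # larger total wins
  # bijective: counts unchanged, rows renamed
  cm <- toy_counts(4, 3, seed = 7)
  ann <- toy_annotation(rownames(cm))
  mapped <- map_genes(cm, ann)
  expect_identical(unname(mapped), unname(cm))
  expect_identical(rownames(mapped), sub("^F", "G", rownames(cm)))
  # nothing survives -> error
  ann$status <- "novel"
  expect_error(map_genes(cm, ann), "no features survive")
})

test_that("size_factors reproduces hand-derived and symmetric cases", {
  m <- matrix(c(1L, 2L, 4L, 2L, 4L, 8L), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(0.7071068, 1.4142136), tolerance = 1e-6)
  # identical columns -> all factors 1
  m2 <- matrix(rep(c(3L, 9L, 27L), 4), nrow = 3,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_equal(unname(size_factors(m2)), rep(1, 4))
  # a row containing zero must not influence the result
  m3 <- rbind(m, g4 = c(0L, 1000L))
  expect_equal(size_factors(m3), size_factors(m))
  # no all-positive row -> error mentioning the disabled fallback
  m4 <- matrix(c(0L, 5L, 5L, 0L), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors(m4), "pseudo-reference")
})

test_that("size_factors agrees with the brute-force median-of-ratios oracle", {
  for (i in 1:200) {
    set.seed(i)
    m <- matrix(rpois(100, 30) + 1L, nrow = 20,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:5)))
    m[sample(100, 10)] <- 0L   # some zeros to exercise the reference rule
    if (!any(apply(m, 1, function(r) all(r > 0)))) next
    expect_equal(unname(size_factors(m)), oracle_size_factors(m),
                 tolerance = 1e-12)
  }
})

test_that("size_factors matches DESeq2's estimator on a random matrix", {
  skip_if_not_installed("DESeq2")
  set.seed(3)
  # odd reference-set size: the ratio median is a single element, where the
  # plain-ratio and log-ratio median conventions coincide exactly
  m <- matrix(rnbinom(606, mu = 80, size = 5) + 1L, nrow = 101,
              dimnames = list(paste0("g", 1:101), paste0("s", 1:6)))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("dispersion trend recovers simulation parameters and handles Poisson data", {
  set.seed(11)
  n_genes <- 2000; n <- 60
  mu <- rlnorm(n_genes, log(50), 1)
  alpha <- 0.05 + 2 / mu
  counts <- matrix(rnbinom(n_genes * n, mu = mu, size = rep(1 / alpha, n)),
                   nrow = n_genes,
                   dimnames = list(paste0("g", 1:n_genes), paste0("s", 1:n)))
  storage.mode(counts) <- "integer"
  sf <- rep(1, n)
  trend <- fit_dispersion_trend(counts, sf)
  expect_gt(trend$a0, 0.05 * 0.5); expect_lt(trend$a0, 0.05 * 1.5)
  expect_gt(trend$a1, 2 * 0.5);    expect_lt(trend$a1, 2 * 1.5)

  # Poisson data: no overdispersion anywhere, so both coefficients collapse
  lam <- rlnorm(800, log(80), 1)
  pois <- matrix(rpois(800 * 100, lam), nrow = 800,
                 dimnames = list(paste0("g", 1:800), paste0("s", 1:100)))
  storage.mode(pois) <- "integer"
  tp <- fit_dispersion_trend(pois, rep(1, 100))
  expect_lt(tp$a0, 0.01)
  expect_lt(tp$a1, 0.5)

  # constant rows get zero method-of-moments dispersion
  cm <- matrix(5L, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  suppressWarnings(tc <- fit_dispersion_trend(cm, rep(1, 4)))
  expect_true(all(tc$per_gene_dispersion == 0))
})

test_that("vst is strictly monotone, hits the log2 limit, and stabilizes variance", {
  trend <- structure(list(a0 = 0.05, a1 = 2), class = "dispersion_trend")
  u <- c(0, 1, 5, 10, 20, 100, 1e4)
  v <- platimg:::vst_value(u, trend$a0, trend$a1)
  expect_true(all(diff(v) > 0))
  expect_true(all(is.finite(v)))

  # vst(2u) - vst(u) -> 1 as u -> Inf (log2 behavior), within 0.01 at u = 1e6
  d <- platimg:::vst_value(2e6, 0.05, 2) - platimg:::vst_value(1e6, 0.05, 2)
  expect_lt(abs(d - 1), 0.01)

  # variance stabilization: per-decile SD ratio < 2 on NB data under the trend
  set.seed(21)
  n_genes <- 2000; n <- 50
  mu <- rlnorm(n_genes, log(100), 1.2)
  alpha <- 0.05 + 2 / mu
  counts <- matrix(rnbinom(n_genes * n, mu = mu, size = rep(1 / alpha, n)),
                   nrow = n_genes,
                   dimnames = list(paste0("g", 1:n_genes), paste0("s", 1:n)))
  storage.mode(counts) <- "integer"
  vmat <- vst_transform(counts, rep(1, n), trend)
  sds <- apply(vmat, 1, sd)
  decile <- cut(rank(mu), 10)
  per_dec <- tapply(sds, decile, mean)
  expect_lt(max(per_dec) / min(per_dec), 2)
})

test_that("preprocess drops exactly the shallow sample and leaves remaining values unchanged", {
  cm <- toy_counts(60, 5, seed = 13, lambda = 3000)
  cm[, 2] <- 0L; cm[1, 2] <- 99999L       # sample 2 below any real threshold
  ann <- toy_annotation(rownames(cm))
  res <- suppressWarnings(preprocess_counts(cm, ann, min_total = 100000))
  expect_identical(res$qc$dropped_samples, "S02")
  expect_identical(ncol(res$normalized), 4L)
  # the other samples' values equal a run without the shallow sample present
  res2 <- suppressWarnings(preprocess_counts(cm[, -2], ann, min_total = 100000))
  expect_equal(res$normalized, res2$normalized)
})

test_that("tsv readers reject ragged rows with a line number and round-trip counts", {
  bad <- tempfile(); writeLines(c("feature\tS1\tS2", "F1\t1\t2", "F2\t3"), bad)
  expect_error(read_counts_tsv(bad), "line 3")
  cm <- toy_counts(8, 3)
  path <- tempfile()
  write_matrix_tsv(cm, path)
  back <- read_counts_tsv(path)
  expect_identical(back, cm)
})
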