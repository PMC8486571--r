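# Readers and writers for the plain-text interchange formats: count matrix
# TSV (feature id column + one integer column per sample), annotation TSV
# (source_id, gene_name, status, level) and label/strata TSV.  All readers
# reject ragged rows with a line-numbered error.

split_tsv_lines <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stopf("'%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1]
    stopf("'%s': ragged row at line %d (%d fields, expected %d)",
          path, bad, widths[bad], widths[1])
  }
  fields
}

#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a header row of sample identifiers, a first column of feature
#' identifiers, and nonnegative integer cells.
#'
#' @param path Path to a tab-separated file.
#' @return Integer matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @export
read_counts_tsv <- function(path) {
  fields <- split_tsv_lines(path)
  header <- fields[[1]]
  sample_ids <- header[-1]
  body <- fields[-1]
  feature_ids <- vapply(body, `[[`, "", 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(length(sample_ids)))
  )
  mat <- if (is.null(dim(vals))) matrix(vals, nrow = 1) else t(vals)
  dimnames(mat) <- list(feature_ids, sample_ids)
  validate_counts(mat)
  storage.mode(mat) <- "integer"
  mat
}

#' Validate a count matrix
#'
#' Checks the count-matrix contract: nonnegative integral counts, unique
#' feature and sample identifiers.
#'
#' @param counts Numeric matrix with dimnames.
#' @return The matrix, invisibly.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts)) stopf("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("counts must carry feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) stopf("feature ids are not unique")
  if (anyDuplicated(colnames(counts))) stopf("sample ids are not unique")
  if (anyNA(counts)) stopf("counts contain missing or non-numeric cells")
  if (any(counts < 0)) stopf("counts contain negative values")
  if (any(counts != round(counts))) stopf("counts contain non-integral values")
  invisible(counts)
}

#' Write a matrix to TSV
#'
#' First column holds rownames under the header `feature`; remaining columns
#' are the matrix columns.
#'
#' @param mat Matrix with dimnames.
#' @param path Output path.
#' @param id_col Header for the identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "feature") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table from TSV
#'
#' Columns: `source_id`, `gene_name`, `status`, `level` (annotation
#' confidence tier, smaller is higher confidence).
#'
#' @param path Path to a tab-separated file with a header row.
#' @return data.frame with the four columns, `level` integer.
#' @export
read_annotation_tsv <- function(path) {
  fields <- split_tsv_lines(path)
  header <- fields[[1]]
  need <- c("source_id", "gene_name", "status", "level")
  if (!all(need %in% header)) {
    stopf("'%s': annotation header must contain %s", path,
          paste(need, collapse = ", "))
  }
  body <- fields[-1]
  get <- function(col) vapply(body, `[[`, "", match(col, header))
  annot <- data.frame(
    source_id = get("source_id"),
    gene_name = get("gene_name"),
    status    = get("status"),
    level     = as.integer(get("level")),
    stringsAsFactors = FALSE
  )
  validate_annotation(annot)
}

#' Validate a gene annotation table
#' @param annot data.frame with source_id, gene_name, status, level.
#' @return The validated data.frame (invisibly usable).
#' @export
validate_annotation <- function(annot) {
  need <- c("source_id", "gene_name", "status", "level")
  if (!all(need %in% colnames(annot))) {
    stopf("annotation must contain columns %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(annot$source_id)) stopf("annotation source_id not unique")
  if (anyNA(annot$level) || any(annot$level < 1)) {
    stopf("annotation level must be an integer >= 1")
  }
  annot
}

#' Read sample labels and strata from TSV
#'
#' Columns: `sample_id`, `label` (0 = control, 1 = case) and optionally
#' `stratum` (e.g. case / benign / healthy) for stratified splitting.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return data.frame with sample_id, label (integer) and stratum columns.
#' @export
read_labels_tsv <- function(path) {
  fields <- split_tsv_lines(path)
  header <- fields[[1]]
  if (!all(c("sample_id", "label") %in% header)) {
    stopf("'%s': labels header must contain sample_id and label", path)
  }
  body <- fields[-1]
  get <- function(col) vapply(body, `[[`, "", match(col, header))
  out <- data.frame(
    sample_id = get("sample_id"),
    label     = as.integer(get("label")),
    stringsAsFactors = FALSE
  )
  out$stratum <- if ("stratum" %in% header) get("stratum") else
    ifelse(out$label == 1, "case", "control")
  if (anyDuplicated(out$sample_id)) stopf("duplicate sample_id in labels")
  if (!all(out$label %in% c(0L, 1L))) stopf("labels must be 0 or 1")
  out
}
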