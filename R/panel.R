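# Pathway panel handling: a categorized GMT dialect (cancer / signaling /
# metabolism in the description field), pruning against expressed genes,
# global intensity scaling and sample-image construction.

.panel_categories <- c("cancer", "signaling", "metabolism")

new_pathway_panel <- function(ids, names, categories, genes) {
  panel <- list(pathway_id = ids, display_name = names,
                category = categories, genes = genes)
  class(panel) <- "pathway_panel"
  panel
}

#' @export
length.pathway_panel <- function(x) length(x$pathway_id)

#' @export
print.pathway_panel <- function(x, ...) {
  tab <- table(factor(x$category, levels = .panel_categories))
  cat(sprintf(
    "pathway panel: %d pathways (%s), longest %d genes\n",
    length(x),
    paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
    if (length(x)) max(lengths(x$genes)) else 0L))
  invisible(x)
}

#' Read a categorized pathway panel from a GMT file
#'
#' Standard GMT layout (set name TAB description TAB member genes...), with
#' the description field carrying the category token `cancer`, `signaling`
#' or `metabolism`, optionally followed by `|display name`. Entries are
#' returned in canonical category order — the cancer block first, then
#' signaling, then metabolism — preserving file order within each block.
#'
#' @param path Path to the GMT file.
#' @return A `pathway_panel` object.
#' @export
read_panel <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  if (length(fields) == 0) stopf("'%s' contains no pathways", path)

  ids <- character(0); names_ <- character(0)
  cats <- character(0); genes <- list()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3) {
      stopf("'%s' line %d: pathway '%s' has an empty gene list",
            path, lineno[i], f[1])
    }
    desc <- strsplit(f[2], "|", fixed = TRUE)[[1]]
    cat_tok <- desc[1]
    if (!cat_tok %in% .panel_categories) {
      stopf("'%s' line %d: unknown category '%s' (expected %s)",
            path, lineno[i], cat_tok, paste(.panel_categories, collapse = "/"))
    }
    ids <- c(ids, f[1])
    names_ <- c(names_, if (length(desc) > 1) desc[2] else f[1])
    cats <- c(cats, cat_tok)
    genes <- c(genes, list(f[-(1:2)]))
  }
  if (anyDuplicated(ids)) {
    stopf("'%s': duplicated pathway_id '%s'", path, ids[duplicated(ids)][1])
  }
  ord <- order(match(cats, .panel_categories))
  new_pathway_panel(ids[ord], names_[ord], cats[ord], genes[ord])
}

#' Write a pathway panel to a GMT file
#'
#' @param panel A `pathway_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_gmt <- function(panel, path) {
  lines <- vapply(seq_along(panel$pathway_id), function(i) {
    desc <- if (panel$display_name[i] == panel$pathway_id[i]) {
      panel$category[i]
    } else {
      paste0(panel$category[i], "|", panel$display_name[i])
    }
    paste(c(panel$pathway_id[i], desc, panel$genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Prune a panel against the expressed gene set
#'
#' Filters every pathway's gene list to the genes present in `expressed`,
#' preserving internal order. Pathways left with no expressed gene are
#' dropped with a logged warning count.
#'
#' @param panel A `pathway_panel`.
#' @param expressed Character vector of expressed gene names.
#' @return The pruned `pathway_panel`.
#' @export
prune_panel <- function(panel, expressed) {
  pruned <- lapply(panel$genes, function(g) g[g %in% expressed])
  nonempty <- lengths(pruned) > 0
  if (!any(nonempty)) stopf("all pathways empty after pruning")
  if (any(!nonempty)) {
    pl_log("WARN", sprintf("prune_panel: dropped %d pathway(s) with no expressed genes",
                           sum(!nonempty)))
  }
  new_pathway_panel(panel$pathway_id[nonempty], panel$display_name[nonempty],
                    panel$category[nonempty], pruned[nonempty])
}

#' Image dimensions implied by a pruned panel
#' @param panel A pruned `pathway_panel`.
#' @return Integer vector `c(height, width)`: number of pathways and
#'   longest pathway length.
#' @export
panel_image_dims <- function(panel) {
  c(height = length(panel), width = max(lengths(panel$genes)))
}

# Intensity scaler ---------------------------------------------------------

#' Fit the global intensity scaler
#'
#' Records the global minimum and maximum transformed expression over the
#' training samples restricted to panel genes. Pixel intensities are later
#' min-max scaled with these bounds (values outside, e.g. on test samples,
#' are clipped).
#'
#' @param values Numeric matrix or vector of transformed expression on the
#'   reference/training set.
#' @return An `intensity_scaler` with fields `v_min`, `v_max`.
#' @export
fit_scaler <- function(values) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2) stopf("cannot fit scaler: fewer than 2 distinct values")
  scaler <- list(v_min = min(v), v_max = max(v))
  class(scaler) <- "intensity_scaler"
  scaler
}

#' @export
print.intensity_scaler <- function(x, ...) {
  cat(sprintf("intensity scaler: [%.17g, %.17g]\n", x$v_min, x$v_max))
  invisible(x)
}

#' Persist an intensity scaler to JSON (bit-exact)
#' @param scaler An `intensity_scaler`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scaler <- function(scaler, path) {
  jsonlite::write_json(list(v_min = scaler$v_min, v_max = scaler$v_max),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload an intensity scaler from JSON
#' @param path Path written by [write_scaler()].
#' @return An `intensity_scaler`.
#' @export
read_scaler <- function(path) {
  x <- jsonlite::read_json(path)
  scaler <- list(v_min = as.numeric(x$v_min), v_max = as.numeric(x$v_max))
  class(scaler) <- "intensity_scaler"
  scaler
}

# Sample images ------------------------------------------------------------

#' Build the pathway-panel image for one sample
#'
#' Produces an `H x W` grid (H = number of pathways, W = longest pathway
#' length). Pixel `(i, j)` holds the min-max-scaled, `[0,1]`-clipped
#' expression of the j-th gene of pathway i; positions beyond a pathway's
#' length are zero-padded (black). A gene belonging to several pathways
#' contributes one pixel per membership.
#'
#' @param values Named numeric vector: one sample's transformed expression.
#' @param panel A pruned `pathway_panel`.
#' @param scaler An `intensity_scaler`.
#' @param sample_id Identifier stored with the image.
#' @return A `sample_image`: list with `sample_id` and `grid`.
#' @export
build_image <- function(values, panel, scaler, sample_id = "sample") {
  dims <- panel_image_dims(panel)
  grid <- matrix(0, nrow = dims["height"], ncol = dims["width"])
  span <- scaler$v_max - scaler$v_min
  for (i in seq_len(dims[["height"]])) {
    g <- panel$genes[[i]]
    v <- values[g]
    if (anyNA(v)) {
      stopf("internal inconsistency: gene(s) %s of pathway '%s' missing from sample vector",
            paste(g[is.na(v)], collapse = ", "), panel$pathway_id[i])
    }
    grid[i, seq_along(g)] <- pmin(pmax((v - scaler$v_min) / span, 0), 1)
  }
  img <- list(sample_id = sample_id, grid = grid)
  class(img) <- "sample_image"
  img
}

#' Build images for every sample of a normalized matrix
#'
#' @param normalized Gene-by-sample matrix of transformed expression.
#' @param panel A pruned `pathway_panel`.
#' @param scaler An `intensity_scaler`.
#' @param labels Optional named 0/1 vector stored alongside.
#' @return An `image_set`: list with `images` (N x H x W array),
#'   `sample_ids`, `labels`, `scaler` and panel dimensions.
#' @export
build_image_set <- function(normalized, panel, scaler, labels = NULL) {
  dims <- panel_image_dims(panel)
  n <- ncol(normalized)
  arr <- array(0, dim = c(n, dims[["height"]], dims[["width"]]))
  for (s in seq_len(n)) {
    img <- build_image(normalized[, s], panel, scaler,
                       sample_id = colnames(normalized)[s])
    arr[s, , ] <- img$grid
  }
  out <- list(
    images = arr,
    sample_ids = colnames(normalized),
    labels = if (is.null(labels)) NULL else labels[colnames(normalized)],
    scaler = scaler,
    height = dims[["height"]],
    width = dims[["width"]],
    pathway_ids = panel$pathway_id
  )
  class(out) <- "image_set"
  out
}

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("image set: %d samples, %d x %d pixels\n",
              length(x$sample_ids), x$height, x$width))
  invisible(x)
}

#' Persist an image set container
#'
#' Stores the image tensor with its sample ids, labels and scaler
#' attributes in a single RDS container.
#'
#' @param image_set An `image_set`.
#' @param path Output path (`.rds`).
#' @return `path`, invisibly.
#' @export
write_image_container <- function(image_set, path) {
  saveRDS(image_set, path)
  invisible(path)
}

#' Reload an image set container
#' @param path Path written by [write_image_container()].
#' @return An `image_set`.
#' @export
read_image_container <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "image_set")) stopf("'%s' is not an image container", path)
  x
}

#' Export a sample image as an 8-bit RGB PNG
#'
#' The red channel carries the quantized intensity (`round(value * 255)`),
#' green and blue are zero: zero expression renders black, maximal
#' expression pure red.
#'
#' @param image A `sample_image`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
export_png <- function(image, path) {
  g <- image$grid
  rgb <- array(0, dim = c(nrow(g), ncol(g), 3))
  rgb[, , 1] <- round(g * 255) / 255
  png::writePNG(rgb, path)
  invisible(path)
}

#' Read back the red channel of an exported PNG
#' @param path PNG path written by [export_png()].
#' @return Matrix of quantized intensities in `[0, 1]`.
#' @export
read_png_grid <- function(path) {
  arr <- png::readPNG(path)
  arr[, , 1]
}
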