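#' Construct a multichannel core image stack
#'
#' A `core_stack` holds one named 2-D raster per antibody channel for a single
#' tissue core, at a stated resolution (IMC is acquired at roughly 1 um per
#' pixel). All rasters must share dimensions and hold finite, nonnegative
#' pixel counts.
#'
#' @param core_id single string identifying the core.
#' @param channels named list of numeric matrices (one per marker).
#' @param pixel_size_um pixel edge length in micrometres (default 1).
#' @return an object of class `core_stack`.
#' @export
core_stack <- function(core_id, channels, pixel_size_um = 1.0) {
  stopifnot(is.character(core_id), length(core_id) == 1L, is.list(channels))
  nm <- names(channels)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
    stop("channels must be uniquely named by marker")
  dims <- vapply(channels, dim, integer(2))
  if (length(channels) > 1L && any(dims != dims[, 1]))
    stop("all channel rasters must share identical dimensions")
  for (k in nm) {
    ch <- channels[[k]]
    if (!is.matrix(ch) || !is.numeric(ch))
      stop("channel '", k, "' is not a numeric matrix")
    if (any(!is.finite(ch)) || any(ch < 0))
      stop("channel '", k, "' contains non-finite or negative values")
  }
  structure(
    list(core_id = core_id, channels = channels,
         pixel_size_um = as.numeric(pixel_size_um)),
    class = "core_stack"
  )
}

#' @export
print.core_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<core_stack> core '%s': %d channels, %d x %d px (%.2g um/px)\n",
              x$core_id, length(x$channels), d[1], d[2], x$pixel_size_um))
  invisible(x)
}

#' @export
dim.core_stack <- function(x) dim(x$channels[[1]])

#' Mask construction parameters for one marker
#'
#' Parameters of the five-step binary mask procedure: median smoothing window,
#' number of k-means intensity levels, how many of the brightest levels count
#' as foreground, minimum connected-blob area, and the optional adaptive
#' refinement with its sensitivity.
#'
#' @param median_window odd window size of the median smoothing (default 3).
#' @param n_levels number of intensity levels for quantization (default 6).
#' @param foreground_level how many of the top (brightest) levels are kept as
#'   foreground; must be in `[1, n_levels]`. The default `NULL` curates the
#'   level per channel by the largest-gap rule: foreground starts above the
#'   biggest jump between consecutive level means (bright-on-dark marker
#'   signal separates from background at that jump), which stands in for
#'   the manual per-marker curation the procedure expects.
#' @param min_blob_area connected components smaller than this many pixels are
#'   removed (default 4).
#' @param adaptive_merge whether to intersect with a locally adaptive
#'   threshold mask as a final refinement step (default FALSE).
#' @param adaptive_sensitivity sensitivity of the adaptive threshold in
#'   `[0, 1]` (default 0.4).
#' @return an object of class `mask_params`.
#' @export
mask_params <- function(median_window = 3L, n_levels = 6L,
                        foreground_level = NULL, min_blob_area = 4L,
                        adaptive_merge = FALSE, adaptive_sensitivity = 0.4) {
  median_window <- as.integer(median_window)
  n_levels <- as.integer(n_levels)
  foreground_level <- if (is.null(foreground_level)) NA_integer_ else
    as.integer(foreground_level)
  if (median_window < 1L || median_window %% 2L == 0L)
    stop("median_window must be an odd integer >= 1")
  if (n_levels < 2L) stop("n_levels must be >= 2")
  if (!is.na(foreground_level) &&
      (foreground_level < 1L || foreground_level > n_levels))
    stop("foreground_level must lie in [1, n_levels]")
  if (min_blob_area < 0) stop("min_blob_area must be >= 0")
  if (adaptive_sensitivity < 0 || adaptive_sensitivity > 1)
    stop("adaptive_sensitivity must lie in [0, 1]")
  structure(
    list(median_window = median_window, n_levels = n_levels,
         foreground_level = foreground_level,
         min_blob_area = as.integer(min_blob_area),
         adaptive_merge = isTRUE(adaptive_merge),
         adaptive_sensitivity = adaptive_sensitivity),
    class = "mask_params"
  )
}

#' Construct a marker panel
#'
#' The panel declares, for every antibody channel, whether it is a lineage
#' marker (used to type cells), a functional marker (used to flag cell
#' states such as Ki-67 positivity), or excluded from analysis; the rank
#' priority used to break majority-vote ties (lineage markers only, lower
#' rank wins); and the per-marker mask construction parameters, mirroring
#' how masks are curated marker by marker in practice.
#'
#' @param markers data.frame with columns `name`, `role`
#'   (`"lineage"`/`"functional"`/`"excluded"`), `priority_rank` (integer, NA
#'   for non-lineage markers).
#' @param mask_params named list of [mask_params()] objects, one per marker;
#'   markers not listed get the defaults.
#' @return an object of class `marker_panel`.
#' @export
marker_panel <- function(markers, mask_params = list()) {
  stopifnot(is.data.frame(markers),
            all(c("name", "role") %in% names(markers)))
  markers$name <- as.character(markers$name)
  if (anyDuplicated(markers$name)) stop("marker names must be unique")
  if (!all(markers$role %in% c("lineage", "functional", "excluded")))
    stop("role must be one of lineage/functional/excluded")
  if (!"priority_rank" %in% names(markers)) markers$priority_rank <- NA_integer_
  lin <- markers$role == "lineage"
  pr <- markers$priority_rank[lin]
  if (any(is.na(pr)) || anyDuplicated(pr))
    stop("lineage markers need unique priority_rank values")
  mp <- lapply(markers$name, function(nm) {
    p <- mask_params[[nm]] %||% imctme::mask_params()
    stopifnot(inherits(p, "mask_params"))
    p
  })
  names(mp) <- markers$name
  structure(list(markers = markers, mask_params = mp), class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  tab <- table(x$markers$role)
  cat(sprintf("<marker_panel> %d markers (%s)\n", nrow(x$markers),
              paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Lineage marker names of a panel, in priority order
#' @param panel a [marker_panel()].
#' @return character vector of lineage marker names ordered by priority rank.
#' @export
lineage_markers <- function(panel) {
  m <- panel$markers[panel$markers$role == "lineage", ]
  m$name[order(m$priority_rank)]
}

#' Functional marker names of a panel
#' @param panel a [marker_panel()].
#' @return character vector.
#' @export
functional_markers <- function(panel) {
  panel$markers$name[panel$markers$role == "functional"]
}

#' Construct a segmentation map
#'
#' Contract type for external cell segmentation: an integer label raster
#' (0 = background, k > 0 = cell k) plus the derived per-cell pixel lists
#' and centroids. Pixel coordinates are 0-based `(row, col)` with origin at
#' the top-left; centroids are arithmetic means of pixel coordinates.
#'
#' @param core_id single string.
#' @param label_raster integer matrix of cell labels.
#' @return an object of class `segmentation_map` with elements `core_id`,
#'   `label_raster`, `cells` (list of 0-based `cbind(row, col)` matrices named
#'   by cell id) and `centroids` (data.frame `cell_id`, `row`, `col`).
#' @export
segmentation_map <- function(core_id, label_raster) {
  stopifnot(is.matrix(label_raster))
  storage.mode(label_raster) <- "integer"
  if (any(label_raster < 0L)) stop("labels must be >= 0")
  ids <- sort(unique(label_raster[label_raster > 0L]))
  idx <- which(label_raster > 0L)
  ord <- order(label_raster[idx])
  idx <- idx[ord]
  labs <- label_raster[idx]
  nr <- nrow(label_raster)
  rows0 <- (idx - 1L) %% nr
  cols0 <- (idx - 1L) %/% nr
  cells <- split(data.frame(row = rows0, col = cols0), labs)
  cells <- lapply(cells, function(d) cbind(row = d$row, col = d$col))
  names(cells) <- as.character(ids)
  centroids <- data.frame(
    cell_id = ids,
    row = vapply(cells, function(p) mean(p[, "row"]), numeric(1)),
    col = vapply(cells, function(p) mean(p[, "col"]), numeric(1)),
    row.names = NULL
  )
  structure(
    list(core_id = core_id, label_raster = label_raster,
         cells = cells, centroids = centroids),
    class = "segmentation_map"
  )
}

#' @export
print.segmentation_map <- function(x, ...) {
  cat(sprintf("<segmentation_map> core '%s': %d cells in %d x %d px\n",
              x$core_id, length(x$cells), nrow(x$label_raster),
              ncol(x$label_raster)))
  invisible(x)
}

#' Validate a cell table
#'
#' A cell table has one row per segmented cell: identifiers, centroid,
#' lineage call, per-channel mean expression (`expr_*` columns) and
#' functional positivity flags (`pos_*` columns).
#'
#' @param table data.frame to validate.
#' @param lineage_levels allowed lineage labels (the configured cell types
#'   plus `"undefined"`); NULL skips the label check.
#' @return the validated data.frame (invisibly classed `cell_table`).
#' @export
validate_cell_table <- function(table, lineage_levels = NULL) {
  need <- c("cell_id", "core_id", "row", "col", "lineage")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("cell table misses columns: ", paste(miss, collapse = ", "))
  expr_cols <- grep("^expr_", names(table), value = TRUE)
  if (length(expr_cols)) {
    bad <- !vapply(table[expr_cols], function(v) all(is.finite(v)), logical(1))
    if (any(bad)) stop("non-finite expression in: ", paste(expr_cols[bad], collapse = ", "))
  }
  if (!is.null(lineage_levels)) {
    bad <- !(table$lineage %in% c(lineage_levels, "undefined"))
    if (any(bad)) {
      stop("unknown lineage label(s) at row(s) ",
           paste(head(which(bad), 10), collapse = ", "), ": ",
           paste(unique(table$lineage[bad]), collapse = ", "))
    }
  }
  class(table) <- unique(c("cell_table", class(table)))
  table
}

#' Validate a clinical table
#'
#' One row per patient with core mapping and outcomes. Histology must be one
#' of the five lung adenocarcinoma growth patterns; survival times must be
#' nonnegative; each core maps to exactly one patient.
#'
#' @param table data.frame with at least `patient_id`, `core_ids`
#'   (semicolon-separated string), `histology`, `progression`,
#'   `survival_months`, `event`.
#' @return the validated data.frame.
#' @export
validate_clinical_table <- function(table) {
  need <- c("patient_id", "core_ids", "histology", "progression",
            "survival_months", "event")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("clinical table misses columns: ", paste(miss, collapse = ", "))
  pats <- c("lepidic", "papillary", "acinar", "micropapillary", "solid")
  if (!all(table$histology %in% pats))
    stop("histology must be one of: ", paste(pats, collapse = ", "))
  if (any(table$survival_months < 0)) stop("survival_months must be >= 0")
  cores <- unlist(strsplit(table$core_ids, ";", fixed = TRUE))
  if (anyDuplicated(cores)) stop("a core maps to more than one patient")
  table
}

#' Expand a clinical table to one row per core
#' @param clinical validated clinical table.
#' @return data.frame with a `core_id` column, one row per core.
#' @export
clinical_by_core <- function(clinical) {
  reps <- strsplit(clinical$core_ids, ";", fixed = TRUE)
  out <- clinical[rep(seq_len(nrow(clinical)), lengths(reps)), , drop = FALSE]
  out$core_id <- unlist(reps)
  rownames(out) <- NULL
  out
}
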