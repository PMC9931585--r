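#' Median smoothing of a channel raster
#'
#' Step 1 of the mask procedure: every pixel is replaced by the median of an
#' odd square window centred on it, with borders handled by edge
#' replication. Smoothing suppresses isolated hot pixels, a common IMC
#' artefact, before intensity quantization.
#'
#' @param channel numeric matrix.
#' @param window odd window size (default 3, i.e. 3x3).
#' @return numeric matrix of the same dimensions.
#' @export
median_smooth <- function(channel, window = 3L) {
  stopifnot(is.matrix(channel), is.numeric(channel))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  if (window == 1L) return(channel)
  .median_filter_cpp(channel, window)
}

#' Quantize a raster into ordered intensity levels
#'
#' Step 2: pixel intensities are clustered one-dimensionally into `n_levels`
#' groups by k-means; clusters are re-indexed so that level 1 has the lowest
#' mean intensity. Because the one-dimensional k-means optimum consists of
#' contiguous intervals of the sorted intensities, the globally optimal
#' clustering is computed exactly by dynamic programming over the distinct
#' values, which removes any dependence on initialisation: identical inputs
#' always yield identical levels.
#'
#' If the raster has fewer distinct values than `n_levels`, levels collapse
#' to the distinct-value count with a warning.
#'
#' Rasters with many distinct intensities (continuous data) are first
#' histogrammed into at most `max_bins` equal-width bins, whose weighted
#' means feed the exact solver; the bin width is far below the noise scale
#' of real counts, so this does not affect the levels in practice.
#'
#' @param raster numeric matrix.
#' @param n_levels number of intensity levels (default 6).
#' @param seed accepted for interface stability; the exact solver is
#'   deterministic and does not consume randomness.
#' @param max_bins histogram resolution for continuous rasters (default 2048).
#' @return integer matrix of levels in `1..L` with attribute `level_means`.
#' @export
quantize_levels <- function(raster, n_levels = 6L, seed = 0L,
                            max_bins = 2048L) {
  stopifnot(is.matrix(raster), is.numeric(raster), all(is.finite(raster)))
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("n_levels must be >= 2")
  v <- as.vector(raster)
  uq <- sort(unique(v))
  if (length(uq) <= max_bins) {
    bin <- findInterval(v, uq)
    vals <- uq
    w <- as.numeric(tabulate(bin, length(uq)))
  } else {
    breaks <- seq(min(v), max(v), length.out = max_bins + 1L)
    bin0 <- findInterval(v, breaks, rightmost.closed = TRUE,
                         all.inside = TRUE)
    cnt <- tabulate(bin0, max_bins)
    keep <- which(cnt > 0L)
    vals <- as.numeric(rowsum(v, bin0)[, 1]) / cnt[keep]
    w <- as.numeric(cnt[keep])
    bin <- match(bin0, keep)
  }
  k <- n_levels
  if (length(vals) < n_levels) {
    k <- length(vals)
    tme_log("warn", "raster has ", k, " distinct values < n_levels = ",
            n_levels, "; collapsing to ", k, " level(s)")
  }
  lab_by_val <- if (k == 1L) 1L else .kmeans1d_cpp(vals, w, k)
  lev <- matrix(lab_by_val[bin], nrow(raster), ncol(raster))
  means <- vapply(seq_len(k), function(l) {
    sel <- lab_by_val == l
    sum(vals[sel] * w[sel]) / sum(w[sel])
  }, numeric(1))
  attr(lev, "level_means") <- means
  lev
}

#' Select foreground levels
#'
#' Step 3: keep the brightest `foreground_level` intensity groups as
#' foreground (marker signal is bright on a dark background), i.e. a pixel
#' is foreground iff its level is at least `max_level - foreground_level + 1`.
#'
#' @param level_raster integer matrix from [quantize_levels()].
#' @param foreground_level number of top levels kept; in `[1, max level]`.
#' @return logical matrix.
#' @export
select_foreground <- function(level_raster, foreground_level) {
  stopifnot(is.matrix(level_raster))
  max_level <- max(level_raster)
  foreground_level <- as.integer(foreground_level)
  if (foreground_level < 1L || foreground_level > max_level)
    stop("foreground_level must lie in [1, ", max_level, "]")
  level_raster >= (max_level - foreground_level + 1L)
}

#' Remove small connected blobs from a binary mask
#'
#' Step 4: 8-connected components with fewer than `min_area` pixels are set
#' to background, removing noisy specks. Idempotent.
#'
#' @param mask logical matrix.
#' @param min_area minimum component area in pixels to keep.
#' @return logical matrix.
#' @export
remove_small_blobs <- function(mask, min_area) {
  stopifnot(is.matrix(mask), is.logical(mask), min_area >= 0)
  if (min_area <= 1L || !any(mask)) return(mask)
  lab <- .label_components_cpp(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  mask & matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Adaptive refinement of a mask
#'
#' Step 5: an additional, locally adaptive binary mask is computed and
#' intersected with the input mask. The local threshold at pixel `p` is
#' `mean_15x15(p) * (1 - sensitivity * (1 - I(p)/max(I)))`: bright pixels
#' (relative to the channel maximum) get a proportionally lowered threshold,
#' so locally bright structure survives while flat regions are suppressed.
#' Because the result is an intersection, refinement can only remove
#' foreground, never add it.
#'
#' @param channel numeric matrix (the smoothed channel).
#' @param mask logical matrix to refine.
#' @param sensitivity fraction in `[0, 1]` (default 0.4).
#' @param window local-mean window (default 15).
#' @return logical matrix, a subset of `mask`.
#' @export
adaptive_refine <- function(channel, mask, sensitivity = 0.4, window = 15L) {
  stopifnot(is.matrix(channel), is.matrix(mask),
            all(dim(channel) == dim(mask)))
  if (sensitivity < 0 || sensitivity > 1) stop("sensitivity must be in [0, 1]")
  mx <- max(channel)
  if (mx <= 0) return(mask & FALSE)
  local_mean <- .box_mean_cpp(channel, as.integer(window))
  thr <- local_mean * (1 - sensitivity * (1 - channel / mx))
  mask & (channel > thr)
}

#' Curate the foreground level by the largest-gap rule
#'
#' Marker signal is bright on a dark background, so the ordered level means
#' separate into a background run and a signal run. This helper places the
#' foreground cut above the largest jump between consecutive level means
#' and returns the number of top levels kept, standing in for per-marker
#' manual curation when no explicit level is configured.
#'
#' @param level_means ascending level means from [quantize_levels()].
#' @return integer foreground level (number of top levels kept).
#' @export
curate_foreground_level <- function(level_means) {
  L <- length(level_means)
  if (L == 1L) return(1L)
  gaps <- diff(level_means)
  L - which.max(gaps)
}

#' Build the binary mask for one marker channel
#'
#' Composes the five mask steps: median smoothing, intensity-level
#' quantization, foreground selection, small-blob removal and (optionally)
#' adaptive refinement, using the per-marker [mask_params()]. The result is
#' fully determined by the channel and parameters.
#'
#' @param channel numeric matrix (raw counts).
#' @param params a [mask_params()] object.
#' @param marker marker name recorded on the result.
#' @param seed forwarded to [quantize_levels()] (kept for interface
#'   stability; the pipeline is deterministic).
#' @return an object of class `marker_mask` with fields `marker`, `mask`
#'   (logical matrix) and `params_used`.
#' @export
build_marker_mask <- function(channel, params = mask_params(),
                              marker = "marker", seed = 0L) {
  stopifnot(inherits(params, "mask_params"))
  sm <- median_smooth(channel, params$median_window)
  lev <- quantize_levels(sm, params$n_levels, seed)
  fg_level <- if (is.na(params$foreground_level))
    curate_foreground_level(attr(lev, "level_means"))
  else min(params$foreground_level, max(lev))
  mask <- select_foreground(lev, fg_level)
  if (max(lev) == 1L) {
    # constant raster: a single level carries no contrast, call it background
    mask[] <- FALSE
  }
  mask <- remove_small_blobs(mask, params$min_blob_area)
  if (params$adaptive_merge)
    mask <- adaptive_refine(sm, mask, params$adaptive_sensitivity)
  structure(list(marker = marker, mask = mask, params_used = params),
            class = "marker_mask")
}

#' Build masks for every panel marker of a core
#'
#' @param stack a [core_stack()].
#' @param panel a [marker_panel()]; only `lineage` and `functional` markers
#'   get masks.
#' @param seed forwarded to [build_marker_mask()].
#' @return named list of `marker_mask` objects.
#' @export
build_panel_masks <- function(stack, panel, seed = 0L) {
  use <- panel$markers$name[panel$markers$role != "excluded"]
  miss <- setdiff(use, names(stack$channels))
  if (length(miss))
    stop("stack '", stack$core_id, "' misses panel channel(s): ",
         paste(miss, collapse = ", "))
  masks <- lapply(use, function(nm) {
    build_marker_mask(stack$channels[[nm]], panel$mask_params[[nm]],
                      marker = nm, seed = seed)
  })
  names(masks) <- use
  masks
}
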