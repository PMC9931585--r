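#' Per-cell majority vector over lineage marker masks
#'
#' For each pixel of a cell, the presence vector records which lineage
#' marker masks contain it; the majority vector is the per-marker sum of
#' those presence bits over all of the cell's pixels, i.e. `counts[k]` is
#' the number of the cell's pixels that are foreground in mask `k`.
#'
#' @param pixels 0-based `cbind(row, col)` pixel coordinates of one cell.
#' @param masks named list of `marker_mask` objects (or logical matrices)
#'   covering all lineage markers.
#' @param markers lineage marker names, in panel priority order.
#' @return list with `counts` (named integer vector) and `n_pixels`.
#' @export
majority_vector <- function(pixels, masks, markers) {
  stopifnot(is.matrix(pixels), nrow(pixels) >= 1L)
  miss <- setdiff(markers, names(masks))
  if (length(miss)) stop("missing mask(s) for marker(s): ",
                         paste(miss, collapse = ", "))
  counts <- vapply(markers, function(k) {
    m <- masks[[k]]
    if (inherits(m, "marker_mask")) m <- m$mask
    idx <- pixels[, "row"] + 1L + nrow(m) * pixels[, "col"]
    sum(m[idx])
  }, numeric(1))
  list(counts = as.integer(counts), markers = markers,
       n_pixels = nrow(pixels))
}

#' Default one-to-one lineage rules for a panel
#'
#' Maps each lineage marker to a cell-type label. Rules may carry a
#' secondary marker that splits the type in two (e.g. CD68 macrophages
#' split by CD163 into CD163+ and CD163- subsets, resolved by whether the
#' secondary mask covers at least half of the cell's pixels).
#'
#' @param markers character vector of lineage marker names.
#' @param types cell-type label per marker (defaults to the marker name).
#' @return data.frame with columns `marker`, `type`, `secondary_marker`,
#'   `secondary_type`, class `type_rules`.
#' @export
type_rules <- function(markers, types = markers) {
  stopifnot(length(markers) == length(types))
  out <- data.frame(marker = markers, type = types,
                    secondary_marker = NA_character_,
                    secondary_type = NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("type_rules", class(out))
  out
}

#' Assign a cell's lineage from its majority vector
#'
#' The marker with the maximum count wins; ties are broken by the panel's
#' rank priority (lower rank wins); an all-zero vector yields
#' `"undefined"` rather than forcing a call. If the winning rule carries a
#' secondary marker, the cell takes the secondary type when the secondary
#' mask covers at least half of its pixels.
#'
#' @param mv result of [majority_vector()].
#' @param panel a [marker_panel()].
#' @param rules a [type_rules()] data.frame.
#' @param masks masks list (needed only when secondary rules exist).
#' @param pixels the cell's pixels (needed only for secondary rules).
#' @return single character lineage label.
#' @export
assign_lineage <- function(mv, panel, rules, masks = NULL, pixels = NULL) {
  counts <- mv$counts
  if (all(counts == 0L)) return("undefined")
  lin <- panel$markers[panel$markers$role == "lineage", ]
  pr <- lin$priority_rank[match(mv$markers, lin$name)]
  best <- which(counts == max(counts))
  win <- best[which.min(pr[best])]
  marker <- mv$markers[win]
  r <- rules[rules$marker == marker, , drop = FALSE]
  if (nrow(r) == 0L) stop("winning marker '", marker, "' has no type rule")
  if (!is.na(r$secondary_marker)) {
    stopifnot(!is.null(masks), !is.null(pixels))
    sec <- masks[[r$secondary_marker]]
    if (is.null(sec)) stop("missing mask for secondary marker '",
                           r$secondary_marker, "'")
    if (inherits(sec, "marker_mask")) sec <- sec$mask
    idx <- pixels[, "row"] + 1L + nrow(sec) * pixels[, "col"]
    if (sum(sec[idx]) >= mv$n_pixels / 2) return(r$secondary_type)
  }
  r$type
}

#' Mean raw expression of a cell across channels
#'
#' Arithmetic mean of the raw, untransformed pixel values of each channel
#' over the cell's pixels; all downstream statistics operate on these raw
#' means.
#'
#' @param pixels 0-based `cbind(row, col)` coordinates.
#' @param stack a [core_stack()].
#' @return named numeric vector over the stack's channels.
#' @export
mean_expression <- function(pixels, stack) {
  nr <- dim(stack)[1]
  idx <- pixels[, "row"] + 1L + nr * pixels[, "col"]
  vapply(stack$channels, function(ch) mean(ch[idx]), numeric(1))
}

#' Functional marker positivity of a cell
#'
#' A cell is positive for a functional marker when at least a threshold
#' fraction of its pixels fall inside that marker's mask (default half).
#'
#' @param pixels 0-based `cbind(row, col)` coordinates.
#' @param mask a `marker_mask` or logical matrix.
#' @param threshold foreground pixel fraction required (default 0.5).
#' @return logical scalar.
#' @export
functional_positivity <- function(pixels, mask, threshold = 0.5) {
  if (inherits(mask, "marker_mask")) mask <- mask$mask
  idx <- pixels[, "row"] + 1L + nrow(mask) * pixels[, "col"]
  mean(mask[idx]) >= threshold
}

#' Normalize values to an upper percentile
#'
#' Divides by the `p`-th percentile (linear-interpolation quantile,
#' [stats::quantile()] type 7) and clips at 1; used for heatmap display of
#' expression and composition matrices.
#'
#' @param values numeric vector.
#' @param p percentile in (0, 100] (default 95).
#' @return numeric vector in `[0, 1]` (all zeros, with a warning, when the
#'   percentile is zero).
#' @export
percentile_normalize <- function(values, p = 95) {
  stopifnot(length(values) > 0)
  q <- as.numeric(quantile(values, p / 100, type = 7, names = FALSE))
  if (q == 0) {
    tme_log("warn", "percentile is zero; returning zeros")
    return(values * 0)
  }
  pmin(values / q, 1)
}

#' Phenotype all cells of one core
#'
#' Runs majority voting, lineage assignment, raw mean expression and
#' functional positivity for every segmented cell, producing one cell-table
#' row per cell.
#'
#' @param stack a [core_stack()].
#' @param seg a [segmentation_map()].
#' @param panel a [marker_panel()].
#' @param masks named list from [build_panel_masks()].
#' @param rules a [type_rules()] data.frame (default: one-to-one on the
#'   panel's lineage markers).
#' @param positivity_threshold forwarded to [functional_positivity()].
#' @return a validated cell table (see [validate_cell_table()]).
#' @export
phenotype_core <- function(stack, seg, panel, masks,
                           rules = type_rules(lineage_markers(panel)),
                           positivity_threshold = 0.5) {
  lm <- lineage_markers(panel)
  fm <- intersect(functional_markers(panel), names(masks))
  chans <- names(stack$channels)
  n <- length(seg$cells)
  lineage <- character(n)
  expr <- matrix(NA_real_, n, length(chans),
                 dimnames = list(NULL, paste0("expr_", chans)))
  pos <- matrix(NA, n, length(fm), dimnames = list(NULL, paste0("pos_", fm)))
  for (i in seq_len(n)) {
    px <- seg$cells[[i]]
    mv <- majority_vector(px, masks, lm)
    lineage[i] <- assign_lineage(mv, panel, rules, masks, px)
    expr[i, ] <- mean_expression(px, stack)
    for (j in seq_along(fm))
      pos[i, j] <- functional_positivity(px, masks[[fm[j]]],
                                         positivity_threshold)
  }
  out <- data.frame(
    cell_id = as.integer(names(seg$cells)),
    core_id = seg$core_id,
    row = seg$centroids$row,
    col = seg$centroids$col,
    lineage = lineage,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(expr))
  if (length(fm)) out <- cbind(out, as.data.frame(pos))
  validate_cell_table(out, lineage_levels = unique(c(rules$type,
                                                     na.omit(rules$secondary_type))))
}

#' Per-core cell-type frequencies
#'
#' Computes each type's fraction per core, over all cells and (optionally)
#' over immune cells only. Fractions sum to 1 per core and denominator;
#' cores without immune cells get missing immune fractions.
#'
#' @param table a cell table.
#' @param types cell-type labels defining the columns (default: observed).
#' @param immune_types subset of `types` counting as immune; NULL disables
#'   the immune denominator.
#' @return list with matrices `total` and (if requested) `immune`
#'   (cores x types).
#' @export
compute_frequencies <- function(table, types = sort(unique(table$lineage)),
                                immune_types = NULL) {
  if (nrow(table) == 0L) stop("cell table is empty")
  cores <- unique(table$core_id)
  tally <- function(sub, denom_types) {
    t(vapply(cores, function(cid) {
      rows <- sub$core_id == cid & sub$lineage %in% denom_types
      denom <- sum(rows)
      if (denom == 0L) return(rep(NA_real_, length(types)))
      as.numeric(table(factor(sub$lineage[rows], levels = types))) / denom
    }, numeric(length(types))))
  }
  total <- tally(table, types)
  dimnames(total) <- list(cores, types)
  out <- list(total = total)
  if (!is.null(immune_types)) {
    imm <- tally(table, immune_types)
    dimnames(imm) <- list(cores, types)
    imm[, setdiff(types, immune_types)] <- NA_real_
    # restrict columns to immune types; rows without immune cells stay NA
    out$immune <- imm[, immune_types, drop = FALSE]
  }
  out
}
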