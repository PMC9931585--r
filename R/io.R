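# Channel rasters are stored as 32-bit float TIFF pages scaled by 1/65536
# (the tiff format here stores [0,1]); counts up to 65536 round-trip to
# float precision.
.tiff_scale <- 65536

#' Write a core stack to TIFF
#'
#' Either one multipage TIFF (one page per channel, in stack order) or a
#' directory of single-channel TIFFs named by marker.
#'
#' @param stack a [core_stack()].
#' @param path target `.tif`/`.tiff` file, or a directory.
#' @param as_dir write one file per channel into `path` (default: decided
#'   by the file extension).
#' @return `path`, invisibly.
#' @export
write_core_stack <- function(stack, path,
                             as_dir = !grepl("\\.tiff?$", path,
                                             ignore.case = TRUE)) {
  if (as_dir) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(stack$channels)) {
      tiff::writeTIFF(stack$channels[[nm]] / .tiff_scale,
                      file.path(path, paste0(nm, ".tif")),
                      bits.per.sample = 32L)
    }
  } else {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    tiff::writeTIFF(lapply(stack$channels, function(ch) ch / .tiff_scale),
                    path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read a core stack from TIFF
#'
#' Accepts a multipage TIFF (one page per channel, page order equal to
#' panel order) or a directory of single-channel TIFFs named
#' `<marker>.tif`. Channels not in the panel are dropped with a warning;
#' a missing lineage channel is a hard error naming the marker; missing
#' functional/excluded channels are warned about and skipped.
#'
#' @param path TIFF file or directory.
#' @param panel a [marker_panel()].
#' @param core_id core identifier (default: file/directory base name).
#' @param pixel_size_um forwarded to [core_stack()].
#' @return a [core_stack()] restricted to panel channels.
#' @export
read_core_stack <- function(path, panel, core_id = NULL,
                            pixel_size_um = 1.0) {
  core_id <- core_id %||% sub("\\.tiff?$", "",
                              basename(path), ignore.case = TRUE)
  want <- panel$markers$name
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    nm <- sub("\\.tiff?$", "", basename(files), ignore.case = TRUE)
    extra <- setdiff(nm, want)
    if (length(extra))
      tme_log("warn", "dropping non-panel channel(s): ",
              paste(extra, collapse = ", "))
    channels <- list()
    for (mk in want) {
      f <- files[match(mk, nm)]
      if (is.na(f)) next
      channels[[mk]] <- tiff::readTIFF(f) * .tiff_scale
    }
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) > length(want)) {
      tme_log("warn", "TIFF has ", length(pages), " pages for ",
              length(want), " panel markers; extra pages dropped")
      pages <- pages[seq_along(want)]
    }
    channels <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1]
      p * .tiff_scale
    })
    names(channels) <- want[seq_along(channels)]
  }
  lm <- lineage_markers(panel)
  miss <- setdiff(lm, names(channels))
  if (length(miss))
    stop("missing lineage channel(s): ", paste(miss, collapse = ", "))
  other_miss <- setdiff(want, c(names(channels)))
  if (length(other_miss))
    tme_log("warn", "missing non-lineage channel(s): ",
            paste(other_miss, collapse = ", "))
  dims <- vapply(channels, dim, integer(2))
  if (any(dims != dims[, 1]))
    stop("channel dimensions differ across pages/files")
  core_stack(core_id, channels, pixel_size_um)
}

#' Write a marker mask as TIFF
#' @param mask a `marker_mask` or logical matrix.
#' @param path target file.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (inherits(mask, "marker_mask")) mask <- mask$mask
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write a label raster as TIFF
#' @param label_raster integer matrix (0 = background).
#' @param path target file.
#' @return `path`, invisibly.
#' @export
write_labels <- function(label_raster, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(label_raster / .tiff_scale, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a label raster from TIFF
#' @param path file written by [write_labels()].
#' @return integer matrix.
#' @export
read_labels <- function(path) {
  m <- round(tiff::readTIFF(path) * .tiff_scale)
  storage.mode(m) <- "integer"
  m
}

#' Write and read cell tables
#'
#' Cell tables are stored as UTF-8 comma-separated text with a header and
#' `.` decimal; writing, reading and re-writing is byte-identical. On
#' read, column classes are restored (`cell_id` integer, coordinates and
#' `expr_*` double, `pos_*` logical) and lineage labels are validated when
#' a label set is supplied.
#'
#' @param table a cell table.
#' @param path target `.csv` file.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(as.data.frame(table), path, sep = ",", dec = ".",
                     quote = "auto", bom = FALSE, eol = "\n",
                     logical01 = FALSE, scipen = 50L)
  invisible(path)
}

#' @rdname write_cell_table
#' @param lineage_levels allowed lineage labels; unknown labels error with
#'   the offending rows (NULL skips the check).
#' @return for `read_cell_table`, the validated cell table.
#' @export
read_cell_table <- function(path, lineage_levels = NULL) {
  dt <- data.table::fread(path, sep = ",", dec = ".", header = TRUE,
                          data.table = FALSE, encoding = "UTF-8")
  if (nrow(dt)) {
    dt$cell_id <- as.integer(dt$cell_id)
    dt$core_id <- as.character(dt$core_id)
    dt$lineage <- as.character(dt$lineage)
    for (cl in c("row", "col", grep("^expr_", names(dt), value = TRUE)))
      dt[[cl]] <- as.double(dt[[cl]])
    for (cl in grep("^pos_", names(dt), value = TRUE))
      dt[[cl]] <- as.logical(dt[[cl]])
  }
  validate_cell_table(dt, lineage_levels = lineage_levels)
}

#' Write and read clinical tables
#' @param table validated clinical table.
#' @param path target `.csv`.
#' @return `path` / the validated table.
#' @export
write_clinical_table <- function(table, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(as.data.frame(table), path, sep = ",", dec = ".",
                     quote = "auto", eol = "\n", logical01 = FALSE,
                     scipen = 50L)
  invisible(path)
}

#' @rdname write_clinical_table
#' @export
read_clinical_table <- function(path) {
  dt <- data.table::fread(path, sep = ",", dec = ".", header = TRUE,
                          data.table = FALSE, encoding = "UTF-8")
  dt$patient_id <- as.character(dt$patient_id)
  dt$core_ids <- as.character(dt$core_ids)
  validate_clinical_table(dt)
}

#' Write a generic matrix as CSV with rownames
#' @noRd
write_matrix_csv <- function(m, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(id = rownames(m) %||% seq_len(nrow(m)), m,
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = ",", eol = "\n", scipen = 50L)
  invisible(path)
}
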