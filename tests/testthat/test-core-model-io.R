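test_that("core stacks validate their invariants", {
  ch <- matrix(1:12, 3, 4)
  expect_s3_class(core_stack("c", list(a = ch, b = ch * 2)), "core_stack")
  expect_error(core_stack("c", list(a = ch, b = matrix(0, 2, 2))),
               "dimensions")
  expect_error(core_stack("c", list(a = ch, a = ch)), "uniquely")
  expect_error(core_stack("c", list(a = -ch)), "negative")
})

test_that("TIFF stacks round-trip through multipage files and directories", {
  ch <- matrix(as.double(0:63), 8, 8)
  panel <- marker_panel(data.frame(
    name = c("m1", "m2", "m3"), role = "lineage", priority_rank = 1:3))
  stack <- core_stack("core7", list(m1 = ch, m2 = ch * 3, m3 = ch * 0 + 5))

  f <- tempfile(fileext = ".tif")
  write_core_stack(stack, f)
  back <- read_core_stack(f, panel, core_id = "core7")
  expect_equal(back$channels, stack$channels, tolerance = 1e-4)

  d <- tempfile()
  write_core_stack(stack, d, as_dir = TRUE)
  # an extra non-panel TIFF is dropped with a warning
  tiff::writeTIFF(ch / 65536, file.path(d, "extra.tif"),
                  bits.per.sample = 32L)
  expect_warning(back2 <- read_core_stack(d, panel), "extra")
  expect_setequal(names(back2$channels), c("m1", "m2", "m3"))

  # a missing lineage channel names the marker
  panel4 <- marker_panel(data.frame(
    name = c("m1", "m2", "m3", "CD20"), role = "lineage",
    priority_rank = 1:4))
  expect_error(suppressWarnings(read_core_stack(d, panel4)), "CD20")
})

test_that("segmentation maps expose 0-based pixels and centroids", {
  lab <- matrix(0L, 5, 5)
  lab[2:3, 2] <- 1L   # rows 1..2, col 1 (0-based)
  lab[5, 5] <- 2L
  seg <- segmentation_map("c", lab)
  expect_identical(names(seg$cells), c("1", "2"))
  expect_equal(seg$centroids$row, c(1.5, 4))
  expect_equal(seg$centroids$col, c(1, 4))
  expect_error(segmentation_map("c", lab - 1L), ">= 0")
})

test_that("cell tables round-trip losslessly and byte-identically", {
  tab <- data.frame(
    cell_id = 1:2, core_id = "c1", row = c(1.5, 20.25), col = c(3, 4.125),
    lineage = c("B cell", "Tumour"),
    check.names = FALSE, stringsAsFactors = FALSE)
  tab[["expr_αSMA"]] <- c(0.125, 7.75)  # unicode marker name
  tab$pos_Ki67 <- c(TRUE, FALSE)
  tab <- validate_cell_table(tab)

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cell_table(tab, f1)
  back <- read_cell_table(f1)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  write_cell_table(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # empty table: header-only file and back
  f3 <- tempfile(fileext = ".csv")
  write_cell_table(tab[0, ], f3)
  expect_equal(nrow(read_cell_table(f3)), 0L)

  # unknown lineage label errors with the offending rows
  bad <- tab; bad$lineage[2] <- "Bcel"
  f4 <- tempfile(fileext = ".csv")
  write_cell_table(bad, f4)
  expect_error(read_cell_table(f4, lineage_levels = c("B cell", "Tumour")),
               "Bcel")
})

test_that("clinical tables validate and round-trip", {
  cl <- data.frame(
    patient_id = c("P1", "P2"), core_ids = c("c1;c2", "c3"),
    histology = c("acinar", "solid"), sex = c("F", "M"),
    age = c(70, 61), bmi = c(24.1, 31.0), smoking = "smoker",
    pack_years = c(30, 45), stage = c("I-II", "III-IV"),
    progression = c(FALSE, TRUE), survival_months = c(60.5, 12.25),
    event = c(FALSE, TRUE), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".csv")
  write_clinical_table(validate_clinical_table(cl), f)
  expect_equal(read_clinical_table(f), cl)
  expect_equal(nrow(clinical_by_core(cl)), 3L)

  dup <- cl; dup$core_ids <- c("c1;c2", "c2")
  expect_error(validate_clinical_table(dup), "more than one patient")
  badh <- cl; badh$histology[1] <- "weird"
  expect_error(validate_clinical_table(badh), "histology")
})

test_that("masks and label rasters survive TIFF round-trips", {
  m <- matrix(runif(64) < 0.4, 8, 8)
  fm <- tempfile(fileext = ".tif")
  write_mask(m, fm)
  expect_identical(tiff::readTIFF(fm) > 0.5, m)

  lab <- matrix(sample(0:5, 100, TRUE), 10, 10)
  fl <- tempfile(fileext = ".tif")
  write_labels(lab, fl)
  expect_identical(read_labels(fl), lab)
})
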