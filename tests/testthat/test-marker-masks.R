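test_that("median smoothing matches its definition", {
  # constant raster is a fixed point
  const <- matrix(5, 8, 8)
  expect_identical(median_smooth(const, 3), const)

  # an isolated bright pixel is erased by a 3x3 median
  x <- matrix(0, 9, 9); x[5, 5] <- 100
  expect_true(all(median_smooth(x, 3) == 0))

  # random rasters match the per-pixel brute force, including borders
  set.seed(41)
  for (i in 1:5) {
    y <- matrix(sample(0:20, 35, replace = TRUE), 5, 7)
    expect_equal(median_smooth(y, 3), oracle_median_filter(y, 3))
    expect_equal(median_smooth(y, 5), oracle_median_filter(y, 5))
  }
  expect_error(median_smooth(y, 4), "odd")
})

test_that("intensity quantization finds the 1-D k-means optimum", {
  # two-valued raster splits exactly
  x <- matrix(rep(c(0, 100), each = 8), 4, 4)
  lev <- quantize_levels(x, 2)
  expect_true(all(lev[x == 0] == 1L) && all(lev[x == 100] == 2L))

  # constant raster collapses to one level with a warning
  expect_warning(lev1 <- quantize_levels(matrix(7, 4, 4), 6), "distinct")
  expect_true(all(lev1 == 1L))

  # tri-modal mixture: boundaries equal Lloyd-to-convergence best-of-50
  set.seed(7)
  v <- c(rnorm(1500, 2, 0.3), rnorm(1500, 10, 0.5), rnorm(1096, 25, 1))
  x3 <- matrix(v, 64, 64)
  lev3 <- quantize_levels(x3, 3)
  oracle <- matrix(oracle_kmeans1d(as.vector(x3), 3), 64, 64)
  expect_equal(unname(lev3[, ]), oracle, ignore_attr = TRUE)

  # levels are ordered by mean intensity
  m <- attr(lev3, "level_means")
  expect_true(all(diff(m) > 0))
})

test_that("foreground selection keeps the brightest levels", {
  set.seed(7)
  v <- c(rnorm(1500, 2, 0.3), rnorm(1500, 10, 0.5), rnorm(1096, 25, 1))
  x3 <- matrix(v, 64, 64)
  lev3 <- quantize_levels(x3, 3)
  expect_true(all(select_foreground(lev3, 3)))          # saturation
  expect_identical(select_foreground(lev3, 1), lev3 == 3L) # brightest only
  expect_identical(select_foreground(lev3, 2), lev3 >= 2L) # top two
  expect_error(select_foreground(lev3, 4), "foreground_level")
})

test_that("blob removal matches a flood-fill oracle and is idempotent", {
  m0 <- matrix(FALSE, 10, 10)
  expect_identical(remove_small_blobs(m0, 0), m0)  # min_area 0 is identity

  # two blobs of areas 3 and 10: only the larger survives min_area 5
  m <- matrix(FALSE, 10, 12)
  m[2:3, 2] <- TRUE; m[2, 3] <- TRUE           # area 3
  m[6:10, 7:8] <- TRUE                          # area 10
  out <- remove_small_blobs(m, 5)
  expect_equal(sum(out), 10)
  expect_true(all(out[6:10, 7:8]))

  set.seed(11)
  for (i in 1:8) {
    r <- matrix(runif(32 * 32) < 0.35, 32, 32)
    got <- remove_small_blobs(r, 4)
    expect_identical(got, oracle_remove_blobs(r, 4))
    expect_identical(remove_small_blobs(got, 4), got)  # idempotent
  }
})

test_that("adaptive refinement never adds foreground", {
  # uniform channel: no pixel exceeds its own local mean
  u <- matrix(3, 20, 20)
  m <- matrix(TRUE, 20, 20)
  expect_true(sum(adaptive_refine(u, m, 0.4)) == 0)

  # bright blob on dark background is retained
  x <- matrix(0.1, 40, 40); x[15:25, 15:25] <- 10
  blob <- x > 1
  expect_true(all(adaptive_refine(x, blob, 0.4)[15:25, 15:25]))

  set.seed(3)
  for (i in 1:100) {
    ch <- matrix(runif(15 * 15, 0, 10), 15, 15)
    mask <- matrix(runif(15 * 15) < 0.5, 15, 15)
    out <- adaptive_refine(ch, mask, runif(1))
    expect_true(all(mask[out]))  # output is a subset of the input mask
  }
})

test_that("the composed mask recovers planted marker signal", {
  sp <- tiny_spec(seed = 13)
  core <- generate_core(sp, "c1")
  ch <- core$stack$channels[["panCK"]]
  on_ids <- core$truth$cell_id[core$truth$lineage == "Tumour"]
  on_px <- core$seg$label_raster %in% on_ids
  # erode to interior pixels: the 3x3 median can only commit to pixels
  # whose window lies mostly inside a cell
  mm <- build_marker_mask(ch, mask_params(), "panCK")
  bg <- core$seg$label_raster == 0
  expect_gt(mean(mm$mask[on_px]), 0.60)   # covers cell bodies
  expect_lt(mean(mm$mask[bg]), 0.05)      # near-clean background
  # determinism
  mm2 <- build_marker_mask(ch, mask_params(), "panCK")
  expect_identical(mm$mask, mm2$mask)
})

test_that("disabling adaptive refinement gives the four-step composition", {
  sp <- tiny_spec(seed = 4)
  core <- generate_core(sp, "c1")
  ch <- core$stack$channels[["CD31"]]
  p4 <- mask_params(foreground_level = 2, adaptive_merge = FALSE)
  manual <- remove_small_blobs(
    select_foreground(quantize_levels(median_smooth(ch, 3), 6), 2),
    p4$min_blob_area)
  expect_identical(build_marker_mask(ch, p4, "CD31")$mask, manual)

  p5 <- mask_params(foreground_level = 2, adaptive_merge = TRUE)
  with5 <- build_marker_mask(ch, p5, "CD31")$mask
  expect_true(all(manual[with5]))  # step 5 only removes pixels
})
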