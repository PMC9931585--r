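make_masks <- function(dim, on = list()) {
  # small helper: named logical masks with given TRUE pixel indices
  lapply(on, function(idx) {
    m <- matrix(FALSE, dim[1], dim[2]); m[idx] <- TRUE; m
  })
}

test_that("majority vectors tally mask membership per pixel", {
  px <- cbind(row = 0:4, col = rep(2L, 5))  # 5-pixel column, 0-based
  masks <- make_masks(c(8, 8), list(CD20 = cbind(1:5, 3), CD3 = cbind(8, 8)))
  mv <- majority_vector(px, masks, c("CD3", "CD20"))
  expect_identical(mv$counts, c(0L, 5L))
  expect_identical(mv$n_pixels, 5L)

  # empty masks give all-zero counts
  masks0 <- make_masks(c(8, 8), list(CD20 = cbind(8, 8)[0, ], CD3 = cbind(8, 8)[0, ]))
  expect_identical(majority_vector(px, masks0, c("CD3", "CD20"))$counts, c(0L, 0L))

  expect_error(majority_vector(px, masks, c("CD3", "CD20", "CD8a")),
               "CD8a")

  # random cells match a per-pixel brute force
  set.seed(5)
  for (i in 1:5) {
    px_r <- unique(cbind(row = sample(0:19, 20, TRUE),
                         col = sample(0:19, 20, TRUE)))
    ms <- lapply(1:3, function(k) matrix(runif(400) < 0.4, 20, 20))
    names(ms) <- c("A", "B", "C")
    mv_r <- majority_vector(px_r, ms, c("A", "B", "C"))
    brute <- vapply(ms, function(m) {
      sum(vapply(seq_len(nrow(px_r)), function(j)
        m[px_r[j, "row"] + 1L, px_r[j, "col"] + 1L], logical(1)))
    }, numeric(1))
    expect_identical(mv_r$counts, as.integer(brute))
  }
})

test_that("lineage assignment follows argmax, priority ties and undefined", {
  panel <- default_panel()
  lm <- lineage_markers(panel)
  rules <- default_rules()
  mk_mv <- function(counts) list(counts = counts, markers = lm, n_pixels = max(counts, 1L))

  counts <- integer(8); counts[match("CD20", lm)] <- 5L
  expect_identical(assign_lineage(mk_mv(counts), panel, rules), "B cell")

  # tie between CD8a and CD20: CD20 has higher priority (rank 2 < rank 3)
  tie <- integer(8)
  tie[match("CD20", lm)] <- 4L; tie[match("CD8a", lm)] <- 4L
  expect_identical(assign_lineage(mk_mv(tie), panel, rules), "B cell")

  expect_identical(assign_lineage(mk_mv(integer(8)), panel, rules),
                   "undefined")

  bad_rules <- rules[rules$marker != "CD20", ]
  expect_error(assign_lineage(mk_mv(counts), panel, bad_rules), "CD20")
})

test_that("secondary-marker rules split a lineage by pixel majority", {
  lp <- luad_panel()
  lm <- lineage_markers(lp$panel)
  counts <- integer(length(lm)); counts[match("CD68", lm)] <- 6L
  mv <- list(counts = counts, markers = lm, n_pixels = 8L)
  px <- cbind(row = 0:7, col = rep(0L, 8))
  cd163_hi <- make_masks(c(8, 8), list(CD163 = cbind(1:5, 1)))  # 5/8 >= half
  cd163_lo <- make_masks(c(8, 8), list(CD163 = cbind(1:3, 1)))  # 3/8 < half
  expect_identical(assign_lineage(mv, lp$panel, lp$rules, cd163_hi, px),
                   "CD163 macrophage")
  expect_identical(assign_lineage(mv, lp$panel, lp$rules, cd163_lo, px),
                   "Macrophage")
})

test_that("mean expression is the raw per-channel pixel mean", {
  ch <- matrix(seq_len(36), 6, 6)
  stack <- core_stack("c", list(m1 = ch, m2 = ch * 0 + 2.5))
  one_px <- cbind(row = 2L, col = 3L)
  expect_equal(unname(mean_expression(one_px, stack)),
               c(ch[3, 4], 2.5))
  set.seed(2)
  px <- unique(cbind(row = sample(0:5, 10, TRUE), col = sample(0:5, 10, TRUE)))
  got <- mean_expression(px, stack)
  brute <- mean(vapply(seq_len(nrow(px)), function(j)
    ch[px[j, 1] + 1, px[j, 2] + 1], numeric(1)))
  expect_equal(unname(got["m1"]), brute)
})

test_that("functional positivity thresholds the foreground fraction", {
  px <- cbind(row = 0:9, col = rep(0L, 10))
  full <- matrix(TRUE, 10, 4); none <- matrix(FALSE, 10, 4)
  half <- matrix(FALSE, 10, 4); half[1:5, 1] <- TRUE
  expect_true(functional_positivity(px, full))
  expect_false(functional_positivity(px, none))
  expect_true(functional_positivity(px, half, threshold = 0.5))
  expect_false(functional_positivity(px, half, threshold = 0.6))
})

test_that("percentile normalization divides by the p-th percentile and clips", {
  v <- 0:100
  out <- percentile_normalize(v, 95)
  expect_equal(out[v == 95], 1)
  expect_equal(out[v == 100], 1)          # clipped
  expect_equal(out[v == 19], 19 / 95)
  expect_equal(percentile_normalize(rep(4.2, 10)), rep(1, 10))
  expect_warning(z <- percentile_normalize(rep(0, 5)), "zero")
  expect_equal(z, rep(0, 5))
  set.seed(8)
  r <- rexp(200)
  expect_equal(percentile_normalize(r, 90),
               pmin(r / quantile(r, 0.9, type = 7, names = FALSE), 1))
})

test_that("frequencies sum to one per denominator and flag degenerate cores", {
  tab <- data.frame(
    cell_id = 1:10, core_id = "c1", row = 1:10, col = 1:10,
    lineage = c(rep("B cell", 4), rep("Tumour", 6)))
  fr <- compute_frequencies(tab, types = c("B cell", "Tumour"),
                            immune_types = "B cell")
  expect_equal(fr$total["c1", "B cell"], 0.4)
  expect_equal(sum(fr$total["c1", ]), 1)
  expect_equal(fr$immune["c1", "B cell"], 1)

  solid <- data.frame(cell_id = 1:5, core_id = "c2", row = 1:5, col = 1:5,
                      lineage = "Tumour")
  fr2 <- compute_frequencies(solid, types = c("B cell", "Tumour"),
                             immune_types = "B cell")
  expect_true(is.na(fr2$immune["c2", "B cell"]))  # no immune denominator
  expect_error(compute_frequencies(tab[0, ]), "empty")
})

test_that("assignment is invariant to marker order given fixed priorities", {
  sp <- tiny_spec(seed = 21)
  core <- generate_core(sp, "c1")
  masks <- suppressWarnings(build_panel_masks(core$stack, sp$panel))
  t1 <- phenotype_core(core$stack, core$seg, sp$panel, masks,
                       rules = sp$rules)
  # permute the panel's marker rows (priorities travel with the markers)
  set.seed(1)
  perm_markers <- sp$panel$markers[sample.int(nrow(sp$panel$markers)), ]
  panel2 <- marker_panel(perm_markers, sp$panel$mask_params)
  t2 <- phenotype_core(core$stack, core$seg, panel2, masks,
                       rules = sp$rules)
  expect_identical(t1$lineage, t2$lineage)
})

test_that("phenotyping recovers planted lineages and functional states", {
  sp <- tiny_spec(seed = 31)
  core <- generate_core(sp, "c1")
  masks <- suppressWarnings(build_panel_masks(core$stack, sp$panel))
  tab <- phenotype_core(core$stack, core$seg, sp$panel, masks,
                        rules = sp$rules)
  expect_gte(mean(tab$lineage == core$truth$lineage), 0.90)

  # planted HIF1a-positive neutrophil fraction recovered within 5 points
  neu <- core$truth$lineage == "Neutrophil"
  if (sum(neu) >= 10) {
    expect_lte(abs(mean(tab$pos_HIF1a[neu]) -
                   mean(core$truth$pos_HIF1a[neu])), 0.05)
  }
})
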