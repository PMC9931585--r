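lab_from_points <- function(dim, pts) {
  lab <- matrix(0L, dim[1], dim[2])
  for (i in seq_len(nrow(pts))) lab[pts[i, 1], pts[i, 2]] <- i
  lab
}

test_that("boundary adjacency is inclusive at the interaction distance", {
  # two 1-pixel cells exactly 6 px apart: edge; 7 px apart: none
  seg6 <- segmentation_map("c", lab_from_points(c(20, 20),
                                                rbind(c(5, 5), c(5, 11))))
  expect_equal(nrow(build_adjacency(seg6, d = 6)$edges), 1L)
  seg7 <- segmentation_map("c", lab_from_points(c(20, 20),
                                                rbind(c(5, 5), c(5, 12))))
  expect_equal(nrow(build_adjacency(seg7, d = 6)$edges), 0L)
})

test_that("adjacency matches an all-pairs pixel distance brute force", {
  sp <- synthetic_spec(n_patients = 1L, image_size = c(72L, 72L),
                       cell_density = 60, seed = 12)
  core <- generate_core(sp, "c1")
  seg <- core$seg
  g <- build_adjacency(seg, d = 6, rule = "boundary")
  ids <- as.integer(names(seg$cells))
  brute <- list()
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    p1 <- seg$cells[[i]]; p2 <- seg$cells[[j]]
    d2 <- outer(p1[, 1], p2[, 1], "-")^2 + outer(p1[, 2], p2[, 2], "-")^2
    if (min(d2) <= 36) brute[[length(brute) + 1L]] <- sort(c(ids[i], ids[j]))
  }
  brute_m <- do.call(rbind, brute)
  got <- t(apply(g$edges, 1, sort))
  expect_identical(got[order(got[, 1], got[, 2]), , drop = FALSE],
                   brute_m[order(brute_m[, 1], brute_m[, 2]), , drop = FALSE])
})

test_that("permutation p-values agree with exhaustive enumeration", {
  # 6 cells on a line, chain adjacency; 3 of each type
  pts <- cbind(rep(5, 6), seq(3, 33, by = 6))
  seg <- segmentation_map("c", lab_from_points(c(40, 40), pts))
  g <- build_adjacency(seg, d = 6)
  types <- c("A", "A", "B", "A", "B", "B")
  res <- interaction_test(g, setNames(types, 1:6), n_perm = 2000, seed = 4)
  ex <- oracle_exact_interaction(g$edges, 1:6, types, "A", "B")
  got <- res[res$type_a == "A" & res$type_b == "B", ]
  expect_equal(got$obs_mean, ex$obs)
  expect_lte(abs(got$p_interact - ex$p_interact), 0.02)
  expect_lte(abs(got$p_avoid - ex$p_avoid), 0.02)
  # add-one lower bound holds everywhere
  ok <- !is.na(res$p_interact)
  expect_true(all(res$p_interact[ok] >= 1 / 2001))
  expect_true(all(res$p_avoid[ok] >= 1 / 2001))
})

test_that("segregated types are called avoidant", {
  set.seed(2)
  ptsA <- cbind(sample(3:28, 12), sample(3:28, 12))
  ptsB <- cbind(sample(70:95, 12), sample(70:95, 12))
  pts <- rbind(ptsA, ptsB)
  seg <- segmentation_map("c", lab_from_points(c(100, 100), pts))
  # dense within-block adjacency via a generous distance
  g <- build_adjacency(seg, d = 20)
  types <- rep(c("A", "B"), each = 12)
  res <- interaction_test(g, setNames(types, seq_len(24)),
                          n_perm = 1000, seed = 1)
  ab <- res[res$type_a == "A" & res$type_b == "B", ]
  expect_identical(ab$call, "avoidance")
  expect_lte(ab$p_avoid, 0.01)
})

test_that("results are invariant to cell id relabelling", {
  sp <- tiny_spec(seed = 14)
  core <- generate_core(sp, "c1")
  g <- build_adjacency(core$seg, d = 6)
  types <- setNames(core$truth$lineage, core$truth$cell_id)
  r1 <- interaction_test(g, types, n_perm = 200, seed = 2)
  # shift ids by a constant
  g2 <- g; g2$ids <- g$ids + 1000L; g2$edges <- g$edges + 1000L
  types2 <- setNames(core$truth$lineage, core$truth$cell_id + 1000L)
  r2 <- interaction_test(g2, types2, n_perm = 200, seed = 2)
  expect_equal(r1[, -1], r2[, -1])
})

test_that("a type with no cells is reported missing", {
  pts <- cbind(rep(5, 4), seq(3, 21, 6))
  seg <- segmentation_map("c", lab_from_points(c(30, 30), pts))
  g <- build_adjacency(seg, d = 6)
  res <- interaction_test(g, setNames(c("A", "A", "B", "B"), 1:4),
                          type_levels = c("A", "B", "C"), n_perm = 100,
                          seed = 1)
  expect_true(all(res$call[res$type_a == "C" | res$type_b == "C"] ==
                  "missing"))
})

test_that("group heatmaps average signed calls over testable cores", {
  res <- data.frame(
    core_id = rep(c("c1", "c2", "c3", "c4"), each = 1),
    type_a = "A", type_b = "B", obs_mean = 1,
    p_interact = c(0.001, 0.001, 0.5, 0.001),
    p_avoid = 1, call = c("interaction", "interaction", "none",
                          "interaction"),
    n_perm = 1000L, alpha = 0.01, stringsAsFactors = FALSE)
  groups <- c(c1 = "solid", c2 = "solid", c3 = "lepidic", c4 = "lepidic")
  hm <- group_heatmap(res, groups)
  expect_equal(hm$solid["A", "B"], 1)          # all interaction
  expect_equal(hm$lepidic["A", "B"], 0.5)      # half interaction, half none
  expect_error(group_heatmap(res, c(c1 = "solid", c2 = "solid",
                                    c3 = "lepidic")), "without a group")
})
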