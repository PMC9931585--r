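two_block_table <- function(n_per = 40, types = c("B cell", "Tumour")) {
  # two well-separated spatial blocks of pure composition
  set.seed(33)
  data.frame(
    cell_id = seq_len(2 * n_per), core_id = "c1",
    row = c(runif(n_per, 0, 30), runif(n_per, 200, 230)),
    col = c(runif(n_per, 0, 30), runif(n_per, 200, 230)),
    lineage = rep(types, each = n_per), stringsAsFactors = FALSE)
}

test_that("window vectors tally the n nearest neighbours", {
  tab <- two_block_table()
  wv <- window_vectors(tab, n = 10)
  expect_true(all(abs(rowSums(wv$freq) - 1) < 1e-12))
  # cells in the pure B block see only B cells
  brows <- wv$cells$cell_id <= 40
  expect_true(all(wv$freq[brows, "B cell"] == 1))
  expect_false(any(wv$cells$truncated))

  # n larger than the core: window over all other cells, flagged
  small <- tab[1:5, ]
  wv2 <- window_vectors(small, n = 10)
  expect_true(all(wv2$cells$truncated))
  expect_true(all(abs(rowSums(wv2$freq) - 1) < 1e-12))

  # a 1-cell core is skipped with a warning
  one <- tab[1, ]
  expect_warning(expect_error(window_vectors(one, n = 3), "at least 2"),
                 "skipped")
})

test_that("neighbour sets match a brute-force sort with id tie-breaks", {
  set.seed(44)
  tab <- data.frame(cell_id = 1:50, core_id = "c1",
                    row = sample(1:20, 50, TRUE),
                    col = sample(1:20, 50, TRUE),
                    lineage = sample(c("A", "B", "C"), 50, TRUE),
                    stringsAsFactors = FALSE)
  wv <- window_vectors(tab, n = 7, type_levels = c("A", "B", "C"))
  for (i in c(1, 17, 50)) {
    d <- sqrt((tab$row - tab$row[i])^2 + (tab$col - tab$col[i])^2)
    ord <- order(d, tab$cell_id)
    nb <- setdiff(ord, i)[1:7]
    brute <- table(factor(tab$lineage[nb], c("A", "B", "C"))) / 7
    expect_equal(as.numeric(wv$freq[wv$cells$cell_id == i, ]),
                 as.numeric(brute))
  }
})

test_that("clustering recovers pure planted niches and is deterministic", {
  tab <- two_block_table()
  wv <- window_vectors(tab, n = 10)
  m <- cluster_windows(wv, tCN = 2, seed = 0)
  truth <- rep(1:2, each = 40)
  agree <- max(mean(m$labels == truth), mean(m$labels == 3 - truth))
  expect_equal(agree, 1)  # pure blocks separate perfectly

  m2 <- cluster_windows(wv, tCN = 2, seed = 0)
  expect_identical(m$labels, m2$labels)
  expect_identical(m$centroids, m2$centroids)

  m1 <- cluster_windows(wv, tCN = 1, seed = 0)
  expect_true(all(m1$labels == 1L))
  expect_error(cluster_windows(wv, tCN = 1000, seed = 0), "exceeds")
})

test_that("prevalence sums to exactly 100 percent per core", {
  tab <- two_block_table()
  wv <- window_vectors(tab, n = 10)
  m <- cluster_windows(wv, tCN = 2, seed = 0)
  prev <- cn_prevalence(m)
  expect_equal(unname(rowSums(prev$percent)), rep(100, nrow(prev$percent)))
  expect_equal(unname(rowSums(prev$fraction)), rep(1, nrow(prev$fraction)))
  expect_equal(sort(unname(prev$fraction["c1", ])), c(0.5, 0.5))

  # brute-force tally on random labels
  m$labels <- sample(1:2, length(m$labels), TRUE)
  prev2 <- cn_prevalence(m)
  expect_equal(unname(prev2$fraction["c1", 1]), mean(m$labels == 1))
})

test_that("CN characterization highlights enriched types", {
  tab <- two_block_table()
  wv <- window_vectors(tab, n = 10)
  m <- cluster_windows(wv, tCN = 2, seed = 0)
  ch <- characterize_cns(m, wv)
  bcn <- which.max(ch$composition[, "B cell"])
  expect_gt(ch$display[bcn, "B cell"], 0)
  expect_equal(unname(ch$composition[bcn, "B cell"]), 1)
})

test_that("a single sweep cell equals the direct pipeline run", {
  sp <- tiny_spec(seed = 19,
                  outcome = outcome_spec(censor_rate = 0.2))
  coh <- generate_cohort(sp)
  tab <- do.call(rbind, lapply(coh$cores, `[[`, "truth"))
  sw <- cn_sweep(tab, coh$clinical, n_values = 8, tCN_values = 2L, seed = 0)
  # direct run with the same parameters
  wv <- window_vectors(tab, n = 8)
  m <- cluster_windows(wv, tCN = 2, seed = 0)
  pat <- patient_prevalence(cn_prevalence(m)$fraction,
                            clinical_by_core(coh$clinical))
  direct <- survival_scan(pat$values, pat$clinical$survival_months,
                          pat$clinical$event)
  expect_equal(sw$p_value, direct$p_value)
  expect_equal(sw$chisq, direct$chisq)
})
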