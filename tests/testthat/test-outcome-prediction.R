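test_that("backbones embed channels to fixed-length concatenated vectors", {
  register_backbone("tiny8", function(x) rep(mean(x), 8), 8L)
  ch <- matrix(runif(64), 8, 8)
  stack <- core_stack("c", list(a = ch, b = ch, c = ch * 2))
  v <- embed_channels(stack, "tiny8", c("a", "b"))
  expect_length(v, 16L)
  # identical channels embed to identical blocks (purity)
  expect_identical(v[1:8], v[9:16])
  expect_error(embed_channels(stack, "nope"), "testhash")
  expect_error(embed_channels(stack, "tiny8", "zz"), "zz")
  # the working backbone matches the reference embedding width
  expect_length(embed_channels(stack, "testhash", "a"), 2048L)
  # embeddings are deterministic
  expect_identical(embed_channels(stack, "testhash", "a"),
                   embed_channels(stack, "testhash", "a"))
})

test_that("sparse PCA recovers low-rank structure and the dense PCA limit", {
  set.seed(5)
  A <- matrix(rnorm(40 * 2), 40, 2) %*% matrix(rnorm(2 * 30), 2, 30)
  red <- fit_sparse_pca(A, n_components = 2, keep_x = 30)
  recon <- red$scores %*% t(red$loadings)
  Ac <- sweep(A, 2, colMeans(A))
  expect_lt(sum((recon - Ac)^2) / sum(Ac^2), 1e-6)

  # dense limit: loadings match prcomp up to sign
  X <- matrix(rnorm(30 * 12), 30, 12)
  d <- fit_sparse_pca(X, n_components = 3, keep_x = 12)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  for (k in 1:3)
    expect_equal(abs(sum(d$loadings[, k] * pc$rotation[, k])), 1,
                 tolerance = 1e-6)

  # default width and determinism
  d9 <- fit_sparse_pca(X, n_components = 9)
  expect_equal(ncol(d9$scores), 9L)
  expect_identical(d9$loadings, fit_sparse_pca(X, n_components = 9)$loadings)
  expect_error(fit_sparse_pca(X, n_components = 31), "exceeds")

  # transform of training data reproduces training scores
  expect_equal(predict(d9, X), d9$scores)
})

test_that("random oversampling reaches exact class parity", {
  labels <- c(rep("a", 12), rep("b", 4), rep("c", 7))
  idx <- random_oversample(labels, seed = 3)
  expect_true(all(table(labels[idx]) == 12))
  expect_true(all(seq_along(labels) %in% idx))  # originals kept
  expect_identical(idx, random_oversample(labels, seed = 3))
})

test_that("the baseline score is the modal class fraction", {
  expect_equal(baseline_score(c(rep(1, 90), rep(0, 30))), 0.75)
  expect_equal(baseline_score(rep(c("a", "b"), 10)), 0.5)
  expect_equal(baseline_score(rep("a", 5)), 1)
})

test_that("cross-validation separates separable classes and respects groups", {
  set.seed(6)
  n <- 60
  y <- rep(c("pos", "neg"), each = n / 2)
  X <- matrix(rnorm(n * 20), n, 20)
  X[y == "pos", 1:3] <- X[y == "pos", 1:3] + 6  # wide margin
  rep_ <- train_eval(X, y, k = 5, n_components = 4, seed = 2)
  expect_equal(rep_$mean_accuracy, 1)
  # folds partition all samples exactly once
  expect_equal(sort(unique(rep_$fold)), 1:5)
  expect_false(any(is.na(rep_$predictions)))

  # patients with two cores stay in one fold
  groups <- rep(sprintf("P%02d", 1:(n / 2)), each = 2)
  y2 <- rep(c("pos", "neg"), each = n / 2)
  rep2 <- train_eval(X, y2, groups = groups, k = 5, n_components = 4,
                     seed = 2)
  for (g in unique(groups))
    expect_length(unique(rep2$fold[groups == g]), 1L)
  expect_false(is.na(rep2$two_core_agreement))
})

test_that("training-fold artifacts ignore held-out labels (leakage canary)", {
  set.seed(7)
  n <- 40
  y <- rep(c("x", "y"), n / 2)
  X <- matrix(rnorm(n * 15), n, 15)
  r1 <- train_eval(X, y, k = 4, n_components = 3, seed = 5)
  # permute the labels of fold-1 test samples only, holding folds fixed
  y_perm <- y
  te <- r1$fold == 1
  set.seed(1); y_perm[te] <- sample(y[te])
  r2 <- train_eval(X, y_perm, k = 4, n_components = 3, seed = 5,
                   fold = r1$fold)
  # identical fold-1 training artifacts: reducer and oversampling draw
  # nothing from the held-out fold
  expect_identical(r1$artifacts[[1]]$center, r2$artifacts[[1]]$center)
  expect_identical(r1$artifacts[[1]]$loadings, r2$artifacts[[1]]$loadings)
  expect_identical(r1$artifacts[[1]]$oversample, r2$artifacts[[1]]$oversample)
})

test_that("label-independent features score near the baseline", {
  set.seed(8)
  n <- 80
  y <- sample(c("a", "b"), n, TRUE, prob = c(0.6, 0.4))
  X <- matrix(rnorm(n * 10), n, 10)
  rep_ <- train_eval(X, y, k = 5, n_components = 4, seed = 3)
  b <- baseline_score(y)
  expect_lte(abs(rep_$mean_accuracy - b), 3 * sqrt(b * (1 - b) / n) + 0.05)
})

test_that("marker ranking puts the informative channel first", {
  set.seed(9)
  n <- 36
  y <- rep(c("hi", "lo"), each = n / 2)
  mk_stack <- function(i) {
    informative <- matrix(rexp(32 * 32, 1), 32, 32)
    if (y[i] == "hi") informative[8:24, 8:24] <- informative[8:24, 8:24] + 4
    core_stack(sprintf("s%02d", i), list(
      sig = informative,
      noise1 = matrix(rexp(32 * 32, 1), 32, 32),
      noise2 = matrix(rexp(32 * 32, 1), 32, 32)))
  }
  stacks <- lapply(seq_len(n), mk_stack)
  names(stacks) <- sprintf("s%02d", seq_len(n))
  rk <- rank_markers(stacks, y, k = 3, n_components = 3, seed = 1)
  expect_identical(rk$marker[1], "sig")
  expect_identical(sort(rk$marker), c("noise1", "noise2", "sig"))

  # subset evaluation: the informative subset approaches the full panel
  ev <- evaluate_subsets(stacks, y,
                         subsets = list(all = c("sig", "noise1", "noise2"),
                                        sig_only = "sig",
                                        noise = c("noise1", "noise2")),
                         k = 3, n_components = 3, seed = 1)
  expect_gte(ev$mean_accuracy[ev$subset == "sig_only"] + 0.05,
             ev$mean_accuracy[ev$subset == "all"])
  expect_lte(ev$mean_accuracy[ev$subset == "noise"],
             ev$baseline[1] + 3 * sqrt(0.25 / n) + 0.05)
})
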