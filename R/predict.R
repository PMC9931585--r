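#' Register an image-embedding backbone
#'
#' A backbone is a pure function from a single-channel image (numeric
#' matrix, scaled to `[0, 1]`) to a fixed-length feature vector. The
#' reference design in the field feeds each channel to a convolutional
#' network pretrained on natural images (an ImageNet ResNet-50, whose
#' penultimate layer yields 2,048 features per channel); any such model
#' can be plugged in here. The built-in `"testhash"` backbone is a
#' deterministic, download-free stand-in: multi-scale pooled intensity and
#' texture statistics pushed through a fixed random projection to 2,048
#' dimensions.
#'
#' @param id backbone identifier.
#' @param fn function(matrix) -> numeric vector of length `output_dim`.
#' @param output_dim embedding length.
#' @export
register_backbone <- function(id, fn, output_dim) {
  if (is.null(.imctme_env$backbones)) .imctme_env$backbones <- list()
  .imctme_env$backbones[[id]] <- list(id = id, fn = fn,
                                      output_dim = as.integer(output_dim))
  invisible(id)
}

#' Look up a registered backbone
#' @param id backbone identifier.
#' @return list with `id`, `fn`, `output_dim`.
#' @export
get_backbone <- function(id) {
  b <- .imctme_env$backbones[[id]]
  if (is.null(b))
    stop("unknown backbone '", id, "'; registered: ",
         paste(names(.imctme_env$backbones), collapse = ", "))
  b
}

# block-mean reduction of a matrix to a g x g grid
block_means <- function(x, g) {
  ri <- cut(seq_len(nrow(x)), g, labels = FALSE)
  ci <- cut(seq_len(ncol(x)), g, labels = FALSE)
  rowsum_r <- rowsum(x, ri)
  cnt_r <- tabulate(ri, g)
  m <- t(rowsum(t(rowsum_r), ci)) / outer(cnt_r, tabulate(ci, g))
  as.vector(m)
}

# Multi-scale pooled statistics of a [0,1]-scaled channel. Like the
# global-average-pooled features of a convolutional backbone, every
# statistic is translation invariant: per spatial scale we summarize the
# *distribution* of block means (aggregated marker signal) rather than
# their layout, so cores differing only in where cells landed embed
# nearby, while cores differing in how clustered the signal is separate.
testhash_stats <- function(x) {
  per_scale <- unlist(lapply(c(2L, 4L, 8L, 16L, 32L), function(g) {
    b <- block_means(x, min(g, nrow(x), ncol(x)))
    c(mean(b), if (length(b) > 1) sd(b) else 0, max(b),
      quantile(b, c(0.1, 0.5, 0.9, 0.99), names = FALSE, type = 7))
  }))
  gx <- x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE]
  gy <- x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE]
  c(mean(x), sd(x),
    quantile(x, c(0.5, 0.9, 0.99, 0.999), names = FALSE, type = 7),
    mean(x > 0.25), mean(x > 0.5), mean(x > 0.75),
    mean(abs(gx)), mean(abs(gy)), sd(gx), sd(gy),
    per_scale)
}

.testhash_dim <- 2048L

testhash_projection <- function(n_stats, output_dim) {
  key <- paste0("proj_", n_stats, "_", output_dim)
  if (is.null(.imctme_env[[key]])) {
    # fixed projection: part of the backbone definition, not of any run
    .imctme_env[[key]] <- with_seed(derive_seed(20240101L, key), {
      matrix(rnorm(n_stats * output_dim) / sqrt(n_stats), n_stats, output_dim)
    })
  }
  .imctme_env[[key]]
}

testhash_backbone <- function(x) {
  f <- testhash_stats(x)
  as.numeric(f %*% testhash_projection(length(f), .testhash_dim))
}

.onLoad <- function(libname, pkgname) {
  register_backbone("testhash", testhash_backbone, .testhash_dim)
}

#' Embed the channels of one core
#'
#' Each selected channel is scaled by its 99th percentile (clipped to
#' `[0, 1]`), embedded by the backbone, and the per-channel embeddings are
#' concatenated in panel order into one feature vector for the core.
#'
#' @param stack a [core_stack()].
#' @param backbone backbone id (default `"testhash"`).
#' @param channels channel subset (default: all channels of the stack).
#' @return numeric vector of length `length(channels) * output_dim`, with
#'   a `blocks` attribute naming the channel of each position.
#' @export
embed_channels <- function(stack, backbone = "testhash",
                           channels = names(stack$channels)) {
  b <- get_backbone(backbone)
  miss <- setdiff(channels, names(stack$channels))
  if (length(miss)) stop("stack misses channel(s): ",
                         paste(miss, collapse = ", "))
  channels <- names(stack$channels)[names(stack$channels) %in% channels]
  parts <- lapply(channels, function(nm) {
    x <- stack$channels[[nm]]
    q <- quantile(x, 0.99, names = FALSE, type = 7)
    if (q > 0) x <- pmin(x / q, 1)
    v <- b$fn(x)
    if (length(v) != b$output_dim)
      stop("backbone '", backbone, "' returned length ", length(v),
           ", expected ", b$output_dim)
    v
  })
  out <- unlist(parts)
  attr(out, "blocks") <- rep(channels, each = b$output_dim)
  out
}

#' Embed a cohort of cores
#'
#' @param stacks named list of [core_stack()]s.
#' @param backbone backbone id.
#' @param channels channel subset.
#' @return matrix (cores x features) with a `blocks` attribute.
#' @export
embed_cohort <- function(stacks, backbone = "testhash",
                         channels = names(stacks[[1]]$channels)) {
  rows <- lapply(stacks, embed_channels, backbone = backbone,
                 channels = channels)
  out <- do.call(rbind, rows)
  rownames(out) <- names(stacks)
  attr(out, "blocks") <- attr(rows[[1]], "blocks")
  out
}

#' Fit a sparse principal component reduction
#'
#' Sequential rank-one sparse PCA by truncated power iteration: each
#' component is the dominant singular direction of the (deflated, centred)
#' feature matrix with all but the `keep_x` largest-magnitude loadings set
#' to zero, re-normalized and iterated to convergence. Initialisation uses
#' the exact leading singular vector (computed from the small
#' cores-by-cores Gram matrix), so the fit is deterministic. With
#' `keep_x = ncol(X)` the components coincide with ordinary PCA loadings.
#'
#' Successive components are found on the residual after score-space
#' deflation (the previous component's score direction is projected out),
#' so scores are mutually orthogonal and components do not repeat.
#'
#' @param X training feature matrix (cores x features).
#' @param n_components number of components (default 9).
#' @param keep_x nonzero loadings per component; the default keeps half
#'   the features (`ceiling(ncol(X)/2)`), a mild sparsity that lets a
#'   component span several channel blocks while still zeroing diffuse
#'   noise loadings.
#' @param seed accepted for interface stability; the fit is deterministic.
#' @return object of class `sparse_pca`: `loadings` (features x
#'   components), `center`, `scores` (training scores), `keep_x`.
#' @export
fit_sparse_pca <- function(X, n_components = 9L, keep_x = NULL, seed = 0L) {
  X <- as.matrix(X)
  n_components <- as.integer(n_components)
  if (n_components > min(dim(X)))
    stop("n_components exceeds min(#cores, feature dimension)")
  keep_x <- as.integer(keep_x %||% ceiling(ncol(X) / 2))
  keep_x <- max(1L, min(keep_x, ncol(X)))
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  W <- matrix(0, ncol(X), n_components)
  truncate_v <- function(v) {
    if (keep_x < length(v)) {
      thr <- sort(abs(v), decreasing = TRUE)[keep_x]
      v[abs(v) < thr] <- 0
    }
    nv <- sqrt(sum(v^2))
    if (nv == 0) v else v / nv
  }
  for (c_ in seq_len(n_components)) {
    G <- tcrossprod(Xc)  # n x n
    eg <- eigen(G, symmetric = TRUE)
    u <- eg$vectors[, 1]
    v <- truncate_v(as.numeric(crossprod(Xc, u)))
    for (it in seq_len(200L)) {
      v_new <- truncate_v(as.numeric(crossprod(Xc, Xc %*% v)))
      if (sum((v_new - v)^2) < 1e-12 || sum((v_new + v)^2) < 1e-12) {
        v <- v_new; break
      }
      v <- v_new
    }
    j <- which.max(abs(v))
    if (v[j] < 0) v <- -v
    W[, c_] <- v
    s <- Xc %*% v
    ss <- sum(s^2)
    if (ss > 0) Xc <- Xc - s %*% (crossprod(s, Xc) / ss)
  }
  structure(list(loadings = W, center = center,
                 scores = sweep(X, 2, center) %*% W, keep_x = keep_x),
            class = "sparse_pca")
}

#' Project new cores onto fitted sparse components
#' @param object a [fit_sparse_pca()] result.
#' @param newdata matrix (cores x features) on the training feature space.
#' @param ... unused.
#' @return matrix (cores x components).
#' @export
predict.sparse_pca <- function(object, newdata, ...) {
  sweep(as.matrix(newdata), 2, object$center) %*% object$loadings
}

#' Random oversampling to class parity
#'
#' Returns row indices in which every class reaches the majority-class
#' count by sampling its own rows with replacement; the original rows are
#' always kept.
#'
#' @param labels class labels.
#' @param seed integer seed.
#' @return integer index vector.
#' @export
random_oversample <- function(labels, seed = 1L) {
  tab <- table(labels)
  target <- max(tab)
  with_seed(seed, {
    extra <- unlist(lapply(names(tab), function(cl) {
      idx <- which(labels == cl)
      need <- target - length(idx)
      if (need > 0) sample(idx, need, replace = TRUE) else integer()
    }))
    c(seq_along(labels), extra)
  })
}

#' Majority-class baseline prediction score
#'
#' The accuracy of always predicting the most frequent class: the count of
#' the modal class over the total number of examples.
#'
#' @param labels class labels.
#' @return fraction in `(0, 1]`.
#' @export
baseline_score <- function(labels) {
  stopifnot(length(labels) > 0)
  max(table(labels)) / length(labels)
}

# stratified, grouped fold assignment: groups (patients) are dealt
# round-robin to folds within each class after a seeded shuffle
make_folds <- function(labels, groups, k, seed) {
  gu <- unique(groups)
  glab <- labels[match(gu, groups)]
  fold_of_group <- integer(length(gu))
  with_seed(seed, {
    for (cl in unique(glab)) {
      idx <- which(glab == cl)
      idx <- idx[sample.int(length(idx))]
      fold_of_group[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold_of_group[match(groups, gu)]
}

#' Cross-validated RBF-SVM evaluation of a feature source
#'
#' Five-fold (by default) cross-validation of the prediction framework:
#' within each fold, the sparse principal component reduction is fitted on
#' the training cores only, the training classes are randomly oversampled
#' to parity, and an RBF-kernel support vector machine (cost 1, bandwidth
#' `1 / (d * var)`) is trained and evaluated on the held-out fold. Folds
#' are stratified by class and grouped by patient, so two cores of one
#' patient never straddle the train/test split. All randomness (fold
#' assignment, oversampling) derives from `seed`.
#'
#' @param features matrix (cores x features).
#' @param labels class labels per core.
#' @param groups grouping (patient id) per core; default one group per core.
#' @param k number of folds (default 5).
#' @param n_components sparse-PCA components (default 9).
#' @param keep_x forwarded to [fit_sparse_pca()].
#' @param seed integer seed.
#' @param fold optional precomputed fold assignment per core (overrides the
#'   stratified grouped assignment; used e.g. to audit that held-out labels
#'   cannot influence training).
#' @param source descriptor recorded on the report.
#' @return object of class `prediction_report`: per-fold and mean accuracy,
#'   macro-averaged precision and recall over the pooled held-out
#'   predictions, the baseline score, per-core predictions, fold
#'   assignment, per-fold training artifacts (reducer centre/loadings and
#'   oversample indices, for leakage audits) and, when any patient has two
#'   cores, the fraction of such patients whose cores receive the same
#'   predicted label (`two_core_agreement`).
#' @export
train_eval <- function(features, labels, groups = NULL, k = 5L,
                       n_components = 9L, keep_x = NULL, seed = 1L,
                       fold = NULL, source = "features") {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2L) stop("need at least two classes")
  if (is.null(groups)) groups <- seq_len(nrow(features))
  if (is.null(fold))
    fold <- make_folds(labels, groups, k, derive_seed(seed, "folds"))
  stopifnot(length(fold) == length(labels))
  pred <- rep(NA_character_, length(labels))
  fold_acc <- rep(NA_real_, k)
  fold_valid <- rep(TRUE, k)
  artifacts <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    if (!any(te)) { fold_valid[f] <- FALSE; next }
    if (length(unique(labels[tr])) < length(unique(labels))) {
      fold_valid[f] <- FALSE
      tme_log("warn", "fold ", f, " lacks a class in training; flagged invalid")
      next
    }
    red <- fit_sparse_pca(features[tr, , drop = FALSE],
                          n_components = n_components, keep_x = keep_x)
    os <- random_oversample(labels[tr], derive_seed(seed, paste0("os", f)))
    Ztr <- red$scores[os, , drop = FALSE]
    ytr <- factor(labels[tr][os])
    gamma <- 1 / (ncol(Ztr) * max(var(as.vector(Ztr)), 1e-12))
    fit <- e1071::svm(Ztr, ytr, kernel = "radial", cost = 1, gamma = gamma,
                      scale = FALSE)
    Zte <- predict(red, features[te, , drop = FALSE])
    pred[te] <- as.character(predict(fit, Zte))
    fold_acc[f] <- mean(pred[te] == labels[te])
    artifacts[[f]] <- list(center = red$center, loadings = red$loadings,
                           oversample = os)
  }
  ok <- !is.na(pred)
  classes <- sort(unique(labels))
  conf <- table(factor(labels[ok], classes), factor(pred[ok], classes))
  precision <- mean(diag(conf) / pmax(colSums(conf), 1))
  recall <- mean(diag(conf) / pmax(rowSums(conf), 1))
  agreement <- NA_real_
  multi <- names(which(table(groups) >= 2))
  if (length(multi)) {
    agreement <- mean(vapply(multi, function(g) {
      p <- pred[groups == g]
      length(unique(p[!is.na(p)])) == 1L
    }, logical(1)))
  }
  structure(list(
    source = source, fold_accuracy = fold_acc, fold_valid = fold_valid,
    mean_accuracy = mean(fold_acc[fold_valid]),
    sd_accuracy = sd(fold_acc[fold_valid]),
    precision = precision, recall = recall,
    baseline = as.numeric(baseline_score(labels)),
    n_components = as.integer(n_components), k = as.integer(k),
    seed = as.integer(seed), fold = fold, predictions = pred,
    labels = labels, two_core_agreement = agreement,
    artifacts = artifacts), class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> %s: accuracy %.3f +/- %.3f (baseline %.3f), precision %.3f, recall %.3f\n",
              x$source, x$mean_accuracy, x$sd_accuracy, x$baseline,
              x$precision, x$recall))
  invisible(x)
}

#' Rank markers by single-channel predictive accuracy
#'
#' Evaluates the prediction framework once per marker, using only that
#' channel's embedding, and ranks markers by mean cross-validated
#' accuracy (ties broken by panel order).
#'
#' @param stacks named list of [core_stack()]s.
#' @param labels class labels per core.
#' @param markers markers to rank (default: all channels).
#' @param backbone backbone id.
#' @param groups,k,n_components,seed forwarded to [train_eval()].
#' @return data.frame `marker`, `mean_accuracy`, `rank`, in rank order.
#' @export
rank_markers <- function(stacks, labels, markers = names(stacks[[1]]$channels),
                         backbone = "testhash", groups = NULL, k = 5L,
                         n_components = 9L, seed = 1L) {
  if (length(markers) < 2L) stop("need at least two markers to rank")
  emb <- embed_cohort(stacks, backbone, markers)
  blocks <- attr(emb, "blocks")
  acc <- vapply(markers, function(m) {
    rep <- train_eval(emb[, blocks == m, drop = FALSE], labels,
                      groups = groups, k = k,
                      n_components = min(n_components, sum(blocks == m),
                                         length(labels) - 1L),
                      seed = seed, source = paste0("raw:", m))
    rep$mean_accuracy
  }, numeric(1))
  ord <- order(-acc, match(markers, markers))
  data.frame(marker = markers[ord], mean_accuracy = acc[ord],
             rank = seq_along(markers), row.names = NULL)
}

#' Evaluate channel subsets
#'
#' Runs the prediction framework once per channel subset and tabulates the
#' cross-validated accuracy, precision and recall of each, for comparing
#' top-ranked or biologically chosen marker combinations against the full
#' panel.
#'
#' @param stacks named list of [core_stack()]s.
#' @param labels class labels per core.
#' @param subsets named list of character channel sets.
#' @param backbone backbone id.
#' @param groups,k,n_components,seed forwarded to [train_eval()].
#' @return data.frame: `subset`, `n_channels`, `mean_accuracy`,
#'   `sd_accuracy`, `precision`, `recall`, `baseline`.
#' @export
evaluate_subsets <- function(stacks, labels, subsets, backbone = "testhash",
                             groups = NULL, k = 5L, n_components = 9L,
                             seed = 1L) {
  stopifnot(length(subsets) >= 1, all(lengths(subsets) >= 1))
  emb <- embed_cohort(stacks, backbone)
  blocks <- attr(emb, "blocks")
  rows <- lapply(seq_along(subsets), function(i) {
    ch <- subsets[[i]]
    rep <- train_eval(emb[, blocks %in% ch, drop = FALSE], labels,
                      groups = groups, k = k, n_components = n_components,
                      seed = seed,
                      source = paste0("subset:", paste(ch, collapse = "+")))
    data.frame(subset = names(subsets)[i] %||% paste(ch, collapse = "+"),
               n_channels = length(ch),
               mean_accuracy = rep$mean_accuracy,
               sd_accuracy = rep$sd_accuracy, precision = rep$precision,
               recall = rep$recall, baseline = rep$baseline)
  })
  do.call(rbind, rows)
}

#' Cell-frequency feature source
#'
#' Per-core cell-type frequency vectors, the non-spatial comparator of the
#' prediction framework.
#'
#' @param table cohort cell table.
#' @param types type columns (default observed).
#' @return matrix cores x types.
#' @export
features_from_frequencies <- function(table,
                                      types = sort(unique(table$lineage))) {
  compute_frequencies(table, types = types)$total
}

#' Clinical-covariate feature source
#'
#' Numeric encoding of routine clinical covariates (sex, age, BMI, smoking,
#' pack-years, stage, histology) per core.
#'
#' @param clinical validated clinical table.
#' @return matrix with core ids as rownames.
#' @export
features_from_clinical <- function(clinical) {
  bc <- clinical_by_core(clinical)
  out <- cbind(
    sex = as.integer(bc$sex == "M"),
    age = bc$age, bmi = bc$bmi,
    smoking = as.integer(bc$smoking == "smoker"),
    pack_years = bc$pack_years,
    stage = as.integer(bc$stage == "III-IV"),
    histology = as.integer(factor(bc$histology,
                                  c("lepidic", "papillary", "acinar",
                                    "micropapillary", "solid"))))
  rownames(out) <- bc$core_id
  out
}
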