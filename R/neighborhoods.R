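#' Nearest-neighbour composition windows
#'
#' For every cell, finds its `n` nearest cells within the same core
#' (Euclidean distance on centroids, ties broken by cell id) and records
#' the cell-type frequency vector of that window. The index cell is
#' excluded from its own window by default; both conventions exist in the
#' neighbourhood literature, so inclusion is a flag. Cores with fewer than
#' `n + 1` cells yield windows over all available neighbours and are
#' flagged as truncated; cores with fewer than 2 cells are skipped with a
#' warning.
#'
#' @param table cell table (needs `cell_id`, `core_id`, `row`, `col`,
#'   `lineage`).
#' @param n window size (default 10 nearest neighbours).
#' @param type_levels cell-type columns of the frequency vectors
#'   (default: observed labels).
#' @param include_self include the index cell in its own window.
#' @return list with `freq` (cells x types matrix, rows sum to 1), `cells`
#'   (data.frame `cell_id`, `core_id`, `truncated`) and `n`.
#' @export
window_vectors <- function(table, n = 10L,
                           type_levels = sort(unique(table$lineage)),
                           include_self = FALSE) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  pieces <- split(seq_len(nrow(table)), table$core_id)
  freq <- list(); meta <- list()
  for (cid in names(pieces)) {
    rows <- pieces[[cid]]
    if (length(rows) < 2L) {
      tme_log("warn", "core '", cid, "' has < 2 cells; skipped")
      next
    }
    sub <- table[rows, , drop = FALSE]
    ord0 <- order(sub$cell_id)
    sub <- sub[ord0, , drop = FALSE]
    m <- length(rows)
    dmat <- as.matrix(stats::dist(cbind(sub$row, sub$col)))
    if (!include_self) diag(dmat) <- Inf
    k <- min(n, if (include_self) m else m - 1L)
    fac <- factor(sub$lineage, levels = type_levels)
    fv <- matrix(0, m, length(type_levels),
                 dimnames = list(NULL, type_levels))
    for (i in seq_len(m)) {
      # ties at equal distance resolved by cell id (rows are id-sorted)
      nb <- order(dmat[i, ])[seq_len(k)]
      fv[i, ] <- tabulate(fac[nb], nbins = length(type_levels)) / k
    }
    freq[[cid]] <- fv
    meta[[cid]] <- data.frame(cell_id = sub$cell_id, core_id = cid,
                              truncated = k < n, stringsAsFactors = FALSE)
  }
  if (!length(freq)) stop("no core with at least 2 cells")
  list(freq = do.call(rbind, freq), cells = do.call(rbind, meta), n = n)
}

# k-means++ seeding over rows of X
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  i <- sample.int(n, 1L)
  centers[1, ] <- X[i, ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (c_ in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) i <- sample.int(n, 1L)
    else i <- sample.int(n, 1L, prob = d2)
    centers[c_, ] <- X[i, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[c_, ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  centers
}

nearest_center <- function(X, centers) {
  cross <- X %*% t(centers)
  d2 <- outer(rep(1, nrow(X)), rowSums(centers^2)) - 2 * cross
  max.col(-d2, ties.method = "first")
}

#' Cluster composition windows into cellular neighbourhoods
#'
#' Mini-batch k-means over the window frequency vectors: k-means++
#' seeding, then stochastic center updates on seeded random batches with
#' per-center learning rates `1/count`, followed by a final full
#' assignment of every cell to its nearest center. Centers that remain
#' empty during training are re-seeded from the data. The whole procedure
#' is deterministic given `seed`.
#'
#' @param wv result of [window_vectors()].
#' @param tCN number of neighbourhoods (clusters).
#' @param batch_size mini-batch size (default 100).
#' @param seed integer seed (default 0).
#' @param max_steps number of mini-batch updates (default: enough for
#'   roughly ten passes, capped at 1500).
#' @return a `neighborhood_model`: list with `n`, `tCN`, `centroids`
#'   (tCN x types), `labels` (integer per cell, aligned to `wv$cells`),
#'   `cells`, `batch_size`, `seed`, `type_levels`.
#' @export
cluster_windows <- function(wv, tCN, batch_size = 100L, seed = 0L,
                            max_steps = NULL) {
  X <- wv$freq
  tCN <- as.integer(tCN)
  if (tCN < 1L) stop("tCN must be >= 1")
  if (tCN > nrow(X)) stop("tCN exceeds the number of window vectors")
  if (is.null(max_steps))
    max_steps <- min(1500L, max(200L, ceiling(10 * nrow(X) / batch_size)))
  if (tCN == 1L) {
    centers <- matrix(colMeans(X), 1, ncol(X))
  } else {
    centers <- with_seed(seed, {
      cen <- kmeanspp_init(X, tCN)
      counts <- rep(0, tCN)
      for (s in seq_len(max_steps)) {
        batch <- sample.int(nrow(X), min(batch_size, nrow(X)))
        lab <- nearest_center(X[batch, , drop = FALSE], cen)
        for (c_ in unique(lab)) {
          rows <- batch[lab == c_]
          counts[c_] <- counts[c_] + length(rows)
          eta <- length(rows) / counts[c_]
          cen[c_, ] <- (1 - eta) * cen[c_, ] +
            eta * colMeans(X[rows, , drop = FALSE])
        }
        if (s %% 50L == 0L && any(counts == 0)) {
          for (c_ in which(counts == 0)) cen[c_, ] <- X[sample.int(nrow(X), 1L), ]
        }
      }
      cen
    })
  }
  labels <- nearest_center(X, centers)
  colnames(centers) <- colnames(X)
  structure(list(n = wv$n, tCN = tCN, centroids = centers, labels = labels,
                 cells = wv$cells, batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 type_levels = colnames(X)),
            class = "neighborhood_model")
}

#' @export
print.neighborhood_model <- function(x, ...) {
  cat(sprintf("<neighborhood_model> tCN = %d neighbourhoods, window n = %d, %d cells\n",
              x$tCN, x$n, length(x$labels)))
  invisible(x)
}

#' Per-core neighbourhood prevalence
#'
#' Fraction of each core's cells allocated to each neighbourhood,
#' normalized so the prevalences of a core sum to 100 percent. Raw
#' fractions are returned alongside display percentages rounded by largest
#' remainder so each row still sums to exactly 100.
#'
#' @param model a [cluster_windows()] result.
#' @return list with `fraction` and `percent` matrices (cores x CNs).
#' @export
cn_prevalence <- function(model) {
  cores <- unique(model$cells$core_id)
  frac <- t(vapply(cores, function(cid) {
    lab <- model$labels[model$cells$core_id == cid]
    tabulate(lab, nbins = model$tCN) / length(lab)
  }, numeric(model$tCN)))
  dimnames(frac) <- list(cores, paste0("CN", seq_len(model$tCN)))
  pct <- t(apply(frac, 1, largest_remainder_percent))
  dimnames(pct) <- dimnames(frac)
  list(fraction = frac, percent = pct)
}

#' Characterize neighbourhoods by enriched cell types
#'
#' Mean window composition per neighbourhood, plus a display matrix
#' normalized per type to the 95th percentile and z-scored across
#' neighbourhoods (the convention used for composition heatmaps).
#'
#' @param model a [cluster_windows()] result.
#' @param wv the [window_vectors()] the model was fit on.
#' @return list with `composition` (tCN x types mean window composition)
#'   and `display` (95th-percentile-normalized, z-scored per type).
#' @export
characterize_cns <- function(model, wv) {
  comp <- t(vapply(seq_len(model$tCN), function(c_) {
    rows <- model$labels == c_
    if (!any(rows)) return(rep(NA_real_, ncol(wv$freq)))
    colMeans(wv$freq[rows, , drop = FALSE])
  }, numeric(ncol(wv$freq))))
  dimnames(comp) <- list(paste0("CN", seq_len(model$tCN)), colnames(wv$freq))
  display <- apply(comp, 2, function(col) {
    ok <- is.finite(col)
    out <- col
    v <- percentile_normalize(col[ok], 95)
    out[ok] <- if (sd(v) == 0) 0 else (v - mean(v)) / sd(v)
    out
  })
  dimnames(display) <- dimnames(comp)
  list(composition = comp, display = display)
}

#' Sweep window size and neighbourhood count with survival read-out
#'
#' Refits neighbourhoods over a grid of window sizes `n` and cluster
#' counts `tCN`, and for each fitted model reports every neighbourhood's
#' z-stratified log-rank survival association, mirroring the robustness
#' sweep used to show that survival-linked neighbourhoods persist across
#' window sizes.
#'
#' @param table cohort cell table.
#' @param clinical validated clinical table.
#' @param n_values window sizes (default 3:30).
#' @param tCN_values cluster counts (default c(10, 30)).
#' @param type_levels forwarded to [window_vectors()].
#' @param batch_size,seed forwarded to [cluster_windows()].
#' @return data.frame: `n`, `tCN`, `cn`, `n_high`, `n_low`, `chisq`,
#'   `p_value`, `direction`.
#' @export
cn_sweep <- function(table, clinical, n_values = 3:30,
                     tCN_values = c(10L, 30L),
                     type_levels = sort(unique(table$lineage)),
                     batch_size = 100L, seed = 0L) {
  bycore <- clinical_by_core(clinical)
  out <- list()
  for (n in n_values) {
    wv <- window_vectors(table, n = n, type_levels = type_levels)
    for (tCN in tCN_values) {
      model <- cluster_windows(wv, tCN = tCN, batch_size = batch_size,
                               seed = seed)
      prev <- cn_prevalence(model)$fraction
      pat <- patient_prevalence(prev, bycore)
      scan <- survival_scan(pat$values, pat$clinical$survival_months,
                            pat$clinical$event)
      scan$n <- n; scan$tCN <- tCN
      names(scan)[names(scan) == "variable"] <- "cn"
      out[[length(out) + 1L]] <- scan
    }
  }
  res <- do.call(rbind, out)
  res[, c("n", "tCN", "cn", "n_high", "n_low", "chisq", "p_value",
          "direction")]
}

#' Average a per-core matrix to patient level
#'
#' Patients contributing several cores get the mean of their cores'
#' values (the convention for two-core validation cohorts).
#'
#' @param core_values matrix with core ids as rownames.
#' @param clinical_by_core output of [clinical_by_core()].
#' @return list with `values` (patients x columns) and `clinical` (one row
#'   per patient, aligned).
#' @export
patient_prevalence <- function(core_values, clinical_by_core) {
  pid <- clinical_by_core$patient_id[match(rownames(core_values),
                                           clinical_by_core$core_id)]
  if (any(is.na(pid)))
    stop("cores without a patient: ",
         paste(rownames(core_values)[is.na(pid)], collapse = ", "))
  agg <- aggregate(core_values, by = list(patient_id = pid), mean)
  vals <- as.matrix(agg[, -1, drop = FALSE])
  rownames(vals) <- agg$patient_id
  cl <- clinical_by_core[!duplicated(clinical_by_core$patient_id), ]
  cl <- cl[match(agg$patient_id, cl$patient_id), ]
  list(values = vals, clinical = cl)
}
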