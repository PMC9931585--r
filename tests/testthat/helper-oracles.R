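# Independent brute-force oracles used across tests. These deliberately
# re-derive each operation from its definition, without touching the
# package's implementation paths.

# median filter with edge replication, computed pixel by pixel
oracle_median_filter <- function(x, window) {
  h <- window %/% 2
  out <- x
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      ii <- pmin(pmax((i - h):(i + h), 1), nrow(x))
      jj <- pmin(pmax((j - h):(j + h), 1), ncol(x))
      out[i, j] <- median(as.vector(x[ii, jj]))
    }
  }
  out
}

# 1-D k-means: Lloyd to convergence, best of `starts` seeded restarts;
# returns per-pixel levels ordered by cluster mean
oracle_kmeans1d <- function(v, k, starts = 50, seed = 1) {
  best <- NULL; best_sse <- Inf
  uq <- unique(v)
  set.seed(seed)
  for (s in seq_len(starts)) {
    centers <- sample(uq, k)
    for (it in 1:200) {
      lab <- apply(abs(outer(v, centers, "-")), 1, which.min)
      new_centers <- vapply(seq_len(k), function(c_) {
        if (any(lab == c_)) mean(v[lab == c_]) else centers[c_]
      }, numeric(1))
      if (max(abs(new_centers - centers)) < 1e-12) break
      centers <- new_centers
    }
    sse <- sum((v - centers[lab])^2)
    if (sse < best_sse) { best_sse <- sse; best <- list(lab = lab, centers = centers) }
  }
  ord <- order(best$centers)
  match(best$lab, ord)
}

# exhaustive 1-D k-means: every optimal clustering is a set of contiguous
# intervals of the sorted distinct values, so enumerating all cut-point
# combinations gives the exact global minimum SSE
oracle_kmeans1d_min_sse <- function(v, k) {
  uq <- sort(unique(v))
  m <- length(uq)
  w <- as.numeric(table(factor(v, levels = uq)))
  if (m <= k) return(0)
  cuts <- utils::combn(m - 1, k - 1)
  sse_of <- function(cut) {
    bounds <- c(0, cut, m)
    s <- 0
    for (j in seq_len(k)) {
      idx <- (bounds[j] + 1):bounds[j + 1]
      mu <- sum(uq[idx] * w[idx]) / sum(w[idx])
      s <- s + sum(w[idx] * (uq[idx] - mu)^2)
    }
    s
  }
  min(apply(cuts, 2, sse_of))
}

# connected-component small-blob removal by recursive flood fill (8-conn)
oracle_remove_blobs <- function(mask, min_area) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (j0 in seq_len(ncol(mask))) for (i0 in seq_len(nrow(mask))) {
    if (!mask[i0, j0] || lab[i0, j0] > 0L) next
    cur <- cur + 1L
    stack <- list(c(i0, j0)); lab[i0, j0] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        i <- p[1] + di; j <- p[2] + dj
        if (i >= 1 && j >= 1 && i <= nrow(mask) && j <= ncol(mask) &&
            mask[i, j] && lab[i, j] == 0L) {
          lab[i, j] <- cur
          stack[[length(stack) + 1L]] <- c(i, j)
        }
      }
    }
  }
  sizes <- tabulate(lab[lab > 0L], nbins = max(cur, 1L))
  mask & matrix(lab %in% which(sizes >= min_area), nrow(mask), ncol(mask))
}

# textbook product-limit estimator
oracle_km <- function(times, events) {
  ut <- sort(unique(times[events > 0]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    n_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events > 0)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  data.frame(time = ut, surv = out)
}

# textbook two-group log-rank O/E/V accumulation over event times
oracle_logrank <- function(times, events, group) {
  g <- as.integer(as.factor(group))
  ut <- sort(unique(times[events > 0]))
  O1 <- E1 <- V <- 0
  for (t in ut) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(times == t & events > 0)
    d1 <- sum(times == t & events > 0 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O1 - E1)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# exhaustive permutation p-values for the pairwise neighbour-count
# statistic on a tiny core (all n! label orders, counted directly)
oracle_exact_interaction <- function(edges, ids, types, a, b) {
  stat <- function(lab) {
    acells <- ids[lab == a]
    if (!length(acells)) return(NA_real_)
    cnt <- 0
    for (ac in acells) {
      nb <- c(edges[edges[, 1] == ac, 2], edges[edges[, 2] == ac, 1])
      cnt <- cnt + sum(lab[match(nb, ids)] == b)
    }
    cnt / length(acells)
  }
  obs <- stat(types)
  perms <- all_permutations(types)
  vals <- vapply(perms, stat, numeric(1))
  list(obs = obs,
       p_interact = mean(vals >= obs), p_avoid = mean(vals <= obs))
}

all_permutations <- function(x) {
  n <- length(x)
  if (n == 1) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in all_permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# small synthetic specs shared across tests (96 px cores keep runtimes low)
tiny_spec <- function(seed = 1, sigma = 0.3, ...) {
  synthetic_spec(n_patients = 2L, image_size = c(96L, 96L),
                 cell_density = 70, signal = signal_model(sigma = sigma),
                 seed = seed, ...)
}
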