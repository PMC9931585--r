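#' Build the cell adjacency graph of a core
#'
#' Two cells interact when they lie within `d` pixels of each other. Under
#' the `boundary` rule (default) the distance is the minimum pixel-to-pixel
#' distance between the two cell masks (inclusive at exactly `d`); the
#' `centroid` rule uses centroid distance and is available as a cheaper
#' fallback. Candidate pairs are pre-filtered by centroid distance plus the
#' cells' radii, so only nearby pixel sets are compared.
#'
#' @param seg a [segmentation_map()].
#' @param d interaction distance in pixels (default 6).
#' @param rule `"boundary"` or `"centroid"`.
#' @return an `adjacency_graph`: list with `core_id`, `ids`, `edges`
#'   (two-column matrix of cell ids, each unordered pair once), `rule`, `d`.
#' @export
build_adjacency <- function(seg, d = 6, rule = c("boundary", "centroid")) {
  rule <- match.arg(rule)
  stopifnot(d > 0)
  ids <- as.integer(names(seg$cells))
  n <- length(ids)
  if (n < 2L) {
    return(structure(list(core_id = seg$core_id, ids = ids,
                          edges = matrix(integer(), 0, 2), rule = rule, d = d),
                     class = "adjacency_graph"))
  }
  cen <- as.matrix(seg$centroids[, c("row", "col")])
  cd <- as.matrix(stats::dist(cen))
  if (rule == "centroid") {
    hit <- which(cd <= d & upper.tri(cd), arr.ind = TRUE)
    edges <- cbind(ids[hit[, 1]], ids[hit[, 2]])
  } else {
    radius <- vapply(seq_len(n), function(i) {
      p <- seg$cells[[i]]
      sqrt(max((p[, "row"] - cen[i, 1])^2 + (p[, "col"] - cen[i, 2])^2))
    }, numeric(1))
    cand <- which(cd <= d + outer(radius, radius, "+") & upper.tri(cd),
                  arr.ind = TRUE)
    keep <- logical(nrow(cand))
    for (e in seq_len(nrow(cand))) {
      p1 <- seg$cells[[cand[e, 1]]]; p2 <- seg$cells[[cand[e, 2]]]
      d2 <- outer(p1[, "row"], p2[, "row"], "-")^2 +
            outer(p1[, "col"], p2[, "col"], "-")^2
      keep[e] <- min(d2) <= d^2
    }
    hit <- cand[keep, , drop = FALSE]
    edges <- cbind(ids[hit[, 1]], ids[hit[, 2]])
  }
  structure(list(core_id = seg$core_id, ids = ids, edges = edges,
                 rule = rule, d = d),
            class = "adjacency_graph")
}

#' Permutation test for pairwise cell-cell interaction and avoidance
#'
#' For every ordered type pair (A, B) the statistic is the mean number of
#' B neighbours per A cell. The null distribution shuffles cell-type labels
#' jointly over the fixed cell positions; the add-one estimator
#' `p = (1 + #permutations at least as extreme) / (1 + n_perm)` gives
#' `p_interact` (permuted statistic >= observed) and `p_avoid` (<=
#' observed). A pair is called an interaction or avoidance by its smaller
#' p-value when that p-value is below `alpha`. Pairs involving a type with
#' no cells in the core are reported with missing values.
#'
#' @param graph an [build_adjacency()] result.
#' @param types character vector of cell types, named by cell id (or in
#'   `graph$ids` order).
#' @param type_levels the full type label set to report (default: observed).
#' @param n_perm number of label permutations (default 1000).
#' @param alpha significance level (default 0.01).
#' @param seed integer seed for the permutations.
#' @return data.frame with one row per ordered type pair: `core_id`,
#'   `type_a`, `type_b`, `obs_mean`, `p_interact`, `p_avoid`, `call`,
#'   `n_perm`, `alpha`.
#' @export
interaction_test <- function(graph, types,
                             type_levels = sort(unique(types)),
                             n_perm = 1000L, alpha = 0.01, seed = 1L) {
  ids <- graph$ids
  n <- length(ids)
  if (!is.null(names(types))) types <- types[as.character(ids)]
  stopifnot(length(types) == n)
  present <- intersect(type_levels, unique(types))
  if (length(present) < 2L) stop("need at least two cell types present")

  fac <- factor(types, levels = present)
  Tm <- matrix(0, n, length(present))
  Tm[cbind(seq_len(n), as.integer(fac))] <- 1
  n_by <- colSums(Tm)
  A <- Matrix::sparseMatrix(
    i = match(graph$edges[, 1], ids), j = match(graph$edges[, 2], ids),
    x = 1, dims = c(n, n), symmetric = TRUE)

  stat <- function(M) as.matrix(Matrix::crossprod(M, A %*% M))
  obs <- stat(Tm)
  ge <- matrix(0L, length(present), length(present))
  le <- ge
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      Mp <- Tm[sample.int(n), , drop = FALSE]
      S <- stat(Mp)
      ge <- ge + (S >= obs)
      le <- le + (S <= obs)
    }
  })
  p_int <- (1 + ge) / (1 + n_perm)
  p_avd <- (1 + le) / (1 + n_perm)

  grid <- expand.grid(type_a = type_levels, type_b = type_levels,
                      stringsAsFactors = FALSE)
  res <- data.frame(core_id = graph$core_id, grid,
                    obs_mean = NA_real_, p_interact = NA_real_,
                    p_avoid = NA_real_, call = "missing",
                    n_perm = as.integer(n_perm), alpha = alpha,
                    stringsAsFactors = FALSE)
  ia <- match(res$type_a, present); ib <- match(res$type_b, present)
  ok <- !is.na(ia) & !is.na(ib)
  idx <- cbind(ia[ok], ib[ok])
  res$obs_mean[ok] <- obs[idx] / n_by[ia[ok]]
  res$p_interact[ok] <- p_int[idx]
  res$p_avoid[ok] <- p_avd[idx]
  call <- rep("none", sum(ok))
  pi_ <- res$p_interact[ok]; pa_ <- res$p_avoid[ok]
  call[pi_ < alpha & pi_ < pa_] <- "interaction"
  call[pa_ < alpha & pa_ < pi_] <- "avoidance"
  res$call[ok] <- call
  res
}

#' Aggregate interaction calls across cores by group
#'
#' Summarizes per-core interaction/avoidance calls into one matrix per
#' group (for example per histological pattern): each entry is the mean
#' signed call over the group's cores (+1 interaction, -1 avoidance,
#' 0 none), taken over the cores where the pair was testable.
#'
#' @param results row-bound [interaction_test()] results across cores.
#' @param groups named character vector, core id -> group label.
#' @return named list of matrices (ordered type_a x type_b) per group.
#' @export
group_heatmap <- function(results, groups) {
  results$group <- groups[results$core_id]
  if (any(is.na(results$group)))
    stop("cores without a group: ",
         paste(unique(results$core_id[is.na(results$group)]), collapse = ", "))
  types <- sort(unique(c(results$type_a, results$type_b)))
  lapply(split(results, results$group), function(gr) {
    if (nrow(gr) == 0L) stop("empty group")
    signed <- ifelse(gr$call == "interaction", 1,
                     ifelse(gr$call == "avoidance", -1,
                            ifelse(gr$call == "none", 0, NA)))
    out <- matrix(NA_real_, length(types), length(types),
                  dimnames = list(types, types))
    agg <- aggregate(signed, by = list(a = gr$type_a, b = gr$type_b),
                     FUN = function(v) mean(v, na.rm = TRUE))
    out[cbind(match(agg$a, types), match(agg$b, types))] <- agg$x
    out
  })
}
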