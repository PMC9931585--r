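#' Planted spatial niche specification
#'
#' A niche is a set of cell types that co-cluster around shared centres,
#' emulating multicellular communities (for instance B-cell aggregates with
#' T helper cells). A fraction `weight` of each member type's cells is
#' placed around the niche centres; the rest follow the core-wide baseline.
#'
#' @param name niche label recorded in the ground truth.
#' @param members character vector of member cell types.
#' @param weight fraction of member-type cells placed in the niche.
#' @param radius spatial spread (pixels); member positions are Gaussian
#'   around a centre with sd `radius / 2`.
#' @param n_centers number of niche centres per core.
#' @param weight_range optional length-2 range; when set, each core draws
#'   its own weight uniformly from it (and the realized value is recorded
#'   as a per-core feature `nichewt_<name>`), creating cores that differ
#'   only in spatial organisation.
#' @return a `niche_spec` list.
#' @export
niche_spec <- function(name, members, weight = 0.9, radius = 18,
                       n_centers = 2L, weight_range = NULL) {
  stopifnot(radius > 0, weight >= 0, weight <= 1)
  if (!is.null(weight_range))
    stopifnot(length(weight_range) == 2L, all(weight_range >= 0),
              all(weight_range <= 1))
  structure(list(name = name, members = members, weight = weight,
                 radius = radius, n_centers = as.integer(n_centers),
                 weight_range = weight_range),
            class = "niche_spec")
}

#' Planted pairwise interaction effect
#'
#' Positive strength attracts cells of type `b` toward their nearest `a`
#' neighbour (each displacement moves a `b` cell the given fraction of the
#' way); negative strength pushes `b` cells away from nearby `a` cells
#' within a repulsion radius. The displacement is applied for a bounded
#' number of iterations, giving an effect monotone in strength that the
#' permutation interaction test should detect.
#'
#' @param a,b cell-type labels.
#' @param strength in `[-1, 1]`; sign encodes attraction (+) or avoidance (-).
#' @param radius repulsion radius in pixels (avoidance only, default 25).
#' @param iterations displacement iterations (default 2).
#' @return an `interaction_effect` list.
#' @export
interaction_effect <- function(a, b, strength, radius = 25, iterations = 2L) {
  stopifnot(strength >= -1, strength <= 1)
  structure(list(a = a, b = b, strength = strength, radius = radius,
                 iterations = as.integer(iterations)),
            class = "interaction_effect")
}

#' Marker signal model
#'
#' Lineage channels read `on_mean` counts on their own type's pixels and
#' `off_mean` elsewhere, under multiplicative log-normal pixel noise
#' (IMC intensities are positive and right-skewed). `sigma` is the standard
#' deviation on the log scale; 0 disables noise.
#'
#' @param on_mean,off_mean mean counts on/off target (defaults 10 and 0.5,
#'   i.e. 5 percent off-target signal).
#' @param sigma log-normal sd (default 0.3).
#' @return a `signal_model` list.
#' @export
signal_model <- function(on_mean = 10, off_mean = 0.5, sigma = 0.3) {
  stopifnot(on_mean >= 0, off_mean >= 0, sigma >= 0)
  structure(list(on_mean = on_mean, off_mean = off_mean, sigma = sigma),
            class = "signal_model")
}

#' Outcome model specification
#'
#' Links per-patient realized core features (cell-type frequencies, niche
#' prevalences, mixing scores) to a progression label through a logistic
#' model and to survival through an exponential proportional-hazards model
#' with independent censoring. With all coefficients zero the baseline
#' survival median is `baseline_scale_months * log(2)`.
#'
#' @param logit_intercept intercept of the progression logit.
#' @param logit_coefs named numeric vector of logistic coefficients over
#'   feature columns.
#' @param surv_coefs named numeric vector of log-hazard coefficients.
#' @param baseline_scale_months exponential baseline scale (mean survival
#'   months at linear predictor 0; default 60).
#' @param censor_rate target censoring fraction in `[0, 1)`; censoring times
#'   are exponential, calibrated against the baseline hazard.
#' @return an `outcome_spec` list.
#' @export
outcome_spec <- function(logit_intercept = -1.6, logit_coefs = numeric(),
                         surv_coefs = numeric(),
                         baseline_scale_months = 60, censor_rate = 0.2) {
  stopifnot(censor_rate >= 0, censor_rate < 1, baseline_scale_months > 0)
  structure(list(logit_intercept = logit_intercept,
                 logit_coefs = logit_coefs, surv_coefs = surv_coefs,
                 baseline_scale_months = baseline_scale_months,
                 censor_rate = censor_rate),
            class = "outcome_spec")
}

#' Synthetic cohort specification
#'
#' Declares the study conditions a synthetic cohort emulates: cohort size,
#' core geometry (a 256 x 256 px core at 1 um/px stands in for a ~1 mm^2
#' tissue-microarray core), cell density and size, the cell-type mixture,
#' planted niches and pairwise interactions, the marker signal model,
#' functional-marker positivity, and the outcome model.
#'
#' @param n_patients number of patients (default 120).
#' @param cores_per_patient 1 (discovery-style) or 2 (validation-style).
#' @param image_size integer length-2 (rows, cols), default `c(256, 256)`.
#' @param cell_density cells per 10^4 px^2 (default 90, about 590 cells per
#'   default core).
#' @param cell_radius disc radius of a rendered cell in pixels (default 3;
#'   discs are truncated where they collide with already-placed cells).
#' @param type_proportions named vector over cell types summing to 1.
#' @param niche_specs list of [niche_spec()].
#' @param interaction_effects list of [interaction_effect()].
#' @param signal a [signal_model()] (or named list of per-marker models
#'   under `overrides`).
#' @param functional_model named list: functional marker -> `list(type =
#'   target cell type, fraction = positive fraction)`.
#' @param outcome an [outcome_spec()].
#' @param panel a [marker_panel()]; lineage markers must map one-to-one to
#'   `names(type_proportions)` via `rules`.
#' @param rules a [type_rules()] mapping markers to the planted types.
#' @param seed base seed; all per-core and outcome seeds derive from it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_patients = 120L, cores_per_patient = 1L,
                           image_size = c(256L, 256L), cell_density = 90,
                           cell_radius = 3L,
                           type_proportions = c(
                             Treg = 0.05, `B cell` = 0.10, Tc = 0.10,
                             TH = 0.12, Macrophage = 0.08, Neutrophil = 0.05,
                             Endothelial = 0.10, Tumour = 0.40),
                           niche_specs = list(),
                           interaction_effects = list(),
                           signal = signal_model(),
                           functional_model = list(
                             Ki67 = list(type = "Endothelial", fraction = 0.25),
                             HIF1a = list(type = "Neutrophil", fraction = 0.30),
                             pERK = list(type = "TH", fraction = 0.30)),
                           outcome = outcome_spec(),
                           panel = default_panel(),
                           rules = default_rules(),
                           seed = 1L) {
  stopifnot(abs(sum(type_proportions) - 1) < 1e-9,
            all(type_proportions >= 0), cell_density > 0, cell_radius >= 1)
  tp_types <- names(type_proportions)
  covered <- rules$type[match(lineage_markers(panel), rules$marker)]
  miss <- setdiff(tp_types, covered)
  if (length(miss))
    stop("type(s) without a lineage marker in the panel: ",
         paste(miss, collapse = ", "))
  for (ns in niche_specs) {
    bad <- setdiff(ns$members, tp_types)
    if (length(bad)) stop("niche '", ns$name, "' references unknown type(s): ",
                          paste(bad, collapse = ", "))
  }
  structure(list(
    n_patients = as.integer(n_patients),
    cores_per_patient = as.integer(cores_per_patient),
    image_size = as.integer(image_size), cell_density = cell_density,
    cell_radius = as.integer(cell_radius),
    type_proportions = type_proportions, niche_specs = niche_specs,
    interaction_effects = interaction_effects, signal = signal,
    functional_model = functional_model, outcome = outcome,
    panel = panel, rules = rules, seed = as.integer(seed)),
    class = "synthetic_spec")
}

# disc pixel offsets for a given radius, 0-centred
disc_offsets <- function(r) {
  g <- expand.grid(di = -r:r, dj = -r:r)
  g[g$di^2 + g$dj^2 <= r^2, , drop = FALSE]
}

# jitter offsets ordered by distance, used when a disc finds no free pixel
jitter_offsets <- function(max_r = 8L) {
  g <- expand.grid(di = -max_r:max_r, dj = -max_r:max_r)
  g <- g[order(g$di^2 + g$dj^2), ]
  g[-1, , drop = FALSE]
}

#' Generate one synthetic core
#'
#' Places cells by a marked point process (uniform baseline, niche members
#' clustered around niche centres, pairwise attraction/repulsion applied by
#' bounded nearest-neighbour displacement), rasterizes each cell as a
#' compact disc truncated at collisions, and renders one channel per panel
#' marker under the signal model. The planted lineage, niche membership and
#' functional positivity of every cell are returned as ground truth.
#'
#' @param spec a [synthetic_spec()].
#' @param core_id core identifier.
#' @param seed integer seed (defaults to a child of `spec$seed`).
#' @return list with `stack` ([core_stack()]), `seg` ([segmentation_map()]),
#'   `truth` (data.frame: `cell_id`, `core_id`, `row`, `col`, `lineage`,
#'   `niche`, one `pos_*` column per functional marker) and `niche_weights`
#'   (realized per-niche weights).
#' @export
generate_core <- function(spec, core_id = "core1",
                          seed = derive_seed(spec$seed, core_id)) {
  with_seed(seed, generate_core_impl(spec, core_id))
}

generate_core_impl <- function(spec, core_id) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  r <- spec$cell_radius
  n_cells <- max(2L, round(spec$cell_density * H * W / 1e4))
  types <- names(spec$type_proportions)
  type_of <- sample(types, n_cells, replace = TRUE,
                    prob = spec$type_proportions)

  # realized niche weights (per-core when a range is declared)
  nw <- vapply(spec$niche_specs, function(ns) {
    if (is.null(ns$weight_range)) ns$weight
    else runif(1, ns$weight_range[1], ns$weight_range[2])
  }, numeric(1))
  names(nw) <- vapply(spec$niche_specs, `[[`, "", "name")

  # niche membership
  niche_of <- rep("none", n_cells)
  niche_center <- vector("list", n_cells)
  # niche centres repel each other (distinct tissue compartments): a new
  # centre keeps at least the two niches' summed radii from every accepted
  # centre, within bounded retries
  all_ctr <- matrix(numeric(), 0, 2)
  all_rad <- numeric()
  centers <- lapply(spec$niche_specs, function(ns) {
    out <- matrix(NA_real_, ns$n_centers, 2,
                  dimnames = list(NULL, c("row", "col")))
    for (j in seq_len(ns$n_centers)) {
      for (try_ in 1:60) {
        p <- c(runif(1, 2 * r + ns$radius, H - 1 - 2 * r - ns$radius),
               runif(1, 2 * r + ns$radius, W - 1 - 2 * r - ns$radius))
        if (nrow(all_ctr) == 0L) break
        d <- sqrt((all_ctr[, 1] - p[1])^2 + (all_ctr[, 2] - p[2])^2)
        if (all(d >= all_rad + ns$radius)) break
      }
      out[j, ] <- p
      all_ctr <<- rbind(all_ctr, p)
      all_rad <<- c(all_rad, ns$radius)
    }
    out
  })
  for (i in seq_along(spec$niche_specs)) {
    ns <- spec$niche_specs[[i]]
    member <- which(type_of %in% ns$members & niche_of == "none")
    take <- member[runif(length(member)) < nw[i]]
    if (!length(take)) next
    which_ctr <- sample.int(nrow(centers[[i]]), length(take), replace = TRUE)
    for (j in seq_along(take))
      niche_center[[take[j]]] <- c(centers[[i]][which_ctr[j], ],
                                   sd = spec$niche_specs[[i]]$radius / 2)
    niche_of[take] <- ns$name
  }

  # hard-core placement: cells have bodies, so centres keep a minimum
  # spacing (2r - 1 px) where possible; after bounded retries a position
  # is accepted anyway and the disc is truncated at rasterization
  spacing2 <- (2 * r - 1)^2
  pos <- matrix(NA_real_, n_cells, 2, dimnames = list(NULL, c("row", "col")))
  placed_r <- numeric(n_cells); placed_c <- numeric(n_cells); n_placed <- 0L
  for (i in sample.int(n_cells)) {
    nc_ <- niche_center[[i]]
    for (try_ in 1:40) {
      if (is.null(nc_)) {
        p <- c(runif(1, r, H - 1 - r), runif(1, r, W - 1 - r))
      } else {
        p <- nc_[1:2] + rnorm(2, 0, nc_[["sd"]])
        p <- pmin(pmax(p, r), c(H, W) - 1 - r)
      }
      if (n_placed == 0L) break
      d2 <- (placed_r[seq_len(n_placed)] - p[1])^2 +
            (placed_c[seq_len(n_placed)] - p[2])^2
      if (min(d2) >= spacing2) break
    }
    n_placed <- n_placed + 1L
    placed_r[n_placed] <- p[1]; placed_c[n_placed] <- p[2]
    pos[i, ] <- p
  }

  # pairwise attraction / repulsion by bounded displacement
  for (eff in spec$interaction_effects) {
    ia <- which(type_of == eff$a); ib <- which(type_of == eff$b)
    if (!length(ia) || !length(ib)) next
    for (it in seq_len(eff$iterations)) {
      dmat <- sqrt(outer(pos[ib, "row"], pos[ia, "row"], "-")^2 +
                   outer(pos[ib, "col"], pos[ia, "col"], "-")^2)
      nn <- ia[apply(dmat, 1, which.min)]
      d <- dmat[cbind(seq_along(ib), apply(dmat, 1, which.min))]
      vec <- pos[nn, , drop = FALSE] - pos[ib, , drop = FALSE]
      if (eff$strength > 0) {
        # move toward the nearest partner, stopping at contact distance
        gap <- pmax(d - 2 * r, 0)
        step <- ifelse(d > 0, eff$strength * gap / d, 0)
        pos[ib, ] <- pos[ib, , drop = FALSE] + vec * step
      } else {
        near <- d < eff$radius
        if (!any(near)) next
        push <- abs(eff$strength) * (eff$radius - d[near])
        step <- ifelse(d[near] > 0, push / d[near], 1)
        pos[ib[near], ] <- pos[ib[near], , drop = FALSE] -
          vec[near, , drop = FALSE] * step
      }
    }
    pos[, "row"] <- pmin(pmax(pos[, "row"], r), H - 1 - r)
    pos[, "col"] <- pmin(pmax(pos[, "col"], r), W - 1 - r)
  }

  # rasterize discs, truncating at collisions; seeded random order avoids
  # systematic truncation of late-placed types
  lab <- matrix(0L, H, W)
  offs <- disc_offsets(r)
  jit <- jitter_offsets()
  order_ <- sample.int(n_cells)
  pr <- round(pos[, "row"]); pc <- round(pos[, "col"])
  for (i in order_) {
    placed <- FALSE
    for (j in 0:nrow(jit)) {
      dr <- if (j == 0) 0L else jit$di[j]
      dc <- if (j == 0) 0L else jit$dj[j]
      rows <- pr[i] + dr + offs$di
      cols <- pc[i] + dc + offs$dj
      ok <- rows >= 0 & rows < H & cols >= 0 & cols < W
      if (!any(ok)) next
      idx <- rows[ok] + 1L + H * cols[ok]
      free <- idx[lab[idx] == 0L]
      if (length(free)) {
        lab[free] <- i
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("no free pixels for cell ", i, " in core '", core_id,
           "'; lower cell_density")
  }

  seg <- segmentation_map(core_id, lab)
  # ids in seg are the original cell indices; align truth to seg order
  ids <- as.integer(names(seg$cells))

  # functional positivity ground truth
  fm <- names(spec$functional_model) %||% character()
  posflags <- matrix(FALSE, n_cells, length(fm))
  if (length(fm)) colnames(posflags) <- paste0("pos_", fm)
  for (j in seq_along(fm)) {
    tgt <- spec$functional_model[[j]]
    sel <- which(type_of == tgt$type)
    posflags[sel, j] <- runif(length(sel)) < tgt$fraction
  }

  # render channels
  marker_type <- setNames(spec$rules$type[match(lineage_markers(spec$panel),
                                                spec$rules$marker)],
                          lineage_markers(spec$panel))
  sm <- spec$signal
  channels <- list()
  for (nm in spec$panel$markers$name) {
    mean_map <- matrix(sm$off_mean, H, W)
    if (nm %in% names(marker_type)) {
      on_ids <- ids[type_of[ids] == marker_type[[nm]]]
      if (length(on_ids)) mean_map[lab %in% on_ids] <- sm$on_mean
    } else if (nm %in% fm) {
      on_ids <- ids[posflags[ids, paste0("pos_", nm)]]
      if (length(on_ids)) mean_map[lab %in% on_ids] <- sm$on_mean
    } # excluded markers stay at the off-target level
    if (sm$sigma > 0)
      mean_map <- mean_map * exp(matrix(rnorm(H * W, 0, sm$sigma), H, W))
    channels[[nm]] <- mean_map
  }

  truth <- data.frame(
    cell_id = ids, core_id = core_id,
    row = seg$centroids$row, col = seg$centroids$col,
    lineage = type_of[ids], niche = niche_of[ids],
    stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(posflags[ids, , drop = FALSE]))
  rownames(truth) <- NULL

  list(stack = core_stack(core_id, channels), seg = seg, truth = truth,
       niche_weights = nw)
}

#' Realized per-core features of a synthetic core
#'
#' Computes the feature values the outcome model can reference: per-type
#' frequencies (`freq_<type>`), per-niche cell prevalence (`niche_<name>`),
#' realized niche weights (`nichewt_<name>`), and per-interaction mixing
#' scores (`mix_<a>_<b>`: fraction of `b` cells with an `a` cell centroid
#' within 10 px).
#'
#' @param core result of [generate_core()].
#' @param spec the [synthetic_spec()] that produced it.
#' @return named numeric vector.
#' @export
core_features <- function(core, spec) {
  truth <- core$truth
  types <- names(spec$type_proportions)
  f <- as.numeric(table(factor(truth$lineage, levels = types))) / nrow(truth)
  names(f) <- paste0("freq_", types)
  out <- f
  for (ns in spec$niche_specs) {
    out[paste0("niche_", ns$name)] <- mean(truth$niche == ns$name)
    if (!is.null(ns$weight_range))
      out[paste0("nichewt_", ns$name)] <- core$niche_weights[[ns$name]]
  }
  for (eff in spec$interaction_effects) {
    ia <- truth$lineage == eff$a; ib <- truth$lineage == eff$b
    key <- paste0("mix_", gsub(" ", "", eff$a), "_", gsub(" ", "", eff$b))
    if (!any(ia) || !any(ib)) { out[key] <- NA_real_; next }
    dmat <- sqrt(outer(truth$row[ib], truth$row[ia], "-")^2 +
                 outer(truth$col[ib], truth$col[ia], "-")^2)
    out[key] <- mean(apply(dmat, 1, min) <= 10)
  }
  out
}

#' Sample clinical outcomes from per-patient features
#'
#' Progression is Bernoulli with logit `intercept + sum(coefs * features)`;
#' survival time is exponential proportional hazards,
#' `T ~ Exp(exp(lp) / scale)`, with independent exponential censoring
#' calibrated so that roughly `censor_rate` of baseline subjects are
#' censored.
#'
#' @param features data.frame or matrix, one row per patient, named columns.
#' @param ospec an [outcome_spec()].
#' @param seed integer seed.
#' @return data.frame with `progression`, `survival_months`, `event` and
#'   the linear predictors (`lp_progression`, `lp_survival`).
#' @export
simulate_outcomes <- function(features, ospec, seed = 1L) {
  features <- as.data.frame(features)
  for (nms in list(names(ospec$logit_coefs), names(ospec$surv_coefs))) {
    bad <- setdiff(nms, names(features))
    if (length(bad))
      stop("outcome model references unplanted feature(s): ",
           paste(bad, collapse = ", "))
  }
  n <- nrow(features)
  lc <- ospec$logit_coefs; sc <- ospec$surv_coefs
  lp_prog <- rep(ospec$logit_intercept, n)
  if (length(lc))
    lp_prog <- lp_prog + as.matrix(features[names(lc)]) %*% lc
  lp_surv <- rep(0, n)
  if (length(sc))
    lp_surv <- lp_surv + as.matrix(features[names(sc)]) %*% sc
  with_seed(seed, {
    progression <- rbinom(n, 1L, stats::plogis(lp_prog)) == 1L
    t_event <- rexp(n, rate = exp(lp_surv) / ospec$baseline_scale_months)
    if (ospec$censor_rate > 0) {
      cr <- ospec$censor_rate
      t_cens <- rexp(n, rate = (cr / (1 - cr)) / ospec$baseline_scale_months)
      data.frame(progression = progression,
                 survival_months = pmin(t_event, t_cens),
                 event = t_event <= t_cens,
                 lp_progression = as.numeric(lp_prog),
                 lp_survival = as.numeric(lp_surv))
    } else {
      data.frame(progression = progression, survival_months = t_event,
                 event = TRUE, lp_progression = as.numeric(lp_prog),
                 lp_survival = as.numeric(lp_surv))
    }
  })
}

#' Generate a full synthetic cohort
#'
#' Generates every patient's core(s), computes the realized per-core
#' features, averages them per patient, and samples clinical covariates and
#' outcomes. The realized features used for outcome sampling are returned
#' as a ground-truth sidecar so planted effects can be audited.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `cores` (named list of [generate_core()] results),
#'   `clinical` (validated clinical table), `core_features` and
#'   `patient_features` (data.frames).
#' @export
generate_cohort <- function(spec) {
  pids <- sprintf("P%03d", seq_len(spec$n_patients))
  core_ids <- unlist(lapply(pids, function(p)
    sprintf("%s_c%d", p, seq_len(spec$cores_per_patient))))
  cores <- lapply(core_ids, function(cid) generate_core(spec, cid))
  names(cores) <- core_ids

  feats <- t(vapply(cores, core_features, core_features(cores[[1]], spec),
                    spec = spec))
  core_feat <- data.frame(core_id = core_ids,
                          patient_id = rep(pids, each = spec$cores_per_patient),
                          feats, check.names = FALSE)
  pat_feat <- aggregate(feats,
                        by = list(patient_id = core_feat$patient_id), mean)
  pat_feat <- pat_feat[match(pids, pat_feat$patient_id), , drop = FALSE]

  outcomes <- simulate_outcomes(pat_feat[, -1, drop = FALSE], spec$outcome,
                                seed = derive_seed(spec$seed, "outcomes"))
  cov <- with_seed(derive_seed(spec$seed, "covariates"), {
    data.frame(
      sex = sample(c("F", "M"), spec$n_patients, TRUE, prob = c(0.56, 0.44)),
      age = round(rnorm(spec$n_patients, 68, 9)),
      bmi = round(rnorm(spec$n_patients, 26.5, 4), 1),
      smoking = sample(c("smoker", "non-smoker"), spec$n_patients, TRUE,
                       prob = c(0.9, 0.1)),
      pack_years = round(pmax(rnorm(spec$n_patients, 35, 20), 0)),
      stage = sample(c("I-II", "III-IV"), spec$n_patients, TRUE,
                     prob = c(0.88, 0.12)),
      histology = sample(c("lepidic", "papillary", "acinar",
                           "micropapillary", "solid"),
                         spec$n_patients, TRUE,
                         prob = c(40, 33, 190, 35, 118) / 416))
  })
  clinical <- data.frame(
    patient_id = pids,
    core_ids = vapply(pids, function(p)
      paste(core_ids[startsWith(core_ids, paste0(p, "_"))], collapse = ";"),
      ""),
    cov,
    progression = outcomes$progression,
    survival_months = outcomes$survival_months,
    event = outcomes$event,
    row.names = NULL, stringsAsFactors = FALSE)
  list(cores = cores, clinical = validate_clinical_table(clinical),
       core_features = core_feat,
       patient_features = cbind(pat_feat,
                                outcomes[c("lp_progression", "lp_survival")]))
}
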