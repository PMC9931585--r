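#' Pipeline configuration
#'
#' Assembles a declarative configuration for [run_pipeline()]. All stage
#' tunables live here; nothing is hard-coded, mirroring how per-marker
#' mask curation and analysis parameters should be reproducible as data.
#' Configurations can also be loaded from YAML with [read_config()].
#'
#' @param stages character subset of `c("synth", "masks", "phenotype",
#'   "interactions", "neighborhoods", "survival", "predict")`.
#' @param synth a [synthetic_spec()] (required when stage `"synth"` runs).
#' @param out_dir output directory.
#' @param seed base seed for every stage.
#' @param write_images write the synthetic channel TIFFs (default FALSE).
#' @param write_masks write per-marker mask TIFFs (default: TRUE when the
#'   masks stage is requested).
#' @param interactions list: `d`, `rule`, `n_perm`, `alpha`.
#' @param neighborhoods list: `n`, `tCN`, `batch_size`.
#' @param predict list: `target` (clinical column), `sources` (subset of
#'   `c("raw", "freq", "clinical")`), `backbone`, `channels`, `k`,
#'   `n_components`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(stages, synth = NULL, out_dir = tempfile("imctme_"),
                            seed = 1L, write_images = FALSE,
                            write_masks = "masks" %in% stages,
                            interactions = list(),
                            neighborhoods = list(),
                            predict = list()) {
  known <- c("synth", "masks", "phenotype", "interactions",
             "neighborhoods", "survival", "predict")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  interactions <- modifyList(list(d = 6, rule = "boundary",
                                  n_perm = 1000L, alpha = 0.01),
                             interactions)
  neighborhoods <- modifyList(list(n = 10L, tCN = 10L, batch_size = 100L),
                              neighborhoods)
  predict <- modifyList(list(target = "progression",
                             sources = c("raw", "freq", "clinical"),
                             backbone = "testhash", channels = NULL,
                             k = 5L, n_components = 9L),
                        predict)
  structure(list(stages = stages, synth = synth, out_dir = out_dir,
                 seed = as.integer(seed), write_images = write_images,
                 write_masks = write_masks, interactions = interactions,
                 neighborhoods = neighborhoods, predict = predict),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]'s arguments; the `synth` block is
#' passed to [synthetic_spec()] (niches as lists of [niche_spec()]
#' arguments, interactions as [interaction_effect()] arguments).
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synth)) {
    s <- y$synth
    args <- s[setdiff(names(s), c("niches", "interactions", "signal",
                                  "outcome"))]
    if (!is.null(s$niches))
      args$niche_specs <- lapply(s$niches, function(a) do.call(niche_spec, a))
    if (!is.null(s$interactions))
      args$interaction_effects <- lapply(s$interactions, function(a)
        do.call(interaction_effect, a))
    if (!is.null(s$signal)) args$signal <- do.call(signal_model, s$signal)
    if (!is.null(s$outcome)) {
      o <- s$outcome
      for (f in c("logit_coefs", "surv_coefs"))
        if (!is.null(o[[f]])) o[[f]] <- unlist(o[[f]])
      args$outcome <- do.call(outcome_spec, o)
    }
    if (!is.null(args$image_size)) args$image_size <- as.integer(args$image_size)
    y$synth <- do.call(synthetic_spec, args)
  }
  do.call(pipeline_config, y)
}

.stage_deps <- list(
  synth = character(), masks = "synth", phenotype = c("synth", "masks"),
  interactions = c("synth", "phenotype"),
  neighborhoods = c("synth", "phenotype"),
  survival = c("synth", "phenotype", "neighborhoods"),
  predict = c("synth", "phenotype"))

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order (cohort generation,
#' marker masks, phenotyping, then interactions, neighbourhoods with
#' survival read-out, and outcome prediction), writing every stage's
#' outputs under `config$out_dir` together with a machine-readable run log
#' recording all seeds and parameters. Dependencies are checked before
#' any work starts. Identical configurations and seeds produce
#' byte-identical tables, labels and reports.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (st in config$stages) {
    miss <- setdiff(.stage_deps[[st]], config$stages)
    if (length(miss))
      stop("stage '", st, "' requires stage(s): ",
           paste(miss, collapse = ", "))
  }
  if ("synth" %in% config$stages && is.null(config$synth))
    stop("stage 'synth' requires a synthetic_spec in config$synth")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  spec <- config$synth
  if (!is.null(spec)) spec$seed <- config$seed

  if ("synth" %in% config$stages) {
    res$cohort <- generate_cohort(spec)
    write_clinical_table(res$cohort$clinical, file.path(out, "clinical.csv"))
    data.table::fwrite(res$cohort$core_features,
                       file.path(out, "core_features.csv"), scipen = 50L)
    if (config$write_images) {
      for (cid in names(res$cohort$cores)) {
        write_core_stack(res$cohort$cores[[cid]]$stack,
                         file.path(out, "images", cid))
        write_labels(res$cohort$cores[[cid]]$seg$label_raster,
                     file.path(out, "images", cid, "labels.tif"))
      }
    }
  }

  if ("masks" %in% config$stages) {
    res$masks <- lapply(res$cohort$cores, function(core)
      build_panel_masks(core$stack, spec$panel,
                        seed = derive_seed(config$seed, "masks")))
    if (config$write_masks) {
      for (cid in names(res$masks))
        for (nm in names(res$masks[[cid]]))
          write_mask(res$masks[[cid]][[nm]],
                     file.path(out, "masks", cid, paste0(nm, ".tif")))
    }
  }

  if ("phenotype" %in% config$stages) {
    tabs <- lapply(names(res$cohort$cores), function(cid) {
      core <- res$cohort$cores[[cid]]
      phenotype_core(core$stack, core$seg, spec$panel, res$masks[[cid]],
                     rules = spec$rules)
    })
    res$cells <- do.call(rbind, tabs)
    write_cell_table(res$cells, file.path(out, "cells.csv"))
    types <- sort(unique(spec$rules$type))
    freq <- compute_frequencies(res$cells, types = types,
                                immune_types = immune_types(types))
    res$frequencies <- freq
    write_matrix_csv(freq$total, file.path(out, "frequencies_total.csv"))
    if (!is.null(freq$immune))
      write_matrix_csv(freq$immune, file.path(out, "frequencies_immune.csv"))
  }

  if ("interactions" %in% config$stages) {
    ip <- config$interactions
    rows <- lapply(names(res$cohort$cores), function(cid) {
      core <- res$cohort$cores[[cid]]
      sub <- res$cells[res$cells$core_id == cid, ]
      graph <- build_adjacency(core$seg, d = ip$d, rule = ip$rule)
      interaction_test(graph, setNames(sub$lineage, sub$cell_id),
                       type_levels = sort(unique(spec$rules$type)),
                       n_perm = ip$n_perm, alpha = ip$alpha,
                       seed = derive_seed(config$seed, paste0("int_", cid)))
    })
    res$interactions <- do.call(rbind, rows)
    data.table::fwrite(res$interactions, file.path(out, "interactions.csv"),
                       scipen = 50L)
    bycore <- clinical_by_core(res$cohort$clinical)
    groups <- setNames(bycore$histology, bycore$core_id)
    res$interaction_heatmaps <- group_heatmap(res$interactions, groups)
    for (g in names(res$interaction_heatmaps))
      write_matrix_csv(res$interaction_heatmaps[[g]],
                       file.path(out, paste0("interactions_", g, ".csv")))
  }

  if ("neighborhoods" %in% config$stages) {
    np <- config$neighborhoods
    wv <- window_vectors(res$cells, n = np$n,
                         type_levels = sort(unique(spec$rules$type)))
    res$cn_model <- cluster_windows(wv, tCN = np$tCN,
                                    batch_size = np$batch_size,
                                    seed = derive_seed(config$seed, "cn"))
    labs <- data.frame(res$cn_model$cells[c("cell_id", "core_id")],
                       cn = res$cn_model$labels)
    data.table::fwrite(labs, file.path(out, "cn_labels.csv"), scipen = 50L)
    res$cn_prevalence <- cn_prevalence(res$cn_model)
    write_matrix_csv(res$cn_prevalence$percent,
                     file.path(out, "cn_prevalence.csv"))
    res$cn_characterization <- characterize_cns(res$cn_model, wv)
    write_matrix_csv(res$cn_characterization$composition,
                     file.path(out, "cn_composition.csv"))
  }

  if ("survival" %in% config$stages) {
    bycore <- clinical_by_core(res$cohort$clinical)
    pat <- patient_prevalence(res$cn_prevalence$fraction, bycore)
    scan_cn <- survival_scan(pat$values, pat$clinical$survival_months,
                             pat$clinical$event)
    patf <- patient_prevalence(res$frequencies$total, bycore)
    scan_fr <- survival_scan(patf$values, patf$clinical$survival_months,
                             patf$clinical$event)
    scan_cn$variable_kind <- "cn_prevalence"
    scan_fr$variable_kind <- "cell_frequency"
    res$survival <- rbind(scan_cn, scan_fr)
    data.table::fwrite(res$survival, file.path(out, "survival_scan.csv"),
                       scipen = 50L)
  }

  if ("predict" %in% config$stages) {
    pp <- config$predict
    bycore <- clinical_by_core(res$cohort$clinical)
    stacks <- lapply(res$cohort$cores, `[[`, "stack")
    ord <- match(names(stacks), bycore$core_id)
    labels <- as.character(bycore[[pp$target]][ord])
    groups <- bycore$patient_id[ord]
    reports <- list()
    if ("raw" %in% pp$sources) {
      channels <- pp$channels %||% lineage_markers(spec$panel)
      emb <- embed_cohort(stacks, pp$backbone, channels)
      reports$raw <- train_eval(emb, labels, groups = groups, k = pp$k,
                                n_components = pp$n_components,
                                seed = derive_seed(config$seed, "pred_raw"),
                                source = "raw_channels")
    }
    if ("freq" %in% pp$sources) {
      fr <- res$frequencies$total[names(stacks), , drop = FALSE]
      reports$freq <- train_eval(fr, labels, groups = groups, k = pp$k,
                                 n_components = min(pp$n_components,
                                                    ncol(fr)),
                                 seed = derive_seed(config$seed, "pred_freq"),
                                 source = "cell_frequencies")
    }
    if ("clinical" %in% pp$sources) {
      cf <- features_from_clinical(res$cohort$clinical)
      cf <- cf[, colnames(cf) != pp$target, drop = FALSE]
      reports$clinical <- train_eval(
        cf[names(stacks), , drop = FALSE], labels, groups = groups,
        k = pp$k, n_components = min(pp$n_components, ncol(cf) - 1L),
        seed = derive_seed(config$seed, "pred_clin"),
        source = "clinical_vector")
    }
    res$prediction <- reports
    slim <- lapply(reports, function(r)
      r[c("source", "fold_accuracy", "fold_valid", "mean_accuracy",
          "sd_accuracy", "precision", "recall", "baseline", "n_components",
          "k", "seed", "two_core_agreement")])
    jsonlite::write_json(slim, file.path(out, "prediction.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  log <- list(
    package_version = as.character(utils::packageVersion("imctme")),
    seed = config$seed, stages = config$stages,
    interactions = config$interactions,
    neighborhoods = config$neighborhoods,
    predict = config$predict[c("target", "sources", "backbone", "k",
                               "n_components")],
    synth = if (!is.null(spec))
      list(n_patients = spec$n_patients,
           cores_per_patient = spec$cores_per_patient,
           image_size = spec$image_size, cell_density = spec$cell_density,
           seed = spec$seed))
  jsonlite::write_json(log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
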