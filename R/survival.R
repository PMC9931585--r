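#' z-score stratification of a per-patient quantity
#'
#' Standardizes a quantity over the analysis cohort and splits patients at
#' z = 0: `high` for z >= 0, `low` for z < 0. This is the stratification
#' used throughout for survival comparison of cell frequencies and
#' neighbourhood prevalences.
#'
#' @param values numeric vector (one per patient).
#' @param ids optional patient identifiers.
#' @return data.frame with `patient_id`, `value`, `z`, `stratum`.
#' @export
zscore_stratify <- function(values, ids = names(values) %||%
                              seq_along(values)) {
  if (length(values) < 2L) stop("need at least two patients")
  z <- zscore(values)
  data.frame(patient_id = ids, value = as.numeric(values), z = z,
             stratum = ifelse(z >= 0, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier estimate of a survival curve
#'
#' Product-limit estimator; censored subjects leave the risk set after
#' their censoring time. The estimate is non-increasing and right
#' continuous with S(0) = 1.
#'
#' @param times nonnegative follow-up times.
#' @param events logical/0-1 event indicators (TRUE = death observed).
#' @return data.frame with `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
kaplan_meier <- function(times, events) {
  if (length(times) == 0L) stop("empty input")
  stopifnot(all(times >= 0), length(times) == length(events))
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Log-rank (Mantel-Cox) test between two groups
#'
#' Standard two-group log-rank chi-square on one degree of freedom, with
#' tied event times handled by the usual discrete hypergeometric formula;
#' the two-sided p-value comes from the chi-square distribution.
#'
#' @param times nonnegative follow-up times.
#' @param events event indicators.
#' @param group two-level grouping (factor, character or logical).
#' @return list with `chisq`, `p_value`, `observed`, `expected`, `var`
#'   (per-group observed/expected event counts and the variance of O-E)
#'   and `groups`.
#' @export
logrank <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop("log-rank comparison needs exactly two non-empty groups")
  if (sum(events) < 1) stop("need at least one event")
  sd_ <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ group)
  p <- pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  list(chisq = unname(sd_$chisq), p_value = unname(p),
       observed = unname(sd_$obs), expected = unname(sd_$exp),
       var = unname(if (is.matrix(sd_$var)) sd_$var[1, 1] else sd_$var),
       groups = levels(droplevels(group)))
}

#' Survival association scan over per-patient variables
#'
#' For each column of `values`, z-score stratifies patients into high
#' (z >= 0) and low (z < 0) groups and compares their overall survival by
#' log-rank test. Raw p-values are reported by default, with an optional
#' Benjamini-Hochberg adjustment column.
#'
#' @param values matrix/data.frame of per-patient quantities (rows =
#'   patients, in the order of `times`).
#' @param times,events survival outcome per patient.
#' @param adjust add a BH-adjusted p-value column (default FALSE).
#' @return data.frame with `variable`, `n_high`, `n_low`, `chisq`,
#'   `p_value`, `direction` (sign of the high-group effect: `"protective"`
#'   when the high group has fewer events than expected) and optionally
#'   `p_adjusted`.
#' @export
survival_scan <- function(values, times, events, adjust = FALSE) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(times))
  rows <- lapply(colnames(values) %||% seq_len(ncol(values)), function(v) {
    x <- values[, v]
    ok <- is.finite(x)
    if (sum(ok) < 2L || sd(x[ok]) == 0)
      return(data.frame(variable = as.character(v), n_high = NA_integer_,
                        n_low = NA_integer_, chisq = NA_real_,
                        p_value = NA_real_, direction = NA_character_))
    st <- zscore_stratify(x[ok])
    if (length(unique(st$stratum)) < 2L || sum(events[ok]) < 1)
      return(data.frame(variable = as.character(v), n_high = NA_integer_,
                        n_low = NA_integer_, chisq = NA_real_,
                        p_value = NA_real_, direction = NA_character_))
    lr <- logrank(times[ok], events[ok], st$stratum)
    hi <- match("high", lr$groups)
    data.frame(variable = as.character(v),
               n_high = sum(st$stratum == "high"),
               n_low = sum(st$stratum == "low"),
               chisq = lr$chisq, p_value = lr$p_value,
               direction = if (lr$observed[hi] < lr$expected[hi])
                 "protective" else "adverse",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}
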