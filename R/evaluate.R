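#' Evaluate risk groups against survival
#'
#' Full survival work-up of a continuous risk score and its dichotomy:
#' per-group Kaplan-Meier curves with median survival ("not reached"
#' flagged as `NA`), the log-rank test between groups, the Cox hazard
#' ratio of the binary group covariate reported in both orientations
#' (high vs low and low vs high, each with a 95% Wald interval), and the
#' time-dependent ROC AUC of the continuous score at each requested
#' horizon.
#'
#' @param scores continuous risk scores, one per sample.
#' @inheritParams km_curve
#' @param cutoff risk-score cutoff defining the groups
#'   (`score > cutoff` = high risk).
#' @param horizons AUC horizons in months, default `c(12, 36, 60)`.
#' @param span NNE window parameter for [td_roc()]; `NULL` for default.
#' @return list of class `"group_eval"`: `group`, `n`, `km` (per-group
#'   [km_curve()]), `median_time`, `logrank`, `cox_high_vs_low`,
#'   `cox_low_vs_high` (rows of HR/CI/p), `auc` data.frame.
#' @export
evaluate_groups <- function(scores, time, event, cutoff,
                            horizons = c(12, 36, 60), span = NULL) {
  check_surv(time, event, need_event = TRUE)
  if (length(scores) != length(time)) stop_("one score per sample")
  if (any(horizons <= 0) || is.unsorted(horizons, strictly = TRUE))
    stop_("'horizons' must be positive and increasing")
  group <- stratify(scores, cutoff)
  if (nlevels(droplevels(group)) < 2L)
    stop_("cutoff yields a single risk group; cannot evaluate")
  km <- lapply(split(seq_along(group), group), function(i)
    km_curve(time[i], event[i]))
  lr <- logrank_test(time, event, group)
  cx <- cox_fit(data.frame(high = as.integer(group == "high")),
                time, event)
  b <- cx$coefficients$beta; se <- cx$coefficients$se
  z <- stats::qnorm(0.975)
  orient <- function(beta) data.frame(
    hr = exp(beta), ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se), p_value = cx$coefficients$p_value)
  auc <- vapply(horizons, function(h)
    td_roc(scores, time, event, h, span)$auc, 0)
  structure(list(
    group = group,
    n = table(group),
    km = km,
    median_time = vapply(km, function(k) k$median_time, 0),
    logrank = lr,
    cox_high_vs_low = orient(b),
    cox_low_vs_high = orient(-b),
    auc = data.frame(horizon = horizons, auc = auc)),
    class = "group_eval")
}

#' @export
print.group_eval <- function(x, ...) {
  med <- ifelse(is.na(x$median_time), "not reached",
                format(x$median_time, digits = 4))
  cat("risk-group evaluation\n")
  cat(sprintf("  groups: low n = %d, high n = %d\n",
              x$n[["low"]], x$n[["high"]]))
  cat(sprintf("  median survival: low %s, high %s\n", med[1L], med[2L]))
  cat(sprintf("  log-rank: chi2 = %.3f, p = %.4g\n",
              x$logrank$chi2, x$logrank$p_value))
  cat(sprintf("  HR high vs low: %.3f (95%% CI %.3f-%.3f, p = %.4g)\n",
              x$cox_high_vs_low$hr, x$cox_high_vs_low$ci_low,
              x$cox_high_vs_low$ci_high, x$cox_high_vs_low$p_value))
  cat(sprintf("  HR low vs high: %.3f (95%% CI %.3f-%.3f)\n",
              x$cox_low_vs_high$hr, x$cox_low_vs_high$ci_low,
              x$cox_low_vs_high$ci_high))
  for (i in seq_len(nrow(x$auc)))
    cat(sprintf("  AUC at %g months: %.3f\n",
                x$auc$horizon[i], x$auc$auc[i]))
  invisible(x)
}

#' Subgroup analysis of a risk score
#'
#' Re-runs [evaluate_groups()] within each level of each clinical factor
#' (sex, age and stage dichotomies, MYCN status, ...). Samples missing a
#' factor's value are excluded from that factor only; levels with fewer
#' than `min_n` samples, no events, or a single risk group are skipped
#' with a warning.
#'
#' @inheritParams evaluate_groups
#' @param clinical `data.frame` (e.g. a `clinical_table`) holding the
#'   factor columns.
#' @param factors column names to stratify on.
#' @param min_n minimum subgroup size, default 10.
#' @return `data.frame` with one row per evaluable (factor, level):
#'   `factor`, `level`, `n`, `n_events`, `hr_high_vs_low`, `ci_low`,
#'   `ci_high`, `logrank_p`. Full evaluations are attached as attribute
#'   `"evaluations"`.
#' @export
subgroup_analysis <- function(scores, time, event, cutoff, clinical,
                              factors = c("sex", "age_ge_18m",
                                          "mycn_amplified", "stage4"),
                              min_n = 10, horizons = c(12, 36, 60)) {
  if (nrow(clinical) != length(scores))
    stop_("one clinical row per sample")
  rows <- list(); evals <- list()
  for (f in factors) {
    if (!f %in% colnames(clinical)) {
      warn_("factor '", f, "' not in clinical table; skipped")
      next
    }
    v <- clinical[[f]]
    lev <- unique(v[!is.na(v)])
    if (length(lev) < 2L) {
      warn_("factor '", f, "' has a single level; skipped")
      next
    }
    for (l in lev) {
      idx <- which(!is.na(v) & v == l)
      tag <- paste0(f, "=", l)
      if (length(idx) < min_n || sum(event[idx]) < 1) {
        warn_("subgroup ", tag, " too small or event-free; skipped")
        next
      }
      ev <- tryCatch(
        evaluate_groups(scores[idx], time[idx], event[idx], cutoff,
                        horizons = horizons),
        error = function(e) {
          warn_("subgroup ", tag, " skipped: ", conditionMessage(e))
          NULL
        })
      if (is.null(ev)) next
      evals[[tag]] <- ev
      rows[[tag]] <- data.frame(
        factor = f, level = as.character(l), n = length(idx),
        n_events = sum(event[idx]),
        hr_high_vs_low = ev$cox_high_vs_low$hr,
        ci_low = ev$cox_high_vs_low$ci_low,
        ci_high = ev$cox_high_vs_low$ci_high,
        logrank_p = ev$logrank$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else data.frame(factor = character(), level = character(),
                         n = integer(), n_events = integer(),
                         hr_high_vs_low = numeric(), ci_low = numeric(),
                         ci_high = numeric(), logrank_p = numeric())
  attr(out, "evaluations") <- evals
  out
}
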