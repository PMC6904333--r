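#' Kaplan-Meier product-limit curve
#'
#' Thin wrapper around [survival::survfit()] returning the curve at the
#' event times: survival probabilities, numbers at risk and the median
#' survival time (`NA` when the curve never drops to 0.5, i.e. the
#' median is not reached). Events precede censorings at tied times, the
#' standard product-limit convention.
#'
#' @param time non-negative follow-up times (months).
#' @param event 0/1 event indicator (1 = event observed).
#' @return list of class `"km_curve"` with `event_times`, `survival`,
#'   `n_at_risk`, `n_events`, `median_time`, `n`, and the underlying
#'   `survfit` object in `$fit`.
#' @export
km_curve <- function(time, event) {
  check_surv(time, event, need_event = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  is_ev <- fit$n.event > 0
  med <- unname(stats::quantile(fit, probs = 0.5)$quantile)
  structure(list(
    event_times = fit$time[is_ev],
    survival = fit$surv[is_ev],
    n_at_risk = fit$n.risk[is_ev],
    n_events = fit$n.event[is_ev],
    median_time = med,
    n = fit$n, fit = fit), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d events, median %s\n",
              x$n, sum(x$n_events),
              if (is.na(x$median_time)) "not reached"
              else format(x$median_time)))
  invisible(x)
}

#' Log-rank test
#'
#' Standard observed-minus-expected log-rank statistic with
#' hypergeometric variance across k groups (df = k - 1), via
#' [survival::survdiff()].
#'
#' @inheritParams km_curve
#' @param group group label per sample (2 or more non-empty groups).
#' @return list of class `"logrank_test"`: `chi2`, `df`, `p_value`, `n`.
#' @export
logrank_test <- function(time, event, group) {
  check_surv(time, event, need_event = TRUE)
  g <- factor(group)
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop_("log-rank test needs at least 2 groups")
  if (length(g) != length(time)) stop_("one group label per sample")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  df <- length(sd$n) - 1L
  structure(list(chi2 = unname(sd$chisq), df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 n = sum(sd$n)), class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("log-rank test: chi2 = %.4g on %d df, p = %.4g (n = %d)\n",
              x$chi2, x$df, x$p_value, x$n))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Fits a Cox model by Newton-Raphson maximization of the Breslow-ties
#' partial likelihood (via [survival::coxph()] with `ties = "breslow"`),
#' and reports per-covariate hazard ratios with 95% Wald intervals.
#' Breslow ties are used throughout the package for consistency with the
#' penalized fits of [penalized_cox()].
#'
#' @param x covariate matrix or data.frame (no constant column).
#' @inheritParams km_curve
#' @return list of class `"cox_fit"`: `coefficients` data.frame with
#'   `term`, `beta`, `hr`, `se`, `ci_low`, `ci_high`, `p_value`;
#'   `log_partial_likelihood` at the optimum; `n`, `n_events`; the
#'   `coxph` object in `$fit`.
#' @export
cox_fit <- function(x, time, event) {
  check_surv(time, event, need_event = TRUE)
  x <- as.data.frame(x)
  if (!nrow(x) || !ncol(x)) stop_("empty covariate matrix")
  if (nrow(x) != length(time)) stop_("one covariate row per sample")
  const <- vapply(x, function(v) length(unique(v[!is.na(v)])) < 2L, TRUE)
  if (any(const))
    stop_("constant covariate(s): ",
          paste(names(x)[const], collapse = ", "))
  if (sum(event) < ncol(x))
    stop_("fewer events than covariates")
  dat <- cbind(.time = time, .event = event, x)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                    ties = "breslow",
                    control = survival::coxph.control(iter.max = 100)),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("infinite|did not converge|out of iterations", msg,
                ignore.case = TRUE))
        stop_("Cox fit failed (", trimws(msg),
              "); consider a penalized fit")
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  beta <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(stats::vcov(fit))))
  if (any(!is.finite(beta)) || any(abs(beta) > 15))
    stop_("Cox fit unstable (monotone likelihood); ",
          "consider a penalized fit")
  z <- stats::qnorm(0.975)
  structure(list(
    coefficients = data.frame(
      term = names(stats::coef(fit)), beta = beta, hr = exp(beta),
      se = se, ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
      p_value = unname(s$coefficients[, "Pr(>|z|)"]),
      stringsAsFactors = FALSE),
    log_partial_likelihood = fit$loglik[2L],
    n = fit$n, n_events = fit$nevent, fit = fit),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Cox model (Breslow ties): n = %d, %d events, loglik %.4f\n",
              x$n, x$n_events, x$log_partial_likelihood))
  print(format(x$coefficients, digits = digits), ...)
  invisible(x)
}

#' Familywise error-rate adjustment
#'
#' Adjusts a vector of p-values for multiple testing under familywise
#' error-rate control. Holm's step-down procedure is the default (it is
#' uniformly more powerful than Bonferroni while controlling the FWER at
#' the same level); plain Bonferroni is available.
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @param method `"holm"` (default) or `"bonferroni"`.
#' @return adjusted p-values, each at least as large as its input.
#' @export
adjust_fwer <- function(p_values, method = c("holm", "bonferroni")) {
  method <- match.arg(method)
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1))
    stop_("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = method)
}

check_surv <- function(time, event, need_event = TRUE) {
  if (!length(time)) stop_("empty survival data")
  if (length(time) != length(event))
    stop_("time and event must have equal length")
  if (anyNA(time) || anyNA(event))
    stop_("missing values in survival data; exclude them first")
  if (!is.numeric(time) || any(time < 0))
    stop_("survival times must be non-negative")
  if (!all(event %in% c(0, 1)))
    stop_("event indicator must be 0/1")
  if (need_event && sum(event) < 1)
    stop_("at least one event required")
  invisible(TRUE)
}
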