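#' Time-dependent ROC curve for censored data (nearest-neighbor estimator)
#'
#' Cumulative-case/dynamic-control ROC at a fixed horizon `t` for a
#' continuous risk marker under right censoring, using the
#' nearest-neighbor (NNE) estimator of the joint distribution of marker
#' and survival: for each subject, conditional survival
#' `S(t | marker)` is estimated by a product-limit calculation over the
#' symmetric nearest-neighbor window containing the fraction `2 * span`
#' of the sample on the marker-percentile scale. Sensitivity and
#' specificity at each marker threshold follow from the smoothed joint
#' distribution, and the AUC is the trapezoidal integral of the
#' (cumulative-maximum monotonized) curve. Only marker ranks enter the
#' estimator, so the AUC is exactly invariant under strictly increasing
#' marker transforms.
#'
#' @param marker numeric risk score per sample (higher = higher risk).
#' @inheritParams km_curve
#' @param horizon_t evaluation horizon in months; must lie within the
#'   observed time range and have at least one prior event.
#' @param span half-width of the nearest-neighbor window as a sample
#'   fraction, in (0, 0.5); default `0.25 * n^(-0.2)`.
#' @return list of class `"td_roc"`: `horizon_t`, `thresholds`
#'   (decreasing, with infinite endpoints), `tpr`, `fpr`, `auc`, `span`.
#' @export
td_roc <- function(marker, time, event, horizon_t, span = NULL) {
  check_surv(time, event, need_event = TRUE)
  n <- length(marker)
  if (n != length(time)) stop_("one marker value per sample")
  if (!all(is.finite(marker))) stop_("marker values must be finite")
  if (is.null(span)) span <- 0.25 * n^(-0.2)
  if (span <= 0 || span >= 0.5) stop_("'span' must be in (0, 0.5)")
  if (horizon_t <= 0 || horizon_t > max(time))
    stop_("'horizon_t' must lie within the observed time range")
  if (!any(event == 1 & time <= horizon_t))
    stop_("no events at or before the horizon")

  # conditional survival at the horizon, smoothed over marker neighbors
  pct <- (rank(marker, ties.method = "average") - 0.5) / n
  s_cond <- vapply(seq_len(n), function(i) {
    nb <- abs(pct - pct[i]) <= span
    km_at(time[nb], event[nb], horizon_t)
  }, 0)
  s_marg <- mean(s_cond)

  thr <- c(Inf, sort(unique(marker), decreasing = TRUE), -Inf)
  tpr <- fpr <- numeric(length(thr))
  denom_case <- 1 - s_marg
  for (k in seq_along(thr)) {
    pos <- marker > thr[k]
    p_pos_surv <- sum(s_cond[pos]) / n            # P(X > c, T > t)
    p_pos <- mean(pos)
    tpr[k] <- if (denom_case > 0) (p_pos - p_pos_surv) / denom_case else 0
    fpr[k] <- if (s_marg > 0) p_pos_surv / s_marg else 0
  }
  tpr <- pmin(pmax(tpr, 0), 1); fpr <- pmin(pmax(fpr, 0), 1)
  tpr[1] <- 0; fpr[1] <- 0
  tpr[length(thr)] <- 1; fpr[length(thr)] <- 1
  # raw NNE curves can be locally non-monotone; enforce monotonicity
  tpr <- cummax(tpr); fpr <- cummax(fpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(horizon_t = horizon_t, thresholds = thr,
                 tpr = tpr, fpr = fpr, auc = auc, span = span, n = n),
            class = "td_roc")
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf("time-dependent ROC at t = %g months: AUC = %.4f (n = %d, span = %.3f)\n",
              x$horizon_t, x$auc, x$n, x$span))
  invisible(x)
}

# product-limit survival at t0 for a (sub)sample; events precede
# censorings at tied times
km_at <- function(tt, ee, t0) {
  et <- sort(unique(tt[ee == 1 & tt <= t0]))
  if (!length(et)) return(1)
  s <- 1
  for (u in et)
    s <- s * (1 - sum(tt == u & ee == 1) / sum(tt >= u))
  s
}

#' Optimal risk-score cutoff from the time-dependent ROC curve
#'
#' Chooses the marker threshold maximizing the Youden index
#' (sensitivity - (1 - specificity)) on the NNE ROC curve at the given
#' horizon. Ties are broken toward the smaller threshold (the larger
#' high-risk group). The returned cutoff is placed at the midpoint
#' between the winning threshold and the next larger observed marker
#' value, so it separates the two marker clusters strictly.
#'
#' @inheritParams td_roc
#' @param horizon_t cutoff-selection horizon in months, default 60.
#' @param criterion only `"youden"` is implemented.
#' @return a single numeric cutoff; samples with `score > cutoff` are
#'   high risk.
#' @export
optimal_cutoff <- function(marker, time, event, horizon_t = 60,
                           span = NULL, criterion = c("youden")) {
  criterion <- match.arg(criterion)
  roc <- td_roc(marker, time, event, horizon_t, span)
  inner <- seq_along(roc$thresholds)[is.finite(roc$thresholds)]
  youden <- roc$tpr[inner] - roc$fpr[inner]
  if (max(youden) < 1e-12)
    warn_("flat ROC curve: marker appears uninformative at this horizon")
  best <- inner[youden == max(youden)]
  cut_thr <- min(roc$thresholds[best])  # tie -> larger high-risk group
  larger <- roc$thresholds[is.finite(roc$thresholds) &
                             roc$thresholds > cut_thr]
  if (length(larger)) (cut_thr + min(larger)) / 2 else cut_thr
}
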