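#' Fit a gene-pair prognostic index (RPI)
#'
#' The package's central fitting function. Starting from candidate genes
#' it (1) builds the binary within-sample pair-indicator matrix,
#' (2) removes pairs constant in any supplied dataset, (3) screens the
#' remaining pairs by per-pair log-rank tests under familywise error
#' control, (4) fits an L1-penalized Cox model on the screened pairs
#' with 10-fold cross-validated penalty selection, (5) keeps the pairs
#' with nonzero coefficients as the signature (when the conservative
#' 1-SE rule keeps none, training falls back to the deviance-minimizing
#' penalty with a warning), and (6) fixes a
#' risk-score cutoff, either from the time-dependent ROC curve at the
#' chosen horizon (default; the cutoff then transfers unchanged to new
#' cohorts) or at the training-cohort median.
#'
#' An optional per-gene pre-filter (`prefilter_p`) restricts candidates
#' to genes whose expression is univariately associated with survival
#' (single-covariate Cox p-value below the threshold) before pairing;
#' it is off by default.
#'
#' @param expr an [expression_matrix()] (any abundance scale; only
#'   within-sample ranks are used).
#' @inheritParams km_curve
#' @param candidates candidate gene ids; default all genes in `expr`.
#' @param prefilter_p optional per-gene univariate Cox p threshold
#'   applied to the candidates before pairing (`NULL` = off).
#' @param fwer_alpha,fwer_method pair-screen parameters, see
#'   [screen_prognostic_pairs()].
#' @param filter_datasets optional list of additional expression
#'   matrices (e.g. the validation cohort) to include in the
#'   constant-pair filter; pair matrices for them are built on the same
#'   candidates.
#' @param n_lambdas,lambda_min_ratio,n_folds,rule,seed penalized-fit
#'   parameters, see [penalized_cox()].
#' @param cutoff_method `"roc"` (default) or `"median"`.
#' @param horizon cutoff-selection horizon in months (default 60).
#' @param span NNE window for the ROC cutoff; `NULL` for default.
#' @param endpoint endpoint label stored in the signature.
#' @return object of class `"rpi"`: `signature` (a [pair_signature()]),
#'   `scores` and `group` on the training samples, `screen` (selected
#'   pair table), `cv` (the [penalized_cox()] fit), `counts` (named
#'   integer log of the pipeline stages: genes in, pairs built, pairs
#'   after the constancy filter, pairs after the screen, pairs in the
#'   model), and `call`.
#' @seealso [predict.rpi()], [validate_rpi()], [evaluate_groups()]
#' @examples
#' sim <- generate_two_cohorts(sim_config(seed = 7))
#' fit <- rpi(sim$cohort1$expression, sim$cohort1$clinical$os_time,
#'            sim$cohort1$clinical$os_event, seed = 7)
#' fit
#' val <- validate_rpi(fit, sim$cohort2$expression,
#'                     sim$cohort2$clinical$os_time,
#'                     sim$cohort2$clinical$os_event)
#' val$logrank
#' @export
rpi <- function(expr, time, event, candidates = rownames(expr),
                prefilter_p = NULL, fwer_alpha = 0.05,
                fwer_method = c("holm", "bonferroni"),
                filter_datasets = NULL,
                n_lambdas = 100, lambda_min_ratio = 0.01, n_folds = 10,
                rule = c("lambda_1se", "lambda_min"), seed = 1L,
                cutoff_method = c("roc", "median"), horizon = 60,
                span = NULL, endpoint = "OS") {
  cl <- match.call()
  fwer_method <- match.arg(fwer_method)
  rule <- match.arg(rule)
  cutoff_method <- match.arg(cutoff_method)
  check_surv(time, event, need_event = TRUE)
  if (ncol(expr) != length(time))
    stop_("one expression column per subject")
  counts <- c(genes_in = length(unique(candidates)))

  if (!is.null(prefilter_p)) {
    keep <- vapply(unique(candidates), function(g) {
      p <- tryCatch(
        cox_fit(data.frame(g = unclass(expr)[g, ]), time,
                event)$coefficients$p_value,
        error = function(e) NA_real_)
      !is.na(p) && p < prefilter_p
    }, TRUE)
    candidates <- unique(candidates)[keep]
    counts["genes_after_prefilter"] <- length(candidates)
  }

  pm <- build_pair_matrix(expr, candidates)
  counts["pairs_built"] <- nrow(pm)

  pms <- list(pm)
  for (d in filter_datasets)
    pms <- c(pms, list(build_pair_matrix(d, candidates)))
  keep_ids <- filter_constant_pairs(pms)
  pm_f <- pm[keep_ids, , drop = FALSE]
  attr(pm_f, "pairs") <- attr(pm, "pairs")[match(keep_ids, rownames(pm)), ,
                                           drop = FALSE]
  class(pm_f) <- class(pm)
  counts["pairs_after_filter"] <- nrow(pm_f)
  if (nrow(pm_f) < 2L)
    stop_("stage 'constant filter': fewer than 2 variable pairs remain")

  screen <- screen_prognostic_pairs(pm_f, time, event,
                                    fwer_alpha = fwer_alpha,
                                    method = fwer_method)
  counts["pairs_after_screen"] <- nrow(screen)
  if (nrow(screen) < 2L)
    stop_("stage 'FWER screen': fewer than 2 pairs pass; ",
          "raise fwer_alpha or supply stronger candidates")

  pm_s <- pm_f[screen$pair_id, , drop = FALSE]
  attr(pm_s, "pairs") <- attr(pm_f, "pairs")[match(screen$pair_id,
                                                   rownames(pm_f)), ,
                                             drop = FALSE]
  class(pm_s) <- class(pm_f)
  cv <- penalized_cox(pm_s, time, event, n_lambdas = n_lambdas,
                      lambda_min_ratio = lambda_min_ratio,
                      n_folds = n_folds, rule = rule, seed = seed)
  sig <- tryCatch(
    extract_signature(cv, rule = rule, endpoint = endpoint,
                      label = "trained"),
    error = function(e) {
      if (rule == "lambda_1se" &&
          grepl("no feature survives", conditionMessage(e))) {
        # conservative 1-SE solutions can be empty at small n; fall
        # back to the deviance minimizer rather than abort training
        warn_("no pair survives the 1-SE penalty; ",
              "falling back to rule = 'lambda_min'")
        extract_signature(cv, rule = "lambda_min", endpoint = endpoint,
                          label = "trained")
      } else {
        stop(e)
      }
    })
  counts["pairs_in_model"] <- length(sig)

  scores <- score_rpi(expr, sig)
  cutoff <- if (cutoff_method == "roc") {
    optimal_cutoff(scores, time, event, horizon_t = horizon, span = span)
  } else {
    stats::median(scores)
  }
  sig$cutoff <- cutoff
  sig$cutoff_method <- cutoff_method

  structure(list(signature = sig, scores = scores,
                 group = stratify(scores, cutoff), screen = screen,
                 cv = cv, counts = counts, horizon = horizon,
                 time = time, event = event, call = cl),
            class = "rpi")
}

#' @export
print.rpi <- function(x, ...) {
  cat("gene-pair prognostic index (RPI)\n")
  cat(sprintf("  %d pairs, cutoff %.4g (%s, horizon %g months)\n",
              length(x$signature), x$signature$cutoff,
              x$signature$cutoff_method, x$horizon))
  cat(sprintf("  training: n = %d (%d events), %d high / %d low risk\n",
              length(x$scores), sum(x$event),
              sum(x$group == "high"), sum(x$group == "low")))
  cat("  stage counts: ",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.rpi <- function(object, horizons = c(12, 36, 60), ...) {
  ev <- evaluate_groups(object$scores, object$time, object$event,
                        object$signature$cutoff, horizons = horizons)
  out <- list(fit = object, training_evaluation = ev)
  class(out) <- "summary.rpi"
  out
}

#' @export
print.summary.rpi <- function(x, ...) {
  print(x$fit)
  cat("\nsignature:\n")
  print(x$fit$signature)
  cat("\ntraining-cohort evaluation:\n")
  print(x$training_evaluation)
  invisible(x)
}

#' @export
coef.rpi <- function(object, ...) coef(object$signature)

#' Score new samples with a fitted RPI
#'
#' Applies the fixed signature (and, for `type = "group"`, the fixed
#' numeric cutoff learned at training time) to new expression data. No
#' re-estimation happens here: the same cutoff that stratified the
#' training cohort is applied verbatim, which is what makes the index
#' transferable across platforms.
#'
#' @param object an [rpi()] fit.
#' @param newdata expression matrix (genes x samples) or single named
#'   profile; all signature genes must be present.
#' @param type `"score"` (continuous risk score), `"group"` (risk-group
#'   factor), or `"pairs"` (the 0/1 indicator matrix of the signature
#'   pairs).
#' @param ... unused.
#' @return per `type`: numeric vector, factor, or 0/1 matrix.
#' @export
predict.rpi <- function(object, newdata,
                        type = c("score", "group", "pairs"), ...) {
  type <- match.arg(type)
  if (type == "pairs") {
    sig <- object$signature
    if (is.null(dim(newdata))) {
      newdata <- as.matrix(newdata); colnames(newdata) <- "sample"
    }
    absent <- setdiff(unique(c(sig$pairs$gene1, sig$pairs$gene2)),
                      rownames(newdata))
    if (length(absent))
      stop_("gene(s) absent from input: ", paste(absent, collapse = ", "))
    e1 <- unclass(newdata)[sig$pairs$gene1, , drop = FALSE]
    e2 <- unclass(newdata)[sig$pairs$gene2, , drop = FALSE]
    ind <- (e1 < e2) + 0L
    rownames(ind) <- rownames(sig$pairs)
    return(ind)
  }
  scores <- score_rpi(newdata, object$signature)
  if (type == "score") scores
  else stratify(scores, object$signature$cutoff)
}

#' @export
plot.rpi <- function(x, ...) {
  sf <- survival::survfit(
    survival::Surv(x$time, x$event) ~ group,
    data = data.frame(group = x$group))
  graphics::plot(sf, col = c("forestgreen", "firebrick"), lwd = 2,
                 xlab = "months", ylab = "survival probability", ...)
  graphics::legend("bottomleft", legend = c("low risk", "high risk"),
                   col = c("forestgreen", "firebrick"), lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Validate a fitted RPI on a new cohort
#'
#' Scores the cohort with the fixed signature and fixed numeric cutoff
#' from the fit (no re-estimation) and runs the full risk-group
#' evaluation. This is the validation-cohort workflow: the cutoff
#' learned on the training cohort is applied verbatim.
#'
#' @param object an [rpi()] fit (or a bare [pair_signature()] with its
#'   cutoff set).
#' @param expr expression matrix of the validation cohort.
#' @inheritParams km_curve
#' @param horizons AUC horizons in months.
#' @return a [evaluate_groups()] result with the scores attached as
#'   attribute `"scores"`.
#' @export
validate_rpi <- function(object, expr, time, event,
                         horizons = c(12, 36, 60)) {
  sig <- if (inherits(object, "rpi")) object$signature else object
  if (!inherits(sig, "pair_signature")) stop_("not an rpi fit or signature")
  if (is.na(sig$cutoff)) stop_("signature has no cutoff set")
  scores <- score_rpi(expr, sig)
  ev <- evaluate_groups(scores, time, event, sig$cutoff,
                        horizons = horizons)
  attr(ev, "scores") <- scores
  ev
}
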