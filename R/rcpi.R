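#' Univariate screen of clinical variables
#'
#' For each requested variable: samples missing it are dropped (for that
#' variable only), a log-rank test across its levels gives the p-value
#' for categorical/binary variables (a single-covariate Cox Wald p for
#' continuous ones), and a single-covariate Cox fit supplies the hazard
#' ratio with 95% CI (for binary and continuous variables; multi-level
#' factors report only the log-rank p). All-missing or constant
#' variables are skipped with a warning.
#'
#' @param data `data.frame` holding the variables (e.g. a
#'   `clinical_table`, possibly augmented with the dichotomized RPI
#'   group as a 0/1 column).
#' @inheritParams km_curve
#' @param variables column names to screen.
#' @return `data.frame` with columns `variable`, `n`, `n_events`, `hr`,
#'   `ci_low`, `ci_high`, `p_value`.
#' @export
univariate_screen <- function(data, time, event, variables) {
  if (nrow(data) != length(time)) stop_("one data row per sample")
  rows <- list()
  for (v in variables) {
    if (!v %in% colnames(data)) {
      warn_("variable '", v, "' not found; skipped")
      next
    }
    x <- data[[v]]
    ok <- !is.na(x)
    if (!any(ok) || length(unique(x[ok])) < 2L) {
      warn_("variable '", v, "' constant or all missing; skipped")
      next
    }
    tt <- time[ok]; ee <- event[ok]; xx <- x[ok]
    categorical <- is.character(xx) || is.factor(xx) ||
      length(unique(xx)) == 2L
    hr <- ci_low <- ci_high <- NA_real_
    p <- NA_real_
    if (categorical) {
      p <- logrank_test(tt, ee, xx)$p_value
      if (length(unique(xx)) == 2L) {
        xn <- if (is.numeric(xx)) xx else as.integer(factor(xx)) - 1L
        cf <- tryCatch(cox_fit(data.frame(v = xn), tt, ee),
                       error = function(e) NULL)
        if (!is.null(cf)) {
          hr <- cf$coefficients$hr
          ci_low <- cf$coefficients$ci_low
          ci_high <- cf$coefficients$ci_high
        }
      }
    } else {
      cf <- cox_fit(data.frame(v = xx), tt, ee)
      hr <- cf$coefficients$hr
      ci_low <- cf$coefficients$ci_low
      ci_high <- cf$coefficients$ci_high
      p <- cf$coefficients$p_value
    }
    rows[[v]] <- data.frame(variable = v, n = sum(ok),
                            n_events = sum(ee), hr = hr,
                            ci_low = ci_low, ci_high = ci_high,
                            p_value = p, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(variable = character(), n = integer(),
                      n_events = integer(), hr = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p_value = numeric()))
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Multivariate Cox fit of selected variables
#'
#' Joint Cox proportional-hazards fit of the selected variables with
#' listwise deletion of samples missing any of them (the number dropped
#' is reported via a message).
#'
#' @inheritParams univariate_screen
#' @param variables column names to fit jointly.
#' @return a [cox_fit()] result.
#' @export
multivariate_fit <- function(data, time, event, variables) {
  missing <- setdiff(variables, colnames(data))
  if (length(missing))
    stop_("variable(s) not found: ", paste(missing, collapse = ", "))
  x <- data[, variables, drop = FALSE]
  ok <- stats::complete.cases(x)
  if (sum(!ok))
    message(sum(!ok), " sample(s) dropped (missing covariate values)")
  if (sum(ok) < 30 || sum(event[ok]) < 10)
    stop_("too few complete samples (need >= 30 with >= 10 events)")
  cox_fit(x[ok, , drop = FALSE], time[ok], event[ok])
}

#' Stepwise Cox variable selection
#'
#' Deterministic forward selection with backward pruning: at each step
#' the candidate with the smallest Wald p-value below `p_enter` joins
#' the model, after which any included term whose Wald p rises above
#' `p_remove` is pruned (worst first). Stops when no candidate can
#' enter. The default thresholds (0.15 to enter, 0.05 to stay) follow
#' the common convention of stepwise Cox selection routines.
#'
#' @inheritParams univariate_screen
#' @param candidates candidate column names.
#' @param p_enter Wald p required to enter, default 0.15.
#' @param p_remove Wald p above which an included term is pruned,
#'   default 0.05.
#' @return character vector of selected variables (possibly empty, with
#'   a warning).
#' @export
stepwise_select <- function(data, time, event, candidates,
                            p_enter = 0.15, p_remove = 0.05) {
  ok <- stats::complete.cases(data[, candidates, drop = FALSE])
  dat <- data[ok, , drop = FALSE]
  tt <- time[ok]; ee <- event[ok]
  current <- character()
  wald_p <- function(vars) {
    cf <- tryCatch(cox_fit(dat[, vars, drop = FALSE], tt, ee),
                   error = function(e) NULL)
    if (is.null(cf)) return(NULL)
    stats::setNames(cf$coefficients$p_value, cf$coefficients$term)
  }
  pruned <- character()  # once pruned, a term may not re-enter
  repeat {
    remaining <- setdiff(candidates, c(current, pruned))
    if (!length(remaining)) break
    entry_p <- vapply(remaining, function(v) {
      p <- wald_p(c(current, v))
      if (is.null(p)) NA_real_ else unname(p[v])
    }, 0)
    entry_p <- entry_p[!is.na(entry_p)]
    if (!length(entry_p) || min(entry_p) >= p_enter) break
    entered <- names(entry_p)[which.min(entry_p)]
    current <- c(current, entered)
    # backward pruning after each entry (the new term is protected)
    repeat {
      p <- wald_p(current)
      if (is.null(p) || length(current) == 1L) break
      removable <- setdiff(names(p)[p > p_remove], entered)
      if (!length(removable)) break
      worst <- removable[which.max(p[removable])]
      current <- setdiff(current, worst)
      pruned <- c(pruned, worst)
    }
  }
  if (!length(current)) warn_("no candidate passed the entry threshold")
  current
}

new_rcpi_model <- function(weights, label = "", fit = NULL) {
  structure(list(terms = names(weights), weights = weights,
                 cutoff_method = "median", label = label, fit = fit),
            class = "rcpi_model")
}

#' Build a clinically adjusted composite index (RCPI)
#'
#' Combines clinical covariates with the continuous gene-pair risk
#' score into a composite: the weights are the coefficients of the
#' joint Cox fit of the listed terms (the RPI enters as its continuous
#' score), and stratification uses the median of the composite in
#' whichever cohort it is applied to — the median is recomputed per
#' cohort at application time, unlike the fixed RPI cutoff.
#'
#' @param data `data.frame` of clinical covariates; a numeric column
#'   named `rpi` holds the continuous risk score (added automatically
#'   when `rpi_scores` is supplied).
#' @inheritParams km_curve
#' @param terms covariate names to combine (e.g. `c("stage4", "rpi")`);
#'   if `NULL`, chosen by [stepwise_select()] from `candidates`.
#' @param rpi_scores optional numeric RPI score per sample, stored into
#'   `data$rpi`.
#' @param candidates candidate set for stepwise selection when `terms`
#'   is `NULL`.
#' @param p_enter,p_remove stepwise thresholds, see [stepwise_select()].
#' @return object of class `"rcpi_model"` with `terms`, `weights`
#'   (full-precision Cox coefficients), `cutoff_method = "median"`, and
#'   the joint fit in `$fit`.
#' @seealso [score_rcpi()], [predict.rcpi_model()], [published_rcpi()]
#' @export
rcpi <- function(data, time, event, terms = NULL, rpi_scores = NULL,
                 candidates = c("sex", "age_ge_18m", "mycn_amplified",
                                "stage4", "rpi"),
                 p_enter = 0.15, p_remove = 0.05) {
  data <- as.data.frame(data)
  if (!is.null(rpi_scores)) {
    if (length(rpi_scores) != nrow(data))
      stop_("one rpi score per sample")
    data$rpi <- as.numeric(rpi_scores)
  }
  if (!is.null(data$sex) && !is.numeric(data$sex))
    data$sex <- as.integer(factor(data$sex,
                                  levels = c("female", "male"))) - 1L
  if (is.null(terms)) {
    candidates <- intersect(candidates, colnames(data))
    terms <- stepwise_select(data, time, event, candidates,
                             p_enter = p_enter, p_remove = p_remove)
    if (!length(terms)) stop_("stepwise selection kept no term")
  }
  ok <- stats::complete.cases(data[, terms, drop = FALSE])
  fit <- cox_fit(data[ok, terms, drop = FALSE], time[ok], event[ok])
  w <- stats::setNames(fit$coefficients$beta, fit$coefficients$term)
  new_rcpi_model(weights = w, label = "trained", fit = fit)
}

#' @export
print.rcpi_model <- function(x, ...) {
  cat(sprintf("clinically adjusted composite (RCPI) '%s'\n", x$label))
  cat("  score =",
      paste(sprintf("%.6g * %s", x$weights, x$terms), collapse = " + "),
      "\n")
  cat("  cutoff: cohort median, recomputed at application time\n")
  invisible(x)
}

#' @export
coef.rcpi_model <- function(object, ...) object$weights

#' Score samples with an RCPI model
#'
#' Plain dot product of the model weights with the term values. Every
#' term must be present and non-missing.
#'
#' @param values named numeric vector, or `data.frame`/matrix with one
#'   column per term and one row per sample.
#' @param model an `"rcpi_model"`.
#' @return numeric score(s).
#' @export
score_rcpi <- function(values, model) {
  if (!inherits(model, "rcpi_model")) stop_("not an rcpi_model")
  if (is.null(dim(values))) values <- t(as.matrix(values))
  values <- as.data.frame(values)
  absent <- setdiff(model$terms, colnames(values))
  if (length(absent))
    stop_("missing term value(s): ", paste(absent, collapse = ", "))
  m <- as.matrix(values[, model$terms, drop = FALSE])
  if (anyNA(m))
    stop_("missing term value(s): ",
          paste(model$terms[colSums(is.na(m)) > 0], collapse = ", "))
  drop(m %*% model$weights)
}

#' Apply an RCPI model to a cohort
#'
#' Computes composite scores and, for `type = "group"`, stratifies at
#' the median of the scores within this cohort (the RCPI's
#' cohort-specific cutoff rule).
#'
#' @param object an `"rcpi_model"`.
#' @param newdata `data.frame` with the model's terms as columns
#'   (supply the continuous RPI score as column `rpi`).
#' @param type `"score"` or `"group"`.
#' @param ... unused.
#' @return numeric scores, or a factor with the applied median cutoff
#'   in attribute `"cutoff"`.
#' @export
predict.rcpi_model <- function(object, newdata,
                               type = c("score", "group"), ...) {
  type <- match.arg(type)
  scores <- score_rcpi(newdata, object)
  if (type == "score") return(scores)
  cutoff <- stats::median(scores)
  out <- stratify(scores, cutoff)
  attr(out, "cutoff") <- cutoff
  out
}
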