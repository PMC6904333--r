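#' L1-penalized Cox regression with cross-validated penalty selection
#'
#' Fits the lasso path of a Cox model on the (binary pair-indicator or
#' real) feature matrix by cyclic coordinate descent on the penalized
#' Breslow partial likelihood (via [glmnet::glmnet()]), over a
#' log-spaced penalty grid from `lambda_max` (smallest penalty with an
#' all-zero solution) down to `lambda_max * lambda_min_ratio`, with warm
#' starts along the path. The penalty is then selected by k-fold
#' cross-validated partial-likelihood deviance, with folds assigned by a
#' seeded shuffle stratified on the event indicator so no fold is left
#' event-free. Two selection rules are supported: `lambda_min`
#' (deviance minimizer) and the default `lambda_1se` (largest penalty
#' within one standard error of the minimum — the sparser model).
#'
#' Binary pair indicators already share the \{0,1\} scale, so features
#' are deliberately not standardized before penalization.
#'
#' @param x features-by-samples or samples-by-features matrix; a
#'   `"pair_matrix"` (pairs in rows) is transposed automatically.
#'   At least 2 features and no constant column.
#' @inheritParams km_curve
#' @param n_lambdas length of the penalty grid (default 100).
#' @param lambda_min_ratio ratio of smallest to largest penalty
#'   (default 0.01).
#' @param n_folds number of cross-validation folds (default 10).
#' @param rule `"lambda_1se"` (default) or `"lambda_min"`.
#' @param seed integer seed driving the fold shuffle; with the seed
#'   fixed the whole fit is reproducible.
#' @param thresh coordinate-descent convergence threshold.
#' @return list of class `"penalized_cox"`: `lambda` (decreasing grid),
#'   `beta` (features x lambda coefficient path), `cv_deviance_mean`,
#'   `cv_deviance_se`, `lambda_min`, `lambda_1se`, `rule`,
#'   `selected` (feature names nonzero at the chosen rule), `foldid`,
#'   `pairs` (pair table when `x` was a pair matrix), and the underlying
#'   fits in `$glmnet_fit` / `$cv_fit`.
#' @export
penalized_cox <- function(x, time, event, n_lambdas = 100,
                          lambda_min_ratio = 0.01, n_folds = 10,
                          rule = c("lambda_1se", "lambda_min"),
                          seed = 1L, thresh = 1e-12) {
  rule <- match.arg(rule)
  pairs <- NULL
  if (inherits(x, "pair_matrix")) {
    pairs <- attr(x, "pairs")
    rownames(pairs) <- rownames(x)
    x <- t(unclass(x))
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  check_surv(time, event, need_event = TRUE)
  if (nrow(x) != length(time)) stop_("one feature row per sample")
  if (ncol(x) < 2L) stop_("need at least 2 features")
  if (sum(event) < 10L) stop_("need at least 10 events")
  if (n_folds < 2L) stop_("need at least 2 folds")
  if (n_folds > sum(event))
    stop_("more folds than events; reduce n_folds")
  const <- apply(x, 2L, function(v) min(v) == max(v))
  if (all(const)) stop_("all features are constant")
  if (any(const))
    stop_("constant feature(s): ",
          paste(colnames(x)[const], collapse = ", "))

  foldid <- with_seed(seed, make_foldid(event, n_folds))
  y <- survival::Surv(time, event)
  # explicit log-spaced grid from lambda_max down to its ratio; an
  # explicit grid also disables glmnet's early path truncation
  lambda_max <- lambda_max_cox(x, time, event)
  lambda <- exp(seq(log(lambda_max),
                    log(lambda_max * lambda_min_ratio),
                    length.out = n_lambdas))
  cv <- glmnet::cv.glmnet(x, y, family = "cox", alpha = 1,
                          lambda = lambda,
                          foldid = foldid, standardize = FALSE,
                          thresh = thresh, grouped = TRUE,
                          type.measure = "deviance")
  fit <- cv$glmnet.fit
  lam <- if (rule == "lambda_1se") cv$lambda.1se else cv$lambda.min
  beta <- as.matrix(fit$beta)
  b_sel <- as.vector(stats::coef(fit, s = lam, exact = FALSE))
  structure(list(
    lambda = fit$lambda, beta = beta,
    cv_deviance_mean = cv$cvm, cv_deviance_se = cv$cvsd,
    cv_lambda = cv$lambda,
    lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se,
    rule = rule, selected = colnames(x)[b_sel != 0],
    foldid = foldid, pairs = pairs, n = nrow(x), n_events = sum(event),
    glmnet_fit = fit, cv_fit = cv), class = "penalized_cox")
}

#' @export
print.penalized_cox <- function(x, ...) {
  cat(sprintf(paste0(
    "penalized Cox path: %d features, n = %d (%d events), %d lambdas\n",
    "  lambda_min = %.5g, lambda_1se = %.5g; rule %s keeps %d feature(s)\n"),
    nrow(x$beta), x$n, x$n_events, length(x$lambda),
    x$lambda_min, x$lambda_1se, x$rule, length(x$selected)))
  invisible(x)
}

# smallest penalty with an all-zero lasso solution: the max-norm of the
# null-model Breslow score divided by n (glmnet's objective scaling)
lambda_max_cox <- function(x, time, event) {
  n <- nrow(x)
  g <- numeric(ncol(x))
  for (i in which(event == 1)) {
    rs <- time >= time[i]
    g <- g + x[i, ] - colMeans(x[rs, , drop = FALSE])
  }
  max(abs(g)) / n
}

# stratified fold assignment: events and censored shuffled separately,
# folds filled cyclically; one reshuffle is attempted before giving up
make_foldid <- function(event, n_folds) {
  assign_once <- function() {
    foldid <- integer(length(event))
    for (grp in list(which(event == 1), which(event == 0))) {
      if (length(grp))
        foldid[sample(grp)] <- rep_len(seq_len(n_folds), length(grp))
    }
    foldid
  }
  foldid <- assign_once()
  if (any(tabulate(foldid[event == 1], n_folds) == 0L)) {
    foldid <- assign_once()
    if (any(tabulate(foldid[event == 1], n_folds) == 0L))
      stop_("a cross-validation fold has zero events")
  }
  foldid
}

#' Extract the sparse signature from a penalized fit
#'
#' Collects the features with nonzero coefficient at the penalty chosen
#' by `rule` into a [pair_signature()], copying coefficients at full
#' precision. The cutoff is left unset; it is filled in later by
#' [optimal_cutoff()] or a median rule.
#'
#' @param fit a [penalized_cox()] object fitted on a pair matrix.
#' @param rule penalty selection rule; defaults to the one used in `fit`.
#' @param endpoint,label metadata passed to [pair_signature()].
#' @return a [pair_signature()] with unset cutoff.
#' @export
extract_signature <- function(fit, rule = fit$rule,
                              endpoint = "OS", label = "trained") {
  if (!inherits(fit, "penalized_cox")) stop_("not a penalized_cox fit")
  rule <- match.arg(rule, c("lambda_1se", "lambda_min"))
  if (is.null(fit$pairs))
    stop_("fit was not trained on a pair matrix")
  lam <- if (rule == "lambda_1se") fit$lambda_1se else fit$lambda_min
  b <- as.vector(stats::coef(fit$glmnet_fit, s = lam, exact = FALSE))
  names(b) <- rownames(fit$glmnet_fit$beta)
  nz <- b[b != 0]
  if (!length(nz))
    stop_("no feature survives the '", rule,
          "' penalty; try rule = 'lambda_min'")
  pr <- fit$pairs[names(nz), , drop = FALSE]
  pair_signature(pr[, "gene1"], pr[, "gene2"], unname(nz),
                 cutoff = NA_real_, cutoff_method = "roc",
                 endpoint = endpoint, label = label)
}
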