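#' Screen gene pairs for prognostic association
#'
#' Tests every pair in the matrix by a log-rank test of the two groups
#' its indicator defines (pair value 0 vs 1), adjusts the p-values for
#' familywise error and returns the pairs whose adjusted p falls below
#' `fwer_alpha`, ordered by adjusted p (ascending). Pairs for which one
#' group is empty — which cannot occur after
#' [filter_constant_pairs()] — are skipped with a warning.
#'
#' @param pm a `"pair_matrix"` (see [build_pair_matrix()]), ideally
#'   already constancy-filtered.
#' @inheritParams km_curve
#' @param fwer_alpha familywise error level, default 0.05.
#' @param method FWER adjustment handed to [adjust_fwer()], or
#'   `"none"` to screen on raw p-values.
#' @return `data.frame` of selected pairs with columns `pair_id`,
#'   `gene1`, `gene2`, `chi2`, `p_value`, `p_adjusted`; the full table
#'   for all tested pairs is attached as attribute `"all_pairs"`.
#' @export
screen_prognostic_pairs <- function(pm, time, event, fwer_alpha = 0.05,
                                    method = c("holm", "bonferroni",
                                               "none")) {
  method <- match.arg(method)
  if (!is.numeric(fwer_alpha) || fwer_alpha <= 0 || fwer_alpha > 1)
    stop_("'fwer_alpha' must be in (0, 1]")
  check_surv(time, event, need_event = TRUE)
  if (ncol(pm) != length(time)) stop_("one sample column per subject")
  rs <- rowSums(pm)
  testable <- rs > 0L & rs < ncol(pm)
  if (any(!testable))
    warn_(sum(!testable), " constant pair(s) skipped; ",
          "run filter_constant_pairs() first")
  ids <- rownames(pm)[testable]
  stat <- vapply(which(testable), function(i) {
    lr <- logrank_test(time, event, pm[i, ])
    c(lr$chi2, lr$p_value)
  }, numeric(2L))
  p_adj <- if (method == "none") stat[2L, ]
           else adjust_fwer(stat[2L, ], method = method)
  pairs <- split_pair_ids(ids)
  all_pairs <- data.frame(
    pair_id = ids, gene1 = pairs[, "gene1"], gene2 = pairs[, "gene2"],
    chi2 = stat[1L, ], p_value = stat[2L, ], p_adjusted = p_adj,
    stringsAsFactors = FALSE)
  sel <- all_pairs[all_pairs$p_adjusted < fwer_alpha, , drop = FALSE]
  sel <- sel[order(sel$p_adjusted, sel$p_value, sel$pair_id), ,
             drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "all_pairs") <- all_pairs
  sel
}

#' Score samples with a gene-pair signature
#'
#' Computes the risk score `sum_k beta_k * s_k` for each sample, where
#' `s_k` is the indicator of the k-th signature pair evaluated in the
#' pair's stored gene order. The input may be an expression matrix
#' (genes x samples), a single named expression profile, or a
#' precomputed pair-indicator matrix/vector named by pair ids. Scoring
#' needs nothing beyond the sample itself, so a single profile can be
#' scored in isolation, and any strictly increasing per-sample transform
#' of the expression values leaves the scores identical.
#'
#' @param x expression matrix with gene rownames, named numeric profile
#'   vector, or 0/1 pair-indicator matrix (pairs x samples) / vector
#'   named `"gene1|gene2"`.
#' @param model a [pair_signature()].
#' @return named numeric vector of risk scores, one per sample.
#' @export
score_rpi <- function(x, model) {
  if (!inherits(model, "pair_signature")) stop_("not a pair_signature")
  if (!length(model)) stop_("signature has 0 pairs")
  ids <- rownames(model$pairs)
  if (is.null(dim(x))) {
    x <- as.matrix(x)
    colnames(x) <- "sample"
  }
  nm <- rownames(x)
  if (is.null(nm)) stop_("input must carry gene or pair-id names")
  if (all(ids %in% nm)) {                       # pair-indicator input
    ind <- x[ids, , drop = FALSE]
    if (!all(ind %in% c(0, 1)))
      stop_("pair-indicator input must be 0/1")
  } else {                                      # expression input
    genes <- unique(c(model$pairs$gene1, model$pairs$gene2))
    absent <- setdiff(genes, nm)
    if (length(absent))
      stop_("gene(s) absent from input: ", paste(absent, collapse = ", "))
    e1 <- unclass(x)[model$pairs$gene1, , drop = FALSE]
    e2 <- unclass(x)[model$pairs$gene2, , drop = FALSE]
    if (!all(is.finite(e1)) || !all(is.finite(e2)))
      stop_("non-finite expression values for signature genes")
    ind <- (e1 < e2) + 0
  }
  drop(crossprod(ind, unname(model$coefficients))[, 1L])
}

#' Stratify risk scores at a cutoff
#'
#' Assigns each sample to the high-risk group when its score strictly
#' exceeds the cutoff; scores at or below the cutoff (including exact
#' ties) are low risk.
#'
#' @param scores finite numeric risk scores.
#' @param cutoff single finite threshold.
#' @return factor with levels `c("low", "high")`, named like `scores`.
#' @export
stratify <- function(scores, cutoff) {
  if (!all(is.finite(scores))) stop_("scores must be finite")
  if (length(cutoff) != 1L || !is.finite(cutoff))
    stop_("cutoff must be a single finite number")
  factor(ifelse(scores > cutoff, "high", "low"),
         levels = c("low", "high"))
}
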