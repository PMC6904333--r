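#' Differential-expression candidate screen
#'
#' Nominates candidate genes for pairing by a two-group contrast on
#' log2-scale expression: per-gene log2 fold change (mean of group 1
#' minus mean of group 0) and a Welch two-sample t-test p-value. Genes
#' passing both `p <= p_threshold` and `|logFC| >= logfc_threshold` are
#' returned. This stage only nominates candidates; no multiplicity
#' correction is applied here (familywise error control enters at the
#' pair-screening stage).
#'
#' @param expr an [expression_matrix()] on the log2 scale.
#' @param group_labels binary (0/1 or two-level) vector, one per sample;
#'   both groups need at least two samples.
#' @param p_threshold p-value cutoff in (0, 1], default 0.05.
#' @param logfc_threshold non-negative absolute log2-fold-change cutoff,
#'   default 1.
#' @return a `data.frame` with one row per selected gene: `gene_id`,
#'   `logfc`, `p_value`, `direction` (`"up"`/`"down"` in group 1 relative
#'   to group 0). The full per-gene table is attached as attribute
#'   `"all_genes"`.
#' @export
select_degs <- function(expr, group_labels, p_threshold = 0.05,
                        logfc_threshold = 1) {
  if (!is_log_scale(expr))
    stop_("DEG screen expects log2-scale expression")
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1)
    stop_("'p_threshold' must be in (0, 1]")
  if (!is.numeric(logfc_threshold) || logfc_threshold < 0)
    stop_("'logfc_threshold' must be non-negative")
  g <- as.factor(group_labels)
  if (nlevels(g) != 2L) stop_("'group_labels' must have exactly 2 levels")
  if (length(g) != ncol(expr))
    stop_("one group label per sample required")
  # group "1" (second level) is the contrast numerator
  a <- unclass(expr)[, g == levels(g)[2L], drop = FALSE]
  b <- unclass(expr)[, g == levels(g)[1L], drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop_("each group needs at least 2 samples")
  wt <- welch_rows(a, b)
  logfc <- rowMeans(a) - rowMeans(b)
  all_genes <- data.frame(
    gene_id = rownames(expr), logfc = unname(logfc),
    p_value = wt$p,
    direction = ifelse(logfc >= 0, "up", "down"),
    stringsAsFactors = FALSE)
  sel <- all_genes$p_value <= p_threshold &
    abs(all_genes$logfc) >= logfc_threshold
  out <- all_genes[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_genes") <- all_genes
  out
}

# row-wise Welch t-test (unequal variances); degenerate rows with zero
# variance in both groups get p = 1 when means agree, p = 0 otherwise
welch_rows <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero <- se2 == 0
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  list(t = tstat, df = df, p = unname(p))
}
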