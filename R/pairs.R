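#' Score a gene pair within a sample
#'
#' The elementary rank comparison: returns 1 when the first gene's
#' abundance is strictly less than the second's, and 0 otherwise (ties
#' score 0). Vectorized over its arguments.
#'
#' @param e1,e2 finite numeric abundances of the pair's two genes.
#' @return integer vector of 0/1 indicators.
#' @export
pair_score <- function(e1, e2) {
  if (!is.numeric(e1) || !is.numeric(e2) ||
      !all(is.finite(e1)) || !all(is.finite(e2)))
    stop_("pair_score needs finite numeric inputs")
  as.integer(e1 < e2)
}

#' Build the binary gene-pair indicator matrix
#'
#' Forms every unordered pair of the candidate genes, oriented
#' canonically (lexicographically by gene id), and scores each pair in
#' each sample with [pair_score()]. The result depends only on
#' within-sample ranks, so any strictly increasing per-sample transform
#' of the expression values (log, global scaling between abundance
#' units, ...) leaves it bitwise unchanged.
#'
#' @param expr an [expression_matrix()] (or plain named matrix),
#'   genes in rows.
#' @param candidate_genes character vector of at least two gene ids,
#'   all present in `expr`.
#' @return a pairs-by-samples binary matrix of class `"pair_matrix"`
#'   with rownames `"gene1|gene2"` and a 2-column character attribute
#'   `"pairs"`.
#' @export
build_pair_matrix <- function(expr, candidate_genes) {
  candidate_genes <- unique(as.character(candidate_genes))
  missing <- setdiff(candidate_genes, rownames(expr))
  if (length(missing))
    stop_("gene(s) not in expression matrix: ",
          paste(missing, collapse = ", "))
  if (length(candidate_genes) < 2L)
    stop_("need at least 2 candidate genes")
  genes <- sort(candidate_genes)            # canonical orientation
  idx <- utils::combn(length(genes), 2L)
  g1 <- genes[idx[1L, ]]; g2 <- genes[idx[2L, ]]
  x <- unclass(expr)[genes, , drop = FALSE]
  if (!all(is.finite(x))) stop_("non-finite expression values")
  pm <- (x[g1, , drop = FALSE] < x[g2, , drop = FALSE]) + 0L
  storage.mode(pm) <- "integer"
  rownames(pm) <- make_pair_ids(g1, g2)
  structure(pm, pairs = cbind(gene1 = g1, gene2 = g2),
            class = c("pair_matrix", "matrix", "array"))
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("pair matrix: %d gene pairs x %d samples\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Drop pairs that are constant in any dataset
#'
#' A pair whose indicator row is all 0 or all 1 in any single dataset
#' carries no within-cohort information there and is removed to increase
#' reproducibility; only pairs that vary (contain both 0 and 1) in
#' every supplied dataset are retained.
#'
#' @param pms a single pair matrix or a list of pair matrices sharing
#'   the same pair rows (e.g. training and validation cohorts).
#' @return character vector of retained pair ids; empty with a warning
#'   if every pair is constant somewhere.
#' @export
filter_constant_pairs <- function(pms) {
  if (!is.list(pms)) pms <- list(pms)
  if (!length(pms)) stop_("no pair matrices supplied")
  ids <- rownames(pms[[1L]])
  for (pm in pms[-1L]) {
    if (!identical(rownames(pm), ids))
      stop_("pair matrices do not share identical pair ids")
  }
  keep <- rep(TRUE, length(ids))
  for (pm in pms) {
    rs <- rowSums(pm)
    keep <- keep & rs > 0L & rs < ncol(pm)
  }
  if (!any(keep)) warn_("all pairs are constant in at least one dataset")
  ids[keep]
}
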