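#' Construct an expression matrix
#'
#' Wraps a genes-by-samples numeric matrix with the metadata the pipeline
#' needs: the abundance units the values are recorded in and whether they
#' are already on the log2 scale. Gene and sample identifiers are taken
#' from the dimnames and must be unique; duplicate gene rows should be
#' collapsed before construction (see [read_expression()]).
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names. All values must be finite, and
#'   non-negative unless `log_scale = TRUE`.
#' @param units character scalar recording the abundance units
#'   (e.g. `"FPKM"`, `"RPM"`); purely descriptive.
#' @param log_scale logical; `TRUE` if values are already log2-transformed.
#' @return the matrix with class `"expr_matrix"` and attributes `units`
#'   and `log_scale`.
#' @seealso [read_expression()], [log2_transform()], [quantile_normalize()]
#' @export
expression_matrix <- function(values, units = "arbitrary", log_scale = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_("'values' must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop_("expression matrix is empty")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop_("duplicate gene identifiers; collapse duplicates first")
  if (anyDuplicated(colnames(values)))
    stop_("duplicate sample identifiers")
  if (!all(is.finite(values)))
    stop_("expression values must be finite")
  if (!isTRUE(log_scale) && any(values < 0))
    stop_("negative values in a non-log-scale matrix")
  structure(values,
            units = as.character(units)[1L],
            log_scale = isTRUE(log_scale),
            class = c("expr_matrix", "matrix", "array"))
}

is_log_scale <- function(x) isTRUE(attr(x, "log_scale"))

#' Read a delimited gene-by-sample expression table
#'
#' Expects a header row of sample identifiers and gene identifiers in the
#' first column. Rows sharing a gene identifier (e.g. multiple probes of
#' one RNA) are collapsed to their per-gene mean before construction, so
#' the result has unique gene ids. Any cell that does not parse as a
#' number (including `NA`) is an error naming the offending gene and
#' sample.
#'
#' @param path path to a delimited text file.
#' @param delimiter field separator, default tab.
#' @param units abundance units to record, see [expression_matrix()].
#' @param log_scale whether the file already holds log2 values.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, delimiter = "\t", units = "arbitrary",
                            log_scale = FALSE) {
  if (!file.exists(path)) stop_("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop_("empty expression table: ", path)
  genes <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop_("non-numeric value '", body[bad[1L], bad[2L]], "' at gene '",
          genes[bad[1L]], "', sample '", samples[bad[2L]], "'")
  }
  # collapse duplicate gene ids by per-gene mean; preserve first-seen order
  if (anyDuplicated(genes)) {
    fac <- factor(genes, levels = unique(genes))
    num <- rowsum(num, fac, reorder = FALSE) / as.vector(table(fac))
    genes <- unique(raw[[1L]])
  }
  dimnames(num) <- list(genes, samples)
  expression_matrix(num, units = units, log_scale = log_scale)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples (%s%s)\n",
              nrow(x), ncol(x), attr(x, "units"),
              if (is_log_scale(x)) ", log2 scale" else ""))
  invisible(x)
}

#' Log2-transform an expression matrix
#'
#' Applies `log2(v + offset)` elementwise. Refuses to transform a matrix
#' already flagged as log-scale, so the conversion can never be applied
#' twice.
#'
#' @param expr an [expression_matrix()] on the raw abundance scale.
#' @param offset positive pseudocount added before taking logs.
#' @return the transformed [expression_matrix()] with `log_scale = TRUE`.
#' @export
log2_transform <- function(expr, offset = 1) {
  if (is_log_scale(expr)) stop_("matrix is already log2 scale")
  if (!is.numeric(offset) || length(offset) != 1L || offset <= 0)
    stop_("'offset' must be a positive scalar")
  expression_matrix(log2(unclass(expr) + offset),
                    units = attr(expr, "units"), log_scale = TRUE)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample column onto the identical value distribution (the
#' row-wise mean of the sorted columns) while preserving within-sample
#' ranks; ties receive the mean of the reference values at their rank
#' positions, which makes the operation idempotent. The heavy lifting is
#' done by [limma::normalizeQuantiles()].
#'
#' @param expr an [expression_matrix()] with at least two samples.
#' @return the normalized [expression_matrix()].
#' @export
quantile_normalize <- function(expr) {
  if (ncol(expr) < 2L)
    stop_("quantile normalization needs at least 2 samples")
  out <- limma::normalizeQuantiles(unclass(expr), ties = TRUE)
  dimnames(out) <- dimnames(expr)
  expression_matrix(out, units = attr(expr, "units"),
                    log_scale = is_log_scale(expr))
}
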