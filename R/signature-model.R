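#' Construct a gene-pair signature model
#'
#' A signature is an ordered list of gene pairs with one Cox coefficient
#' per pair and a risk-score cutoff. The risk score of a sample is
#' `sum_k beta_k * s_k`, where `s_k` is 1 when the pair's first gene is
#' expressed strictly below its second gene within that sample and 0
#' otherwise. Because the indicators only compare abundances inside one
#' sample, the score is invariant to any per-sample monotone rescaling
#' (FPKM vs RPM and the like) and needs no cohort for normalization.
#'
#' The stored (gene1, gene2) order of each pair is honored verbatim when
#' scoring: coefficients are order-dependent, so pairs are never
#' re-canonicalized here.
#'
#' @param gene1,gene2 character vectors of gene identifiers; members of a
#'   pair must differ and pairs must be unique.
#' @param coefficients numeric coefficient per pair, finite.
#' @param cutoff risk-score threshold dividing high from low risk
#'   (`score > cutoff` is high risk); `NA` until one is chosen.
#' @param cutoff_method how the cutoff was (or will be) chosen:
#'   `"roc"` (time-dependent ROC, fixed across cohorts) or `"median"`
#'   (recomputed per cohort).
#' @param endpoint label of the survival endpoint the model targets.
#' @param label free-text provenance label.
#' @return an object of class `"pair_signature"`.
#' @seealso [published_signature()], [score_rpi()], [read_signature()]
#' @export
pair_signature <- function(gene1, gene2, coefficients, cutoff = NA_real_,
                           cutoff_method = c("roc", "median"),
                           endpoint = "OS", label = "") {
  cutoff_method <- match.arg(cutoff_method)
  gene1 <- as.character(gene1); gene2 <- as.character(gene2)
  if (length(gene1) != length(gene2) ||
      length(gene1) != length(coefficients))
    stop_("gene1, gene2 and coefficients must have equal length")
  if (length(gene1) == 0L)
    warn_("signature with 0 pairs")
  if (any(gene1 == gene2))
    stop_("a pair's two genes must differ")
  ids <- make_pair_ids(gene1, gene2)
  if (anyDuplicated(ids)) stop_("duplicate gene pairs")
  if (!all(is.finite(coefficients))) stop_("coefficients must be finite")
  if (length(cutoff) != 1L || (!is.na(cutoff) && !is.finite(cutoff)))
    stop_("cutoff must be a single finite number or NA")
  structure(list(
    pairs = data.frame(gene1 = gene1, gene2 = gene2,
                       stringsAsFactors = FALSE, row.names = ids),
    coefficients = stats::setNames(as.numeric(coefficients), ids),
    cutoff = as.numeric(cutoff),
    cutoff_method = cutoff_method,
    endpoint = as.character(endpoint)[1L],
    label = as.character(label)[1L]),
    class = "pair_signature")
}

#' @export
print.pair_signature <- function(x, ...) {
  cat(sprintf("gene-pair signature '%s' (%s): %d pairs, cutoff %s (%s)\n",
              x$label, x$endpoint, nrow(x$pairs),
              if (is.na(x$cutoff)) "unset" else format(x$cutoff),
              x$cutoff_method))
  if (nrow(x$pairs)) {
    df <- cbind(x$pairs, coefficient = unname(x$coefficients))
    print(df, ...)
  }
  invisible(x)
}

#' @export
length.pair_signature <- function(x) nrow(x$pairs)

#' @export
coef.pair_signature <- function(object, ...) object$coefficients

#' The published ten-pair neuroblastoma signature
#'
#' Returns the bundled ten gene-pair overall-survival signature for
#' neuroblastoma, with full-precision coefficients and the fixed
#' ROC-derived risk-score cutoff of -4.774 that transfers unchanged from
#' the training cohort to any new cohort or single sample.
#'
#' @return a [pair_signature()] with 10 pairs.
#' @export
published_signature <- function() {
  path <- system.file("extdata", "nbl_rpi_signature.txt",
                      package = "pairsig", mustWork = TRUE)
  read_signature(path)
}

#' The published clinically adjusted composite model
#'
#' Weights combining the binary stage-4 indicator with the continuous
#' gene-pair risk score: `RCPI = 1.8445 * stage4 + 1.0563 * RPI`,
#' thresholded at the median of the cohort it is applied to.
#'
#' @return an object of class `"rcpi_model"` (see [rcpi()]).
#' @export
published_rcpi <- function() {
  new_rcpi_model(weights = c(stage4 = 1.8445, rpi = 1.0563),
                 label = "published")
}

#' Write / read a signature file
#'
#' A signature is serialized as a single structured text document: a
#' `key: value` header (schema version, label, endpoint, cutoff, cutoff
#' method) followed by a tab-separated pair table. All reals are written
#' with 17 significant digits so a write/read round trip reproduces the
#' model bit-for-bit.
#'
#' @param model a [pair_signature()].
#' @param path file path.
#' @return `write_signature` returns `path` invisibly; `read_signature`
#'   returns the [pair_signature()].
#' @export
write_signature <- function(model, path) {
  if (!inherits(model, "pair_signature")) stop_("not a pair_signature")
  head <- c("pairsig-signature: 1",
            paste0("label: ", model$label),
            paste0("endpoint: ", model$endpoint),
            paste0("cutoff: ", if (is.na(model$cutoff)) "NA"
                   else fmt_num(model$cutoff)),
            paste0("cutoff_method: ", model$cutoff_method),
            "pairs:",
            "gene1\tgene2\tcoefficient")
  rows <- if (nrow(model$pairs)) {
    paste(model$pairs$gene1, model$pairs$gene2,
          vapply(unname(model$coefficients), fmt_num, ""), sep = "\t")
  } else character()
  writeLines(c(head, rows), path)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop_("file not found: ", path)
  lines <- readLines(path)
  sep <- match("pairs:", trimws(lines))
  if (is.na(sep)) stop_("signature schema error: missing 'pairs:' section")
  head <- lines[seq_len(sep - 1L)]
  kv <- regmatches(head, regexec("^([^:]+):\\s*(.*)$", head))
  keys <- vapply(kv, function(m) if (length(m)) m[2L] else NA_character_, "")
  vals <- vapply(kv, function(m) if (length(m)) m[3L] else NA_character_, "")
  get <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) stop_("signature schema error: missing field '", key, "'")
    vals[i]
  }
  cutoff <- get("cutoff")
  cutoff <- if (identical(cutoff, "NA")) NA_real_ else as.numeric(cutoff)
  body <- lines[-seq_len(sep + 1L)]  # drop header row of the pair table
  body <- body[nzchar(trimws(body))]
  if (length(body)) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(fields) != 3L))
      stop_("signature schema error: malformed pair row")
    m <- do.call(rbind, fields)
    g1 <- m[, 1L]; g2 <- m[, 2L]; co <- as.numeric(m[, 3L])
    if (anyNA(co)) stop_("signature schema error: non-numeric coefficient")
  } else {
    g1 <- g2 <- character(); co <- numeric()
  }
  pair_signature(g1, g2, co, cutoff = cutoff,
                 cutoff_method = get("cutoff_method"),
                 endpoint = get("endpoint"), label = get("label"))
}
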