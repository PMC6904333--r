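# Internal helpers shared across the package.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_ <- function(...) stop(..., call. = FALSE)
warn_ <- function(...) warning(..., call. = FALSE)

# gene-pair id strings; "|" is reserved (gene symbols may contain "-",
# e.g. the FXYD6-FXYD2 readthrough)
PAIR_SEP <- "|"

make_pair_ids <- function(gene1, gene2) {
  if (any(grepl(PAIR_SEP, c(gene1, gene2), fixed = TRUE)))
    stop_("gene identifiers must not contain '", PAIR_SEP, "'")
  paste(gene1, gene2, sep = PAIR_SEP)
}

split_pair_ids <- function(ids) {
  parts <- strsplit(ids, PAIR_SEP, fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop_("malformed pair id(s): ", paste(ids[bad], collapse = ", "))
  m <- do.call(rbind, parts)
  colnames(m) <- c("gene1", "gene2")
  m
}

fmt_num <- function(x) sprintf("%.17g", x)
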