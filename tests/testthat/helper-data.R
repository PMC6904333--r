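# Fixtures built in code at test time.

write_expr_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# small deterministic expression matrix with given dims
toy_expr <- function(n_genes = 5, n_samples = 4, seed = 42,
                     log_scale = FALSE) {
  vals <- pairsig:::with_seed(seed,
    matrix(stats::runif(n_genes * n_samples, 1, 100),
           nrow = n_genes,
           dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                           sprintf("S%02d", seq_len(n_samples)))))
  if (log_scale) vals <- log2(vals + 1)
  expression_matrix(vals, units = "FPKM", log_scale = log_scale)
}

# six-subject mixed survival set used for hand-checked KM/Cox tests
toy_surv6 <- function() {
  list(time = c(2, 3, 3, 5, 8, 9),
       event = c(1, 1, 0, 1, 0, 1))
}
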