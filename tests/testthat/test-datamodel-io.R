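test_that("read_expression collapses duplicate gene rows by their mean", {
  path <- write_expr_file(c("gene\tS1\tS2",
                            "GENE1\t2\t10",
                            "GENE2\t5\t6",
                            "GENE1\t4\t20"))
  m <- read_expression(path)
  expect_equal(rownames(m), c("GENE1", "GENE2"))
  expect_equal(unclass(m)["GENE1", ], c(S1 = 3, S2 = 15))
  expect_equal(unclass(m)["GENE2", ], c(S1 = 5, S2 = 6))
})

test_that("duplicate collapsing is order-independent", {
  a <- read_expression(write_expr_file(c("g\tS1", "X\t2", "Y\t7", "X\t4")))
  b <- read_expression(write_expr_file(c("g\tS1", "X\t4", "X\t2", "Y\t7")))
  expect_equal(unclass(a)[sort(rownames(a)), , drop = FALSE],
               unclass(b)[sort(rownames(b)), , drop = FALSE])
})

test_that("unique-id tables are read verbatim and bad cells are named", {
  path <- write_expr_file(c("g\tS1\tS2", "A\t1.5\t2", "B\t0\t3.25"))
  m <- read_expression(path)
  expect_equal(as.vector(unclass(m)), c(1.5, 0, 2, 3.25))
  bad <- write_expr_file(c("g\tS1\tS2", "A\t1\tNA", "B\t2\t3"))
  expect_error(read_expression(bad), "gene 'A'.*sample 'S2'")
  expect_error(read_expression(write_expr_file("g\tS1")), "empty")
})

test_that("expression_matrix enforces its invariants", {
  v <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_s3_class(expression_matrix(v), "expr_matrix")
  v2 <- v; rownames(v2) <- c("a", "a")
  expect_error(expression_matrix(v2), "duplicate gene")
  v3 <- v; v3[1] <- -1
  expect_error(expression_matrix(v3), "negative")
  expect_silent(expression_matrix(v3 * 1.0, log_scale = TRUE))
  v4 <- v; v4[1] <- Inf
  expect_error(expression_matrix(v4), "finite")
})

test_that("read_clinical applies the dichotomizations and error contracts", {
  path <- write_expr_file(c(
    "id\tsex\tage\tmycn\tstage\ttime\tdead",
    "P1\tMale\t<18 months\tAmplified\t4S\t12.5\t0",
    "P2\tFemale\t>=18 months\tNot Amplified\t4\t0\t0",
    "P3\tfemale\tUnknown\tUnknown\t2\t30\t1"))
  map <- list(sample = "id", sex = "sex", age = "age", mycn = "mycn",
              stage = "stage", os_time = "time", os_event = "dead")
  cl <- read_clinical(path, map)
  expect_equal(cl$age_ge_18m, c(0, 1, NA))
  expect_equal(cl$stage4, c(0, 1, 0))
  expect_equal(cl$mycn_amplified, c(1, 0, NA))
  expect_equal(cl$sex, c("male", "female", "female"))
  expect_equal(cl$os_time[2], 0)  # censored at origin is accepted

  bad_event <- sub("30\t1", "30\t2", readLines(path))
  expect_error(read_clinical(write_expr_file(bad_event), map),
               "outside \\{0,1\\}")
  bad_stage <- sub("\t2\t", "\tstage9\t", readLines(path))
  expect_error(read_clinical(write_expr_file(bad_stage), map), "stage9")
  bad_time <- sub("12\\.5", "-3", readLines(path))
  expect_error(read_clinical(write_expr_file(bad_time), map), "negative")
})

test_that("day-denominated times are converted to months", {
  path <- write_expr_file(c("id\ttime\tdead", "P1\t365.25\t1"))
  cl <- read_clinical(path, list(sample = "id", os_time = "time",
                                 os_event = "dead"), time_unit = "days")
  expect_equal(cl$os_time, 365.25 / 30.4375)
})

test_that("signature files round-trip bit-for-bit", {
  sig <- pair_signature(c("A", "B"), c("C", "FX-Y2"),
                        c(-1.234567891234, 0.000123456789),
                        cutoff = -4.774, cutoff_method = "roc",
                        endpoint = "OS", label = "roundtrip")
  path <- withr::local_tempfile()
  write_signature(sig, path)
  back <- read_signature(path)
  expect_identical(back$coefficients, sig$coefficients)
  expect_identical(back$pairs, sig$pairs)
  expect_identical(back$cutoff, sig$cutoff)
  expect_identical(back$cutoff_method, sig$cutoff_method)
})

test_that("degenerate and malformed signature files follow the contract", {
  empty <- suppressWarnings(pair_signature(character(), character(),
                                           numeric(), cutoff = 0))
  path <- withr::local_tempfile()
  write_signature(empty, path)
  expect_warning(read_signature(path), "0 pairs")

  lines <- readLines(path)
  writeLines(lines[!grepl("^cutoff:", lines)], path)
  expect_error(read_signature(path), "missing field 'cutoff'")
})

test_that("the bundled published signature matches its printed source", {
  sig <- published_signature()
  expect_equal(length(sig), 10L)
  expect_equal(unname(coef(sig)["EFNB3|EREG"]), -1.48200304)
  expect_equal(sig$cutoff, -4.774)
  expect_identical(sig$cutoff_method, "roc")
  expect_identical(sig$pairs["CIB4|FXYD6-FXYD2", "gene2"], "FXYD6-FXYD2")
})
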