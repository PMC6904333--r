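test_that("score_rpi reproduces the published worked values", {
  sig <- published_signature()
  ids <- rownames(sig$pairs)
  zeros <- stats::setNames(rep(0, 10), ids)
  expect_equal(unname(score_rpi(zeros, sig)), 0)

  one <- zeros; one["EFNB3|EREG"] <- 1
  expect_equal(unname(score_rpi(one, sig)), -1.48200304)

  ones <- stats::setNames(rep(1, 10), ids)
  # independent arithmetic oracle: plain sum of the coefficients
  expect_equal(unname(score_rpi(ones, sig)), sum(coef(sig)))
  expect_equal(unname(score_rpi(ones, sig)), -5.022125484,
               tolerance = 1e-12)
})

test_that("score_rpi honors the stored gene order, not canonical order", {
  sig <- pair_signature("ZZZ", "AAA", 2)   # reverse-lexicographic pair
  x <- matrix(c(1, 5), 2, 1, dimnames = list(c("ZZZ", "AAA"), "s"))
  # ZZZ (1) < AAA (5) -> indicator 1 in the stored order
  expect_equal(unname(score_rpi(x, sig)), 2)
  x2 <- matrix(c(5, 1), 2, 1, dimnames = list(c("ZZZ", "AAA"), "s"))
  expect_equal(unname(score_rpi(x2, sig)), 0)
})

test_that("scores are invariant under per-sample monotone rescaling", {
  m <- toy_expr(12, 8, seed = 6)
  sig <- pair_signature(c("G01", "G03"), c("G05", "G07"), c(-1.2, 0.4),
                        cutoff = -0.5)
  fpkm <- score_rpi(m, sig)
  rpm <- score_rpi(expression_matrix(unclass(m) * 10, units = "RPM"),
                   sig)
  logd <- score_rpi(log2_transform(m), sig)
  expect_identical(fpkm, rpm)
  expect_identical(fpkm, logd)
  expect_identical(stratify(fpkm, sig$cutoff), stratify(rpm, sig$cutoff))
})

test_that("single-sample scoring equals cohort scoring", {
  m <- toy_expr(12, 8, seed = 6)
  sig <- pair_signature(c("G01", "G03"), c("G05", "G07"), c(-1.2, 0.4),
                        cutoff = -0.5)
  cohort <- score_rpi(m, sig)
  singles <- vapply(colnames(m), function(s)
    unname(score_rpi(unclass(m)[, s], sig)), 0)
  expect_equal(cohort, singles)
  expect_identical(stratify(cohort, sig$cutoff),
                   stratify(singles, sig$cutoff))
})

test_that("score_rpi errors name absent genes", {
  m <- toy_expr(4, 3)
  sig <- pair_signature(c("G01", "MISSING1"), c("G02", "MISSING2"),
                        c(1, 1))
  expect_error(score_rpi(m, sig), "MISSING1, MISSING2")
})

test_that("stratify applies the strict cutoff rule with ties low", {
  expect_equal(as.character(stratify(-5.022125484, -4.774)), "low")
  expect_equal(as.character(stratify(0, -4.774)), "high")
  expect_equal(as.character(stratify(-4.774, -4.774)), "low")
  expect_error(stratify(c(1, NA), 0), "finite")
})

test_that("screen_prognostic_pairs ranks by adjusted p and respects alpha", {
  d <- pairsig:::with_seed(31, {
    n <- 160
    sig_ind <- stats::rbinom(n, 1, 0.4)
    noise <- matrix(stats::rbinom(5 * n, 1, 0.5), 5, n)
    pm <- rbind(sig_ind, noise)
    rownames(pm) <- paste0("g", 1:6, "|h", 1:6)
    tt <- stats::rexp(n, 0.05 * exp(1.3 * sig_ind))
    list(pm = pm, t = tt, e = rep(1L, n))
  })
  pm <- structure(d$pm, pairs = pairsig:::split_pair_ids(rownames(d$pm)),
                  class = c("pair_matrix", "matrix", "array"))
  sel <- screen_prognostic_pairs(pm, d$t, d$e, fwer_alpha = 0.05)
  expect_true("g1|h1" %in% sel$pair_id)
  expect_false(is.unsorted(sel$p_adjusted))
  # vacuous screen (no adjustment, alpha 1) keeps every testable pair
  all_sel <- screen_prognostic_pairs(pm, d$t, d$e, fwer_alpha = 1,
                                     method = "none")
  expect_equal(nrow(all_sel), 6L)
  # constant pairs are skipped with a warning
  pmc <- rbind(pm, "x|y" = rep(1L, ncol(pm)))
  pmc <- structure(pmc, pairs = pairsig:::split_pair_ids(rownames(pmc)),
                   class = c("pair_matrix", "matrix", "array"))
  expect_warning(screen_prognostic_pairs(pmc, d$t, d$e), "constant")
})

test_that("evaluate_groups reports KM, log-rank, both HR orientations and AUCs", {
  d <- pairsig:::with_seed(41, {
    n <- 200
    score <- stats::rnorm(n)
    tt <- stats::rexp(n, 0.03 * exp(0.9 * (score > 0)))
    cc <- stats::runif(n, 0, 80)
    list(s = score, t = pmin(tt, cc), e = as.integer(tt <= cc))
  })
  ev <- evaluate_groups(d$s, d$t, d$e, cutoff = 0,
                        horizons = c(12, 36, 60))
  expect_equal(nrow(ev$auc), 3L)
  expect_equal(ev$auc$horizon, c(12, 36, 60))
  expect_equal(ev$cox_low_vs_high$hr, 1 / ev$cox_high_vs_low$hr)
  expect_gt(ev$cox_high_vs_low$hr, 1)
  expect_equal(unname(ev$n["low"] + ev$n["high"]), 200L)
  expect_error(evaluate_groups(d$s, d$t, d$e, cutoff = 99), "single")
})

test_that("subgroup_analysis skips degenerate strata and excludes NA listwise", {
  d <- pairsig:::with_seed(51, {
    n <- 120
    score <- stats::rnorm(n)
    tt <- stats::rexp(n, 0.03 * exp(1.0 * (score > 0)))
    list(s = score, t = tt, e = rep(1L, n),
         clin = data.frame(
           stage4 = stats::rbinom(n, 1, 0.5),
           mycn_amplified = c(rep(NA, 6), stats::rbinom(n - 6, 1, 0.3)),
           onelevel = rep(1, n)))
  })
  expect_warning(
    res <- subgroup_analysis(d$s, d$t, d$e, cutoff = 0, clinical = d$clin,
                             factors = c("stage4", "mycn_amplified",
                                         "onelevel"),
                             horizons = 12),
    "single level")
  expect_true(all(res$factor %in% c("stage4", "mycn_amplified")))
  na_rows <- res[res$factor == "mycn_amplified", ]
  expect_equal(sum(na_rows$n), 120 - 6)
  expect_true(all(res$hr_high_vs_low > 1))
})
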