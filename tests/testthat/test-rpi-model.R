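# end-to-end behaviour of the central fitting function

fit_once <- function(seed = 7) {
  sim <- generate_two_cohorts(sim_config(seed = seed))
  fit <- suppressWarnings(
    rpi(sim$cohort1$expression, sim$cohort1$clinical$os_time,
        sim$cohort1$clinical$os_event, seed = seed))
  list(sim = sim, fit = fit)
}

test_that("training logs every stage count and finds the planted pairs", {
  r <- fit_once()
  expect_named(r$fit$counts, c("genes_in", "pairs_built",
                               "pairs_after_filter",
                               "pairs_after_screen", "pairs_in_model"))
  expect_equal(unname(r$fit$counts["genes_in"]), 40)
  expect_equal(unname(r$fit$counts["pairs_built"]), choose(40, 2))
  expect_gte(length(r$fit$signature), 1L)
  # at least one planted pair passes the FWER screen (the penalized fit
  # may keep correlated surrogate pairs instead of the planted id)
  planted <- pairsig:::make_pair_ids(r$sim$truth$planted_pairs$gene1,
                                     r$sim$truth$planted_pairs$gene2)
  expect_true(any(planted %in% r$fit$screen$pair_id))
})

test_that("refitting with the same seed reproduces the model exactly", {
  a <- fit_once(seed = 19)$fit
  b <- fit_once(seed = 19)$fit
  expect_identical(a$signature$pairs, b$signature$pairs)
  expect_identical(a$signature$coefficients, b$signature$coefficients)
  expect_identical(a$signature$cutoff, b$signature$cutoff)
  expect_identical(a$scores, b$scores)
})

test_that("validation applies the fixed cutoff without re-estimation", {
  r <- fit_once()
  cl1 <- r$sim$cohort1$clinical
  # validating on the training cohort reproduces training stratification
  self <- validate_rpi(r$fit, r$sim$cohort1$expression,
                       cl1$os_time, cl1$os_event)
  expect_identical(unname(self$group), unname(r$fit$group))
  # rescaling the cohort 10x changes nothing
  resc <- expression_matrix(unclass(r$sim$cohort1$expression) * 10,
                            units = "RPM")
  again <- validate_rpi(r$fit, resc, cl1$os_time, cl1$os_event)
  expect_identical(unname(again$group), unname(self$group))
  expect_identical(again$logrank$chi2, self$logrank$chi2)
  # a cohort lacking a signature gene aborts naming it
  g1 <- r$fit$signature$pairs$gene1[1]
  missing <- unclass(r$sim$cohort2$expression)
  missing <- missing[setdiff(rownames(missing), g1), , drop = FALSE]
  expect_error(validate_rpi(r$fit, missing, cl1$os_time, cl1$os_event),
               g1)
})

test_that("predict returns scores, groups and indicator pairs coherently", {
  r <- fit_once()
  e2 <- r$sim$cohort2$expression
  sc <- predict(r$fit, e2, type = "score")
  gr <- predict(r$fit, e2, type = "group")
  pr <- predict(r$fit, e2, type = "pairs")
  expect_identical(gr, stratify(sc, r$fit$signature$cutoff))
  expect_equal(dim(pr), c(length(r$fit$signature), ncol(e2)))
  expect_equal(unname(drop(crossprod(pr, coef(r$fit)))), unname(sc))
  expect_identical(unname(coef(r$fit)),
                   unname(r$fit$signature$coefficients))
})

test_that("summary evaluates the training cohort", {
  r <- fit_once()
  s <- summary(r$fit, horizons = c(12, 36))
  expect_s3_class(s$training_evaluation, "group_eval")
  expect_equal(s$training_evaluation$auc$horizon, c(12, 36))
  expect_output(print(s), "training-cohort evaluation")
})

test_that("an event-free cohort aborts before any screening", {
  sim <- generate_two_cohorts(sim_config(seed = 4))
  cl <- sim$cohort1$clinical
  expect_error(rpi(sim$cohort1$expression, cl$os_time,
                   rep(0, nrow(cl)), seed = 1),
               "at least one event")
})

test_that("the optional per-gene prefilter narrows the candidate set", {
  sim <- generate_two_cohorts(sim_config(seed = 23))
  cl <- sim$cohort1$clinical
  fit <- rpi(sim$cohort1$expression, cl$os_time, cl$os_event,
             prefilter_p = 0.01, seed = 23)
  expect_lt(unname(fit$counts["genes_after_prefilter"]),
            unname(fit$counts["genes_in"]))
  expect_equal(unname(fit$counts["pairs_built"]),
               choose(unname(fit$counts["genes_after_prefilter"]), 2))
})
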