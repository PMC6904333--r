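test_that("km_curve reproduces closed-form and hand-computed curves", {
  # no censoring: S(t) drops by 1/n at each event
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$event_times, c(1, 2, 3))
  expect_equal(km$survival, c(2/3, 1/3, 0))
  expect_equal(km$n_at_risk, c(3, 2, 1))

  # all censored: survival stays 1, median undefined
  km0 <- km_curve(c(4, 5, 6), c(0, 0, 0))
  expect_length(km0$event_times, 0L)
  expect_true(is.na(km0$median_time))

  # mixed six-subject set against the naive product-limit oracle
  s <- toy_surv6()
  km6 <- km_curve(s$time, s$event)
  ref <- naive_km(s$time, s$event)
  expect_equal(km6$event_times, ref$event_times)
  expect_equal(km6$survival, ref$survival)
})

test_that("without censoring the KM curve equals the empirical survival", {
  t <- pairsig:::with_seed(1, stats::rexp(40, 0.1))
  km <- km_curve(t, rep(1, 40))
  emp <- vapply(km$event_times, function(u) mean(t > u), 0)
  expect_equal(km$survival, emp)
})

test_that("logrank_test matches the direct O-E summation oracle", {
  s <- toy_surv6()
  g <- c(0, 0, 1, 0, 1, 1)
  lr <- logrank_test(s$time, s$event, g)
  expect_equal(lr$chi2, naive_logrank_chi2(s$time, s$event, g),
               tolerance = 1e-10)
  expect_equal(lr$df, 1L)
  expect_equal(lr$p_value,
               stats::pchisq(lr$chi2, 1, lower.tail = FALSE))

  # completely separated event times
  t2 <- c(1, 2, 3, 10, 11, 12); e2 <- rep(1, 6)
  g2 <- rep(c("a", "b"), each = 3)
  lr2 <- logrank_test(t2, e2, g2)
  expect_equal(lr2$chi2, naive_logrank_chi2(t2, e2, g2),
               tolerance = 1e-10)
})

test_that("logrank chi2 is invariant to relabeling and time shifts", {
  s <- toy_surv6(); g <- c(0, 1, 0, 1, 0, 1)
  a <- logrank_test(s$time, s$event, g)
  b <- logrank_test(s$time, s$event, ifelse(g == 0, "x", "w"))
  d <- logrank_test(s$time + 100, s$event, g)
  expect_equal(a$chi2, b$chi2)
  expect_equal(a$chi2, d$chi2)

  # exchangeable groups: duplicated data in both groups gives chi2 = 0
  same <- logrank_test(rep(s$time, 2), rep(s$event, 2),
                       rep(c(0, 1), each = 6))
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-10)
})

test_that("logrank_test error contracts", {
  expect_error(logrank_test(1:4, rep(1, 4), rep("a", 4)), "2 groups")
  expect_error(logrank_test(1:4, rep(0, 4), c(1, 1, 2, 2)),
               "at least one event")
})

test_that("cox_fit matches grid-search partial-likelihood maximization", {
  t <- c(2, 4, 4, 6, 7, 9, 11, 12, 15, 17)
  e <- c(1, 1, 0, 1, 1, 0, 1, 1, 0, 1)
  x <- c(1, 1, 0, 1, 0, 1, 0, 1, 0, 0)
  fit <- cox_fit(data.frame(x = x), t, e)
  b_ref <- grid_max_cox(x, t, e)
  expect_equal(fit$coefficients$beta, b_ref, tolerance = 1e-6)
  expect_equal(fit$coefficients$hr, exp(fit$coefficients$beta))
  expect_equal(fit$log_partial_likelihood,
               breslow_loglik(fit$coefficients$beta,
                              matrix(x, ncol = 1), t, e),
               tolerance = 1e-8)
})

test_that("the score vanishes at the optimum and matches finite differences", {
  d <- pairsig:::with_seed(8, {
    n <- 120
    x <- cbind(a = stats::rbinom(n, 1, 0.5), b = stats::rnorm(n))
    tt <- stats::rexp(n, 0.1 * exp(0.6 * x[, "a"]))
    list(x = x, t = tt, e = stats::rbinom(n, 1, 0.8))
  })
  fit <- cox_fit(d$x, d$t, d$e)
  g <- breslow_grad(fit$coefficients$beta, d$x, d$t, d$e)
  expect_lt(max(abs(g)), 1e-5)
  # analytic gradient vs central finite differences of the loglik
  b0 <- c(0.3, -0.2); h <- 1e-5
  for (j in 1:2) {
    bp <- bm <- b0; bp[j] <- bp[j] + h; bm[j] <- bm[j] - h
    fd <- (breslow_loglik(bp, d$x, d$t, d$e) -
             breslow_loglik(bm, d$x, d$t, d$e)) / (2 * h)
    expect_equal(breslow_grad(b0, d$x, d$t, d$e)[j], fd,
                 tolerance = 1e-5)
  }
})

test_that("cox_fit error contracts", {
  s <- toy_surv6()
  expect_error(cox_fit(data.frame(x = rep(1, 6)), s$time, s$event),
               "constant")
  # complete separation: all events in one covariate level
  t <- c(1, 2, 3, 50, 60, 70, 80, 90)
  e <- c(1, 1, 1, 0, 0, 0, 0, 0)
  x <- c(1, 1, 1, 0, 0, 0, 0, 0)
  expect_error(cox_fit(data.frame(x = x), t, e), "penalized")
})

test_that("adjust_fwer implements bonferroni and holm", {
  expect_equal(adjust_fwer(rep(0.001, 31), "bonferroni")[1], 0.031)
  expect_equal(adjust_fwer(0.02, "holm"), 0.02)
  expect_equal(adjust_fwer(c(0.01, 0.04), "holm"), c(0.02, 0.04))
  p <- pairsig:::with_seed(4, stats::runif(20))
  expect_true(all(adjust_fwer(p) >= p))
  expect_error(adjust_fwer(c(0.5, 1.2)), "\\[0, 1\\]")
})
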