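# Independent oracles, deliberately naive: direct summations and grid
# searches kept separate from the package's implementation paths.

# product-limit survival at each event time, computed by direct counting
naive_km <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  surv <- numeric(length(et))
  s <- 1
  for (k in seq_along(et)) {
    u <- et[k]
    d <- sum(time == u & event == 1)
    n <- sum(time >= u)
    s <- s * (1 - d / n)
    surv[k] <- s
  }
  list(event_times = et, survival = surv)
}

# Breslow-ties Cox log partial likelihood and its analytic gradient
breslow_loglik <- function(beta, x, time, event) {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  ll <- 0
  for (i in which(event == 1)) {
    rs <- time >= time[i]
    ll <- ll + eta[i] - log(sum(w[rs]))
  }
  ll
}

breslow_grad <- function(beta, x, time, event) {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  g <- numeric(ncol(x))
  for (i in which(event == 1)) {
    rs <- time >= time[i]
    g <- g + x[i, ] - colSums(w[rs] * x[rs, , drop = FALSE]) / sum(w[rs])
  }
  unname(g)
}

# single-covariate partial-likelihood maximizer by iterative grid zoom
grid_max_cox <- function(x, time, event, lo = -6, hi = 6) {
  for (round in 1:7) {
    grid <- seq(lo, hi, length.out = 101)
    ll <- vapply(grid, function(b)
      breslow_loglik(b, matrix(x, ncol = 1), time, event), 0)
    k <- which.max(ll)
    lo <- grid[max(1, k - 1)]
    hi <- grid[min(length(grid), k + 1)]
  }
  (lo + hi) / 2
}

# two-group log-rank chi2 by direct O-E / hypergeometric-variance sums
naive_logrank_chi2 <- function(time, event, group) {
  g <- as.integer(factor(group)) == 1L
  oe <- v <- 0
  for (u in sort(unique(time[event == 1]))) {
    at <- time >= u
    n <- sum(at); n1 <- sum(at & g)
    d <- sum(time == u & event == 1)
    d1 <- sum(time == u & event == 1 & g)
    oe <- oe + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oe^2 / v
}
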