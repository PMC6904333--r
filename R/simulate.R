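#' Configuration for the two-cohort synthetic generator
#'
#' Bundles the parameters of the synthetic study design: two cohorts on
#' different abundance scales (emulating FPKM- and RPM-profiled
#' platforms) sharing a planted gene-pair hazard mechanism, with
#' exponential baseline event times, clinical covariates carrying their
#' own hazard, and uniform right-censoring calibrated to a target rate.
#'
#' The defaults define the study conditions the package's validation
#' runs under: cohort sizes of 150 and 250 with the clinical mix skewed
#' between cohorts (stage-4 and age-over-18-months fractions of about
#' 0.8 in cohort 1 versus 0.4 in cohort 2, mirroring the imbalance
#' typical of a high-risk training registry versus a broader validation
#' series), 40 genes of which 3 pairs carry a planted per-indicator
#' hazard ratio of 3, 50% indicator prevalence, an exponential baseline
#' hazard of 0.003 per month, 30% censoring, clinical log-hazards of
#' log(2) for stage 4 and log(1.5) for age, and a 10x abundance scale
#' factor between cohorts.
#'
#' @param n_samples integer vector of two cohort sizes.
#' @param n_genes number of genes.
#' @param n_planted_pairs number of gene pairs whose order relation
#'   drives the hazard (planted on disjoint genes).
#' @param pair_effect_betas log hazard ratio per planted pair indicator
#'   (recycled to `n_planted_pairs`).
#' @param pair_prevalence probability the planted indicator is 1.
#' @param baseline_hazard exponential baseline hazard per month.
#' @param weibull_shape Weibull shape of the event-time distribution;
#'   1 (default) gives the exponential baseline.
#' @param censoring_rate_target fraction of subjects censored, in
#'   `[0, 1)`.
#' @param clinical_effects named log hazard ratios for `stage4` and
#'   `age_ge_18m`.
#' @param p_stage4,p_age_ge_18m per-cohort fractions of stage-4 and
#'   older-age patients.
#' @param p_male,p_mycn,p_missing sex, MYCN-amplification and
#'   missing-MYCN fractions (shared by both cohorts).
#' @param platform_scale_factors per-cohort global abundance scale
#'   (strictly monotone, so pair indicators are unaffected).
#' @param efs_rate_ratio hazard multiplier generating the event-free
#'   survival endpoint from the same linear predictor.
#' @param sdlog log-normal within-gene spread of abundances.
#' @param seed master seed; per-cohort substreams are derived from it.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = c(150L, 250L), n_genes = 40L,
                       n_planted_pairs = 3L,
                       pair_effect_betas = log(3),
                       pair_prevalence = 0.5,
                       baseline_hazard = 0.003, weibull_shape = 1,
                       censoring_rate_target = 0.3,
                       clinical_effects = c(stage4 = log(2),
                                            age_ge_18m = log(1.5)),
                       p_stage4 = c(0.8, 0.4),
                       p_age_ge_18m = c(0.8, 0.4),
                       p_male = 0.58, p_mycn = 0.2, p_missing = 0.01,
                       platform_scale_factors = c(1, 10),
                       efs_rate_ratio = 1.4, sdlog = 0.5, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_genes = as.integer(n_genes),
              n_planted_pairs = as.integer(n_planted_pairs),
              pair_effect_betas = rep_len(pair_effect_betas,
                                          n_planted_pairs),
              pair_prevalence = pair_prevalence,
              baseline_hazard = baseline_hazard,
              weibull_shape = weibull_shape,
              censoring_rate_target = censoring_rate_target,
              clinical_effects = clinical_effects,
              p_stage4 = rep_len(p_stage4, 2L),
              p_age_ge_18m = rep_len(p_age_ge_18m, 2L),
              p_male = p_male, p_mycn = p_mycn, p_missing = p_missing,
              platform_scale_factors = rep_len(platform_scale_factors,
                                               2L),
              efs_rate_ratio = efs_rate_ratio, sdlog = sdlog,
              seed = as.integer(seed))
  with(cfg, {
    if (any(n_samples < 10L)) stop_("cohorts must have >= 10 samples")
    if (n_genes < 2L) stop_("need at least 2 genes")
    if (n_planted_pairs < 0L ||
        2L * n_planted_pairs > n_genes)
      stop_("planted pairs need 2 disjoint genes each")
    if (censoring_rate_target < 0 || censoring_rate_target >= 1)
      stop_("censoring target must be in [0, 1)")
    if (baseline_hazard <= 0 || weibull_shape <= 0)
      stop_("hazard parameters must be positive")
    if (any(platform_scale_factors <= 0))
      stop_("scale factors must be positive")
  })
  structure(cfg, class = "sim_config")
}

#' Generate one synthetic cohort
#'
#' Gene abundances are log-normal with gene-specific means (shared
#' between cohorts so both use the same gene identities). For each
#' planted pair a latent Bernoulli state fixes the within-sample order
#' relation of its two genes (values are swapped when needed), making
#' the pair indicator the exact hazard driver. Event times are Weibull
#' (exponential by default) with per-subject rate
#' `baseline * exp(sum(beta_k * s_k) + clinical effects)`; censoring
#' times are uniform on `(0, c_max)` with `c_max` calibrated so the
#' expected censoring fraction equals the target. Finally the cohort's
#' global platform scale factor is applied to the abundances — a
#' strictly monotone per-sample transform that leaves all pair
#' indicators untouched.
#'
#' @param config a [sim_config()].
#' @param cohort_index 1 or 2.
#' @return list with `expression` (an [expression_matrix()], units
#'   `"FPKM"` for cohort 1, `"RPM"` for cohort 2), `clinical` (a
#'   `clinical_table` with `os_*` and `efs_*` endpoints), and `truth`
#'   (planted pair table with betas, plus the latent indicator states).
#' @export
generate_cohort <- function(config, cohort_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (!cohort_index %in% c(1L, 2L)) stop_("cohort_index must be 1 or 2")
  # deterministic per-cohort substream of the master seed
  sub_seed <- (config$seed * 7L + cohort_index * 104729L) %% 2147483647L
  with_seed(sub_seed, generate_cohort_impl(config, cohort_index))
}

generate_cohort_impl <- function(config, ci) {
  n <- config$n_samples[ci]
  g <- config$n_genes
  genes <- sprintf("G%03d", seq_len(g))
  samples <- sprintf("C%dS%03d", ci, seq_len(n))

  # gene-specific log-means are a fixed property of the gene panel,
  # shared by both cohorts
  meanlog <- with_seed(config$seed, stats::runif(g, 1, 6))
  x <- matrix(stats::rlnorm(g * n, meanlog = rep(meanlog, n),
                            sdlog = config$sdlog),
              nrow = g, ncol = n, dimnames = list(genes, samples))

  npp <- config$n_planted_pairs
  planted <- if (npp > 0L) {
    cbind(gene1 = genes[seq_len(npp) * 2L - 1L],
          gene2 = genes[seq_len(npp) * 2L])
  } else {
    cbind(gene1 = character(), gene2 = character())
  }
  states <- matrix(0L, nrow = npp, ncol = n,
                   dimnames = list(if (npp) make_pair_ids(
                     planted[, 1L], planted[, 2L]), samples))
  for (k in seq_len(npp)) {
    s <- stats::rbinom(n, 1L, config$pair_prevalence)
    i1 <- planted[k, 1L]; i2 <- planted[k, 2L]
    flip <- (x[i1, ] < x[i2, ]) != (s == 1L)
    tmp <- x[i1, flip]; x[i1, flip] <- x[i2, flip]; x[i2, flip] <- tmp
    states[k, ] <- s
  }

  stage4 <- stats::rbinom(n, 1L, config$p_stage4[ci])
  age <- stats::rbinom(n, 1L, config$p_age_ge_18m[ci])
  sex <- ifelse(stats::rbinom(n, 1L, config$p_male) == 1L,
                "male", "female")
  mycn <- stats::rbinom(n, 1L, config$p_mycn)
  mycn[stats::runif(n) < config$p_missing] <- NA

  eta <- drop(crossprod(states, config$pair_effect_betas)) +
    config$clinical_effects[["stage4"]] * stage4 +
    config$clinical_effects[["age_ge_18m"]] * age
  if (!length(eta)) eta <- numeric(n)
  rate <- config$baseline_hazard * exp(eta)
  shape <- config$weibull_shape
  # inverse-CDF draw; shape 1 reduces to the exponential
  u <- stats::runif(n)
  t_os <- (-log(u) / rate)^(1 / shape)
  t_efs <- (-log(u) / (rate * config$efs_rate_ratio))^(1 / shape)

  target <- config$censoring_rate_target
  if (target > 0) {
    cmax <- calibrate_censoring(rate, shape, target)
    cens <- stats::runif(n, 0, cmax)
  } else {
    cens <- rep(Inf, n)
  }
  os_time <- pmin(t_os, cens); os_event <- as.integer(t_os <= cens)
  efs_time <- pmin(t_efs, cens); efs_event <- as.integer(t_efs <= cens)

  clinical <- data.frame(
    sample_id = samples, sex = sex, age_ge_18m = age,
    mycn_amplified = mycn, stage4 = stage4,
    os_time = os_time, os_event = os_event,
    efs_time = efs_time, efs_event = efs_event,
    stringsAsFactors = FALSE)
  class(clinical) <- c("clinical_table", "data.frame")

  scale <- config$platform_scale_factors[ci]
  expr <- expression_matrix(x * scale,
                            units = if (ci == 1L) "FPKM" else "RPM",
                            log_scale = FALSE)
  list(expression = expr, clinical = clinical,
       truth = list(planted_pairs = data.frame(
         gene1 = planted[, 1L], gene2 = planted[, 2L],
         beta = config$pair_effect_betas,
         stringsAsFactors = FALSE),
         states = states))
}

# choose the uniform-censoring upper bound so the expected censored
# fraction over the cohort's subject-specific rates hits the target;
# P(C < T | rate, cmax) has closed form for the exponential and is
# integrated numerically for general Weibull shape
calibrate_censoring <- function(rate, shape, target) {
  p_cens <- function(cmax) {
    if (shape == 1) {
      mean((1 - exp(-rate * cmax)) / (rate * cmax))
    } else {
      mean(vapply(rate, function(r) {
        stats::integrate(function(c) exp(-r * c^shape) / cmax,
                         0, cmax)$value
      }, 0))
    }
  }
  f <- function(log_cmax) p_cens(exp(log_cmax)) - target
  root <- stats::uniroot(f, lower = log(1e-4), upper = log(1e6),
                         extendInt = "yes")
  exp(root$root)
}

#' Generate the paired training/validation cohorts
#'
#' Two cohorts sharing gene identities and the planted-pair hazard
#' mechanism but differing in size, clinical mix and global abundance
#' scale (FPKM-like versus RPM-like), emulating a cross-platform
#' training/validation design. The ground truth (planted pairs, betas,
#' latent states) is returned alongside.
#'
#' @param config a [sim_config()].
#' @return list with `cohort1`, `cohort2` (each as returned by
#'   [generate_cohort()]) and `truth` (the shared planted-pair table
#'   plus per-cohort latent states).
#' @export
generate_two_cohorts <- function(config) {
  c1 <- generate_cohort(config, 1L)
  c2 <- generate_cohort(config, 2L)
  list(cohort1 = c1, cohort2 = c2,
       truth = list(planted_pairs = c1$truth$planted_pairs,
                    states = list(cohort1 = c1$truth$states,
                                  cohort2 = c2$truth$states)))
}
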