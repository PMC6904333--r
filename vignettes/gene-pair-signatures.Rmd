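---
title: "Gene-pair prognostic signatures: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-pair prognostic signatures: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairsig)
```

## The model

`pairsig` builds prognostic indices from *within-sample gene-pair order
indicators*. For a pair of genes $(g_1, g_2)$ and a sample with
abundances $e_1, e_2$, the pair feature is

$$ s(g_1, g_2) = \mathbf{1}\{\, e_1 < e_2 \,\}, $$

with ties scoring 0. Because the comparison happens entirely inside one
sample, $s$ is invariant under any strictly increasing per-sample
transform of the expression values: global scaling between abundance
units (FPKM vs RPM), log transforms, or monotone platform effects all
leave every indicator — and everything built from it — bitwise
unchanged. This is the property that lets a signature trained on one
platform be applied verbatim, sample by sample, on another, with no
cohort-level normalization step.

The RNA-seq prognostic index of a sample is the linear combination

$$ \mathrm{RPI} = \sum_k \beta_k \, s_k, $$

where the $\beta_k$ are Cox regression coefficients and the $s_k$ are
the signature's pair indicators evaluated in the pair's *stored* gene
order (coefficients are order-dependent, so pairs are never
re-canonicalized at scoring time). Samples with
$\mathrm{RPI} > \text{cutoff}$ are called high risk; exact ties fall to
the low-risk group. The package ships the published ten-pair
neuroblastoma overall-survival signature with its fixed cutoff of
−4.774 (`published_signature()`).

The clinically adjusted composite (RCPI) combines the continuous RPI
with a clinical covariate — the binary stage-4 indicator — using joint
Cox coefficients as weights:
$\mathrm{RCPI} = w_1 \cdot \mathrm{stage4} + w_2 \cdot \mathrm{RPI}$
(the published weights are 1.8445 and 1.0563). Unlike the RPI cutoff,
the RCPI cutoff is by construction the *median of the cohort it is
applied to* and is recomputed at application time.

## The training pipeline

`rpi()` runs the stages in order and logs a count after each one:

1. **Candidate nomination** (optional upstream): `select_degs()`
   contrasts two groups on log2 expression with per-gene Welch t-tests
   and thresholds $p \le 0.05$, $|\log_2 FC| \ge 1$. We use Welch's
   t-test rather than a moderated (empirical-Bayes) statistic: the
   screen's only job is nominating candidates, and a self-contained
   unequal-variance test keeps the stage free of hyperparameters. This
   is a deliberate simplification; with very few samples per group a
   moderated test would be more powerful. An optional per-gene
   univariate Cox pre-filter (`prefilter_p`) can further narrow
   candidates before pairing; whether such a gene-level survival filter
   composes with the pair-level screen is genuinely open, so both
   stages exist separately and the pre-filter defaults to off.
2. **Pair construction**: all $\binom{k}{2}$ unordered candidate pairs
   in lexicographic orientation (`build_pair_matrix()`).
3. **Constancy filter**: pairs whose indicator is all-0 or all-1 in
   *any* participating dataset are dropped (`filter_constant_pairs()`).
   Constancy is strict, not a minority-frequency threshold. Which
   datasets participate is the caller's choice (`filter_datasets`);
   by default only the training cohort, since validation data may not
   exist at training time.
4. **Prognostic screen**: each remaining pair defines two groups
   (indicator 0 vs 1); a log-rank test per pair, followed by
   familywise-error adjustment, keeps pairs with adjusted $p <$ 0.05.
   Holm's step-down is the default adjustment — it controls the FWER
   at the same level as Bonferroni and is uniformly more powerful;
   Bonferroni is available. Screening uses the log-rank test, not a
   per-pair Cox p-value.
5. **Penalized fit**: lasso Cox on the screened pair indicators
   (`penalized_cox()`), penalty chosen by 10-fold cross-validated
   partial-likelihood deviance at the 1-SE rule. Folds are assigned by
   a seeded shuffle stratified on the event indicator so no fold is
   event-free at small n. Pair indicators already live on a common
   {0,1} scale, so features are *not* standardized — standardizing
   indicators would re-weight the penalty by prevalence. The grid has
   100 log-spaced penalties down to 1% of $\lambda_{max}$, the common
   penalized-regression default. When the conservative 1-SE solution
   is empty — which happens at desk-scale n — training falls back to
   the deviance-minimizing penalty with a warning rather than abort.
6. **Cutoff**: either from the time-dependent ROC curve (default;
   the cutoff is then a fixed number that travels with the signature)
   or the training-cohort median. The source method reports both an
   ROC-derived cutoff and a median rule for the same index without
   resolving the difference; we surface both as `cutoff_method` and
   default to `"roc"`, whose fixed numeric cutoff is what makes
   validation re-estimation-free.

`validate_rpi()` applies the *fixed* signature and *fixed* cutoff to a
new cohort — nothing is re-estimated. Only the RCPI recomputes its
median cutoff per cohort, and that distinction is enforced by
`cutoff_method`.

## Survival machinery and numerical conventions

Kaplan-Meier curves, log-rank tests and Cox models are delegated to the
`survival` package; the penalized path to `glmnet`. Conventions that
matter:

* **Breslow ties everywhere.** The unpenalized fits use
  `ties = "breslow"` so that the penalized and unpenalized estimates
  are maximizing the same partial likelihood — the test suite checks
  that the path at $\lambda \to 0$ agrees with the unpenalized fit to
  $10^{-4}$ and that Karush-Kuhn-Tucker residuals stay below $10^{-5}$
  along the path (coordinate-descent threshold $10^{-12}$).
* **Events precede censorings at tied times** (the standard
  product-limit convention).
* **Medians** are reported as `NA` ("not reached") when the curve never
  drops to 0.5.
* $\lambda_{max}$ is computed analytically as the max-norm of the
  null-model Breslow score divided by $n$, and the grid is passed to
  the optimizer explicitly so the path is never truncated early.
* Hazard ratios are reported in both orientations (high vs low and
  low vs high) with 95% Wald intervals.
* Complete separation or non-convergence in an unpenalized fit is an
  error that advises penalization, not a silent huge coefficient.

## Time-dependent ROC

`td_roc()` implements the cumulative-case/dynamic-control ROC at a
horizon $t$ under right censoring with the nearest-neighbor estimator
of the bivariate (marker, survival) distribution: conditional survival
$S(t \mid \text{marker})$ is a product-limit estimate over the
symmetric window containing the fraction $2 \cdot \mathrm{span}$ of the
sample on the marker-percentile scale. The default
$\mathrm{span} = 0.25\, n^{-0.2}$ follows the reference implementation
of the method, which cites it without parameters. Raw NNE curves can be
locally non-monotone, so the TPR is made monotone by cumulative maximum
over decreasing thresholds before trapezoidal integration. Only marker
ranks enter, hence AUC is exactly invariant under increasing marker
transforms. The cutoff criterion is the Youden index; ties break toward
the smaller threshold (the larger high-risk group), and the returned
cutoff is the midpoint to the next larger observed marker value. The
default cutoff-selection horizon is 60 months, the headline horizon of
the 12/36/60-month evaluation grid; it is configurable.

## Clinical screening and the composite

`univariate_screen()` mirrors the conventional screening table:
log-rank p-values for categorical variables, single-covariate Cox HRs
with 95% CIs, with the RPI entered as its dichotomized group.
`multivariate_fit()` is the joint Cox fit with listwise deletion.
`stepwise_select()` is deterministic forward selection (smallest Wald
p below 0.15 enters) with backward pruning (terms above 0.05 leave,
worst first; a pruned term may not re-enter, which guarantees
termination). The 0.15/0.05 thresholds follow the usual convention of
stepwise Cox routines. In `rcpi()` the RPI enters as its *continuous*
score — a single printed weight implies a single degree of freedom —
while the screen uses the dichotomized group; stage enters as the
binary stage-4 indicator for the same reason.

## What the synthetic generator emulates — and what it does not

`generate_two_cohorts()` produces the two-cohort design every
validation in this package runs on: shared gene panel, a planted
gene-pair hazard mechanism, different sample sizes, a skewed clinical
mix, and a global abundance scale factor emulating FPKM- versus
RPM-profiled platforms.

The planted signal is placed *directly on the order relation*: a latent
Bernoulli state per sample decides which gene of a planted pair is
higher (values are swapped when needed), and survival is drawn with
hazard $\lambda_0 \exp(\sum_k \beta_k s_k + \text{clinical effects})$.
This makes the pair indicator the exact hazard driver, so screening
power and Cox recovery are analytically tractable, at the cost of
realism: real pair signals arise from additive expression shifts and
are noisier. Censoring is uniform on $(0, c_{max})$ with $c_{max}$
calibrated (closed form for the exponential baseline, numerically for
Weibull shapes $\ne 1$) so the expected censored fraction hits the
target. The baseline is exponential by default because it admits
closed-form checks (Kolmogorov-Smirnov against the analytic survival
function, KM and Cox recovery); a Weibull shape is exposed as an
option.

Default study conditions, chosen once for clinical plausibility:
cohorts of 150 and 250; 40 genes with 3 planted pairs at per-indicator
HR 3 and 50% prevalence; baseline hazard 0.003/month; 30% censoring;
stage-4 and age log-HRs of log 2 and log 1.5; stage-4 and older-age
fractions 0.8 versus 0.4 across cohorts (a high-risk training registry
versus a broader validation series); scale factors 1 and 10. Under
these conditions the high-risk stratum has median survival around
20–30 months while low-risk medians lie beyond follow-up — the pattern
seen in high-risk pediatric cohorts — and events occur well before all
of the 12/36/60-month evaluation horizons.

What the generator does **not** model: negative-binomial count noise,
library-size variation, batch effects beyond global scaling, gene-gene
correlation outside the planted pairs, informative censoring, or
competing risks. Passing the end-to-end tests therefore demonstrates
that the pipeline recovers rank-level signal planted under its own
assumptions and transfers it across monotone platform differences — it
does not certify performance on real RNA-seq noise.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen to finish in minutes:
log-rank calibration uses 1000 replicates of two exponential groups of
100; the screen's familywise-error check uses 100 replicates of a
50-pair global null at n = 100; the null-AUC check uses 100 replicates
at n = 500; screen power uses 30 replicates of a single planted HR-3
pair at n = 300; Cox recovery uses one n = 2000 draw; and the
end-to-end transfer check trains and validates on 50 replicate cohort
pairs at the default conditions above.

## Known limitations

* Identifiers are opaque strings; alias resolution and probe
  annotation are out of scope, so the published signature requires the
  exact gene symbols it was defined with.
* The DEG stage assumes log2-scale input and at least two samples per
  group; it applies no multiplicity correction by design.
* The NNE ROC estimator needs events before the horizon and a span
  below 0.5; very small strata are skipped in subgroup analysis rather
  than estimated.
* Stepwise selection explores a single deterministic path; it is a
  reproduction of the conventional routine, not a model-averaging
  procedure.
* The lasso path asserts sparsity monotonicity only at its endpoints;
  coordinate-descent discreteness can transiently add or drop a
  feature mid-path.
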