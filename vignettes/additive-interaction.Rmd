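---
title: "Estimating additive-scale interaction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating additive-scale interaction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(addint)
```

## The problem and the measures

When two binary exposures A and B act on disease risk, "interaction" can be
judged on two scales. Exponential models (logistic, Cox) naturally test
departure from *multiplicativity* via a product term, but for public-health
questions the *additive* scale is usually the relevant one: does the joint
effect exceed the sum of the individual effects? With `RR10`, `RR01`, `RR11`
the relative risks of the singly and doubly exposed categories against the
doubly unexposed reference, the three standard measures are

* `RERI = RR11 - RR10 - RR01 + 1` (relative excess risk due to interaction),
* `AP = RERI / RR11` (attributable proportion due to interaction),
* `S = (RR11 - 1) / (RR10 + RR01 - 2)` (synergy index).

Under exact additivity `RERI = AP = 0` and `S = 1`. In case-control data the
relative risks are replaced by odds ratios (rare-disease approximation),
estimated from the dummy-coded logistic model

`logit p = b0 + b1 I(A1B0) + b2 I(A0B1) + b3 I(A1B1) + X'g`,

so `OR10 = exp(b1)`, `OR01 = exp(b2)`, `OR11 = exp(b3)`. The product-term
parameterisation (`A`, `B`, `AB`) is saturated over the same four categories
and maps bijectively onto the dummy coding; `measures_from_coef()` accepts
both but converts to dummy coding immediately, so all downstream code sees a
single coding.

`S` is only meaningful when both factors are (re)coded as risk factors; at
points where `RR11 <= 1` or `RR10 + RR01 <= 2` the package returns a tagged
`NA` with a reason, rather than raising. This matters downstream: bootstrap
and posterior draws routinely wander outside the domain in finite samples,
and the right behaviour is to count and report those draws, not to abort.

## Fitting

`addint()` is the central fitting function. For a 2x4 table (all cells
positive) the saturated MLE has a closed form — log cross-product ratios with
`Var(b_j) = 1/cases_j + 1/controls_j + 1/cases_0 + 1/controls_0` and
`Cov(b_j, b_k) = 1/cases_0 + 1/controls_0` — which equals the iteratively
reweighted least squares fit on the expanded subjects (the test suite checks
this equivalence exactly). With confounders the model is fit by `glm()`
(IRLS, covariance from the inverse Fisher information), and the
`(b1, b2, b3)` covariance sub-block is read off the full-model inverse —
marginalising the confounders by matrix inversion, not by refitting.

```{r}
example <- addint(oral_cancer())
example
```

## Interval procedures

**Delta method.** A first-order Taylor expansion propagates the coefficient
covariance to `Z` in `{RERI, AP, ln S}`, giving the Wald interval
`Z +/- z * sqrt(g' Sigma g)`. The analytic gradients (in `?delta_interval`)
are verified in the tests against central finite differences to a relative
error below 1e-6. For `S` the interval is built on the log scale and
exponentiated. We use the exact normal quantile (1.959964 at 95%) rather
than the conventional rounded 1.96; at two printed decimals the results are
unaffected.

**Stratified bootstrap.** Resampling is done with replacement separately
within cases and within controls, as the case-control design fixes both
margins; without confounders this is equivalent to multinomial resampling of
the eight cell counts, and the whole distribution of B = 1000 refits is
vectorised through the closed form. Three constructions are offered:
percentile `(Z*_{a/2}, Z*_{1-a/2})`, basic `(2Z - Z*_{1-a/2}, 2Z - Z*_{a/2})`
and normal `Z +/- z * sd(draws)`. Quantiles throughout the package are
*type-1 order statistics* (index `ceiling(n q)`): a fixed, documented
convention that makes runs bit-reproducible and lets the basic interval
satisfy its algebraic identity exactly.

A resample with an empty cell has no finite saturated MLE. Such draws are
refit by IRLS, whose coefficients run toward the boundary until the
convergence tolerance halts them; the resulting enormous odds ratios are
*retained* in the order statistics. This is deliberate: with sparse tables
(the oral-cancer reference cell holds 3 cases) roughly 5% of resamples are
degenerate, and retaining them is precisely what produces the notorious
10^6-scale percentile upper limits for RERI. The count of degenerate
resamples is reported in the diagnostics, never silently dropped.

**Bayesian posterior.** The coefficients get independent `N(0, 10^2)`
priors — proper but diffuse, so the likelihood dominates at these sample
sizes — and the posterior is sampled by random-walk Metropolis: Gaussian
proposals with covariance `(2.38^2 / d) * Sigma_MLE` (the classic optimal
scaling; acceptance rates land near 0.3), chain 1 started at the MLE and
later chains at overdispersed jitter (2x the proposal sd), defaults of 2
chains x 20,000 iterations with 10,000 burn-in, no thinning. Convergence is
monitored by the Gelman-Rubin potential scale reduction factor with a 1.1
warning threshold. Each retained draw is mapped through the measure
formulas; the point estimate is the posterior median (the posterior mean is
kept in the diagnostics) and the interval is equal-tailed, with an optional
shortest-interval (HPD) variant. Draws where `S` is undefined are excluded
from `S`'s order statistics with the fraction reported; above 50% the
summary is flagged unreliable.

The sampler is validated in the test suite against an exact quadrature
oracle: given the intercept, the per-category logits are conditionally
independent, so posterior means for a 2x4 table can be computed by nested
1-D quadrature with no MCMC at all. Posterior medians and credible limits
for skewed functionals such as `S` carry visible Monte Carlo error in the
far tails even at 20,000 draws, and published credible intervals for the
classic oral-cancer example differ across reports for exactly this reason;
this package's summaries agree with the quadrature oracle.

## Preventive factors

The measures assume all non-reference categories carry at least the
reference risk. If a factor is preventive, the lowest-risk joint category is
made the reference: subtracting the minimal category coefficient from all
four is algebraically identical to refitting with recoded factors
(`A* = 1 - A` and/or `B* = 1 - B`), which the tests confirm exactly for the
saturated model. Ties for the minimum prefer the original reference, then
the fixed category order — a deterministic tie-break. For the frequentist
methods `addint(..., recode = TRUE)` refits once on the recoded data (so the
covariance also refers to the new reference); for the Bayesian method the
recode is applied *per posterior draw*, keeping every draw a coherent
parameter state, and is the identity whenever the draw's coefficients are
all positive.

## The simulation harness

`builtin_scenarios()` defines 20 odds-ratio settings (blocks A-D crossed
with five `OR11` values spanning strong synergy to strong antagonism), with
joint exposure probabilities fixed at `(0.6, 0.1, 0.2, 0.1)` for
`(A0B0, A1B0, A0B1, A1B1)` and a default balanced design of 300 cases and
300 controls (the unbalanced variant uses 200/400, keeping n = 600).

Without a confounder, `draw_sample()` draws controls' exposure multinomially
from `q` and cases' from `p ∝ q * OR` — the standard case-control
construction, under which the scenario ORs are exactly the population
exposure odds ratios and control frequencies are exactly `q`. With a
confounder, a source cohort is generated (exposure `~ q`, X standard normal
independent of exposure, `gamma = 0.5`, intercept solved by `uniroot()` +
`integrate()` so the expected case fraction matches the design) and cases
and controls are sampled from it. Because X is independent of exposure it is
strictly a covariate, not a true confounder — a deliberate, documented
simplification; correlated-confounder designs are future work.

`run_coverage_study()` tallies, per scenario x measure x method: the median
point estimate, coverage, left miscoverage (lower limit above the truth),
right miscoverage (upper limit below the truth), a target-range flag, and
deviation ranks of `|coverage - 95|` with ties averaged. The target range is
parameterised by the replicate count as
`95 +/- 1.96 sqrt(0.95 * 0.05 / reps) * 100` (93.6-96.4 at 1,000
replicates). Left/right are defined strictly as above; note that symmetric
delta intervals, whose width grows with `OR11`, necessarily miss a strongly
positive RERI from *below* (upper < truth) far more often than from above —
the miscoverage under synergy is extremely one-sided. Per-replicate seeds
are drawn once per scenario from `set.seed(master + scenario index)`, so any
replicate is reproducible in isolation; fit failures are counted and the
replicate excluded for the affected cell rather than aborting the run.

## Problem sizes and numerical choices

* Default study conditions: n = 600 (300/300), 1,000 replicates per
  scenario, B = 1,000 bootstrap resamples, 2 x 20,000 MCMC iterations with
  10,000 burn-in. The packaged test suite and acceptance script run the
  Bayesian coverage benchmark at 300 replicates with single chains of
  10,000 iterations (5,000 burn-in) — chosen as the smallest sizes at which
  the binomial Monte Carlo error still makes the comparison meaningful — and
  the delta coverage benchmark at the full 1,000 replicates.
* IRLS: `glm.control(epsilon = 1e-10, maxit = 100)`; saturated tables use
  the closed form. Zero cells error by default; an explicit 0.5 continuity
  correction is available and announces itself.
* All quantiles are type-1 order statistics; the index computation carries a
  1e-9 slack so that `1000 * 0.025` does not round up through floating
  point.
* Every stochastic entry point (`bootstrap_draws()`, `sample_posterior()`,
  `draw_sample()`, `run_coverage_study()`) *requires* a seed — there are no
  hidden defaults, and fixed seeds make full pipelines bit-reproducible.

## What the generator does and does not emulate

The synthetic scenarios emulate categorical exposure data with known
population ORs, fixed design margins and an optional independent normal
covariate. They do not emulate misclassification, correlated confounding,
continuous exposures, or cohort/survival sampling. Passing coverage tests
under these conditions demonstrates calibration of the interval procedures
for the sampling designs stated above, not robustness to model
misspecification.

## Known limitations

* The rare-disease OR-for-RR substitution is inherited from the case-control
  design; the measures are reported on the OR scale.
* Exact (conditional) logistic regression, Firth correction, BCa/studentised
  bootstrap and Hamiltonian samplers are out of scope.
* The delta interval for `S` requires the point estimate inside `S`'s
  domain; near the boundary the log-scale interval is unstable, which is one
  of the motivations for the bootstrap and Bayesian alternatives.
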