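---
title: "Multistate survival models with an unobservable pre-return state"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate survival models with an unobservable pre-return state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscmr)
```

## The problem and the model

Colonially breeding seabirds tagged as chicks disappear from the colony for
several years before returning to breed.  A detection system at the colony
entrance (here: a PIT-tag gateway, as in the macaroni penguin colony study
this package is built around) therefore sees two very different kinds of
animal: adults, which attend the colony annually and are detectable every
season, and juveniles, which are alive but *unobservable* until their first
return.  Treating the missing juvenile years as ordinary non-detections
badly confounds survival and detection.

`mscmr` implements the standard remedy: a multistate
capture--mark--recapture model with three latent states,

* **pre-return** (state 1): alive, never yet returned; detection
  probability is structurally zero;
* **returned** (state 2): alive and attending annually; detected at
  occasion $t$ with probability $p_t$;
* **dead**: absorbing.

Fledgling-marked animals start in state 1 at tagging, adult-marked animals
in state 2.  Over the interval from occasion $t$ to $t+1$ an animal first
survives with probability $\phi$, then (if in state 1) returns for the
first time at arrival age $a$ with probability $\psi_a$; detection happens
on arrival.  The reverse transition is fixed at zero and $\psi_a \equiv 1$
above a maximum age (3--5 years), so a surviving bird is certainly back by
then.  The likelihood of an encounter history, conditional on marking, is
computed by an exact forward recursion over the three states; a
brute-force enumeration over all latent state paths ships as a testing
oracle, and with only adult-marked animals the model collapses to the
classical Cormack--Jolly--Seber likelihood (verified in the test suite
against an independent closed-form oracle at $10^{-6}$).

Survival is modelled on the logit scale as an age-class-specific linear
function of covariates:

$$\mathrm{logit}\,\phi_{i,t} = \mu_{c(i,t)} + \text{(year terms)} +
  \beta_{\mathrm{mass}} z_i \,[c=1] + \textstyle\sum_j \beta_j z_{j,t},$$

with age classes `a1` (none), `a2` (fledging year vs older) or `a3`
(fledging year, second year, older); adult-marked animals, of unknown age,
always occupy the oldest class.  Year effects can be shared across classes
(additive, `a+t`) or class-specific (interactive, `a*t`).  Individual
fledging mass enters only the fledging-year class.  First-return
probabilities are free per age or follow 2-parameter linear or log-age
trends on the logit scale (the logit keeps trend-implied probabilities in
the unit interval for any coefficients, which a probability-scale trend
would not).  Detection is per-year, constant, or grouped by gateway effort:
0 days of reader operation (`not_working`), 1--100 days (`intermittent`),
more than 100 days (`working_well`).

## Covariate standardization

Every covariate enters as a z-score, $(x - \bar x)/s$ with the sample
standard deviation, so logit-scale coefficients are directly comparable
effect sizes per SD.  Annual covariates are standardized over the survival
intervals they act on (occasions $1..T-1$); individual fledging mass is
standardized against the pooled mass distribution of all retained
fledglings across cohorts, not per cohort, so within- and between-year
contrasts stay on one scale.  `destandardize_slope()` converts a per-SD
slope back to natural units.  Fledglings lacking a mass measurement cannot
contribute to mass models and are removed up front by
`filter_missing_mass()` (the field study removed 11 such birds).

## Estimation and its numerical choices

`fit_model()` maximizes the exact likelihood with BFGS from jittered
starting points (5 by default; simulation studies in this package use 1--2
because the surface is well behaved at these sample sizes), followed by a
restart of BFGS at the optimum and one guarded Newton step using the
numerically differenced Hessian.  The coefficient covariance is the
inverse Hessian.  Convergence requires the optimizer to report success, a
positive-definite Hessian, and a gradient norm below
`tol * (1 + |loglik|)` with `tol = 1e-3`; with finite-difference gradients
the objective carries noise of order $10^{-9}$, so demanding much smaller
raw gradients would reject perfectly converged fits.  Deviance is defined
as $-2\log L$ without a saturated-model reference: every statistic used
downstream (ΔAICc, LRT, ANODEV, $R^2_{\mathrm{DEV}}$) depends only on
deviance *differences* between models on the same data, which are
invariant to that choice.

The effective sample size for AICc is the number of encounter histories;
with individual covariates each animal is the natural unit, and the choice
only moves the small-sample correction term.

## Model selection

Candidates are ranked by AICc, or QAICc after overdispersion adjustment
(`information_criteria()`, `rank_models()`): models within 2 criterion
units of the best are treated as equally supported and the one with fewest
parameters wins; exact ties break by label order so rankings are
deterministic.

**Median c-hat.**  Goodness of fit of the global model is assessed by the
simulation-based median-$\hat c$ protocol: datasets are simulated from the
fitted model at a grid of true overdispersion values spanning bounds
$[1, 4]$ (7 grid points, 100 replicates by default; a result above 3 flags
lack of fit), each replicate is refitted, and a logistic regression of
"simulated statistic exceeds observed statistic" on true $c$ locates the
crossing at probability one half.  Overdispersion is *induced* by
fate-sharing clusters: animals within a tagging cohort share the uniform
draws behind their survival and first-return transitions (comonotone
coupling, so marginal rates are untouched), with non-integer $c$ realized
as a mixture of adjacent integer cluster sizes; a cluster size of $c$
inflates the variance of cohort fate counts by about $c$.  The per-fit
statistic is a Pearson dispersion: for every tagging cohort and later
occasion, the observed detection count is compared with its exact mean and
variance under the fitted model's marginal state distribution, and the
statistic is the mean of $(O-E)^2/V$ over cells.  A deviance-per-animal
statistic cannot serve here: duplicating every animal doubles both the
deviance and the sample size, leaving it unchanged, so it is blind to
exactly the correlation structure $\hat c$ must detect.  The Pearson
statistic scales with the variance-inflation factor by construction, and
the calibration tests (cluster size 1 vs 2) check the resulting estimator
end to end.  `inflate_by_chat()` then scales coefficient covariances by
$\hat c$ and QAICc divides the deviance by it (counting one extra
parameter).

**Step-up covariate selection.**  Following the field protocol,
`step_up_selection()` starts from the time-constant base model; tests
individual fledging mass in isolation with a likelihood-ratio test
(retained at $p < 0.05$); then, at each step, fits every remaining annual
covariate on top of the current model — additively or interactively with
age class, the better entry chosen by QAICc, or forced by configuration
when a term is kept on extra-statistical grounds — and computes ANODEV
against the current model as the "constant" reference and a full-year
model as the temporal reference:

$$R^2_{\mathrm{DEV}} =
  \frac{\mathrm{DEV}(.) - \mathrm{DEV}(\mathrm{cov})}
       {\mathrm{DEV}(.) - \mathrm{DEV}(t)}.$$

The candidate with the largest $R^2_{\mathrm{DEV}}$ is retained if it
exceeds 0.20 (the conventional "explains a fifth of the remaining temporal
deviance" rule; the ANODEV $p$ is reported as a diagnostic rather than the
gate, matching protocols that proceed at $p \approx 0.08$ when
$R^2 = 0.20$); otherwise the procedure stops.  Two numerical details
matter.  First, the temporal reference carries per-class (interactive)
year effects whenever interactive covariate entry is allowed: an
additive-year reference does not nest a class-specific covariate slope,
and a non-nesting reference can push $R^2_{\mathrm{DEV}}$ above 1.
Second, every nested fit is warm-started from the current model's
coefficients (matched by name, new coefficients at zero), which guarantees
the fitted deviance can only fall as terms are added — cold starts
occasionally left a larger model at a worse optimum, producing negative
test statistics.  Retained coefficients are finally verified through their
Wald confidence intervals on the logit scale under the
$\hat c$-inflated covariance (`verify_coefficient()`).

## Derived quantities

* `cumulative_first_return()`: $C(a) = 1 - \prod_{i \le a}(1 - \psi_i)$,
  reaching 1 one age past the maximum.
* `annual_survival()` extracts per-year survival for one age class from a
  year-effects model at covariate means, with delta-method variances; an
  estimate whose logit-scale SE exceeds 3 is flagged non-identifiable and
  excluded from variance components (the field analysis likewise dropped
  one fledgling cohort with an uninformative interval; the SE threshold is
  a package constant since the original criterion was not numeric).
* `variance_components()` separates temporal process variance from
  sampling variance with the intercept-only random-effects moment
  estimator: solve $\sum_t w_t(\theta_t-\hat\mu)^2 = T-1$ with
  $w_t = 1/(\sigma^2 + v_t)$, truncating at $\sigma^2 = 0$; only the
  diagonal of the sampling covariance is used.
* `sensitivity()`: the partial derivative of survival with respect to a
  covariate under the logit link, $S = \beta\,\phi(1-\phi)$, evaluated at
  standardized-covariate zero (covariate means) and reported per SD of the
  covariate — the means are the conventional evaluation point and per-SD
  units keep sensitivities comparable across covariates.  The identity is
  cross-checked against finite differences of `predict_survival()`.
* `mass_year_anova()`: one-way fixed-effects ANOVA of fledging mass across
  cohort years.

## The synthetic-data generator

No field data ship with the package; `simulate_dataset()` generates
datasets from exactly the process the likelihood assumes, with a full
`truth` record (generating coefficients on the fitted parameterization,
realized parameters, latent state paths), so every stage is testable by
parameter recovery.  Defaults emulate the penguin study's published scale:
10 annual occasions; seven fledgling cohorts of 150 chicks plus 100 adults
tagged per year (approximating the reported totals of 1070 fledglings and
966 adults; the per-cohort table was not published); fledging-year
survival 0.33 and older survival 0.89; detection 0.99/0.88/0.15 by
gateway effort level, with one season down and one intermittent; first
return at ages 1--3 with $\psi = (0.10, 0.50, 0.756)$, giving 10% back by
age 1 and 89% cumulatively by age 3; mean fledging mass 3.28 kg with a
0.30 kg within-cohort SD and 0.15 kg between-cohort SD (within-cohort
spread was not published; these give mass ANOVA F statistics of the
published order).  Default covariate effects are back-calculated from the
published per-SD sensitivities through $\beta = S/[\phi(1-\phi)]$:
predation $(-0.68, -0.20)$ interactive with age class, mass $+0.41$
(fledging year), local SST anomaly $+0.14$ additive — so the generated
world reproduces the published importance ordering (predation > mass >
environment for fledglings).  Annual covariates are drawn independently
(predation as a rounded truncated normal count, mean 25, SD 8; anomalies
and climate indices as zero-mean normals), and covariates enter the
generating logits as the same within-dataset z-scores the fitting code
computes, so configured slopes are exactly the estimands.  Because effects
are logit-linear, generated probabilities are automatically inside the
unit interval and no resampling guard is needed.

What the generator does *not* emulate: tag loss and tag-induced mortality,
individual heterogeneity beyond fledging mass, breeding-state structure or
within-season timing, autocorrelated environments (an option exists for
none by default), and model misspecification generally — passing recovery
tests shows the estimator is correct under its own assumptions, not that
real colonies satisfy them.  Overdispersion enters only through the
explicit fate-sharing cluster mechanism.

## Problem sizes and reproducibility

All stochastic routines take explicit seeds; the same seed reproduces
byte-identical datasets and protocol reports.  The test suite and the
acceptance script size their simulation studies to run on a single CPU in
minutes while keeping Monte-Carlo error well inside the asserted margins:
likelihood oracles on 1000 random history/parameter pairs; the CJS
reduction on 500 adults over 4 occasions; parameter recovery on 12--20
replicates of the full study scale (~2500 animals); LRT size on 200 null
replicates of a reduced 6-occasion design; step-up first-pick power on
40--50 replicates with one active covariate at $\beta = 1$ per SD;
median-$\hat c$ calibration on 10 trials of 25 replicates at a reduced
scale; variance-components recovery on 50 replicates at the published
fledgling process SD of 0.12.

## Known limitations

* Interactive-time global models on sparse data can place class-year
  cells at the boundary; `count_parameters(check_rank = TRUE)` flags
  rank-deficient designs, and boundary years are excluded from variance
  components by the SE rule rather than by a formal identifiability
  analysis.
* Parameter counts are structural (coefficients after reference coding);
  software that counts *estimable* parameters on a given dataset may
  differ for boundary fits, so printed $k$ values from other programs are
  not directly comparable.
* Wald intervals only (no profile likelihood); ESS is the animal count.
* The `.inp` dialect is deliberately minimal: 0/1 histories, a frequency
  field, one group column, one optional mass column; no multistate letter
  codes (the unobservable state is never detected, so histories are
  binary by construction) and no binary project files.
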