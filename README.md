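# mscmr — multistate mark–recapture survival with an unobservable pre-return state

`mscmr` estimates age-specific annual survival of colonially breeding
animals from individual encounter histories when juveniles defer their
first return to the colony for several years.  It was built around the
analysis design of a decade-long macaroni penguin PIT-tag study (an
automated gateway reader at the colony entrance, fledglings and adults
tagged each season) but applies to any study with that structure.

The core model is a multistate Cormack–Jolly–Seber likelihood with three
latent states — *pre-return* (alive, detection probability 0), *returned*
(alive, detectable), *dead* — conditional on marking.  Per interval, an
animal survives with probability φ, a surviving pre-return animal of age
*a* returns for the first time with probability Ψₐ (Ψ ≡ 1 above a maximum
age; the reverse transition is 0), and detection at arrival occurs with
probability *p*.  Survival is a logit-linear, age-class-specific function
of standardized covariates:

    logit φ = μ_class + year terms + β_mass·z_mass·[fledging year] + Σ β_j·z_j(t)

On top of the likelihood engine the package provides:

* maximum-likelihood fitting with Hessian-based covariances
  (`fit_model`), AICc/QAICc (`information_criteria`) and ranking with the
  Δ≤2 parsimony rule (`rank_models`);
* median-ĉ overdispersion estimation by simulate-and-refit calibration
  with fate-sharing clusters (`estimate_median_chat`, `inflate_by_chat`);
* the step-up covariate protocol: LRT for individual fledging mass,
  ANODEV with R²_DEV = [DEV(.)−DEV(cov)]/[DEV(.)−DEV(t)] and the
  20%-of-temporal-deviance retention rule for annual covariates
  (`step_up_selection`, `anodev`, `verify_coefficient`);
* derived quantities: survival predictions with delta-method intervals,
  cumulative first-return curves, temporal process variance by variance
  components, covariate sensitivities S = β·φ(1−φ), slope
  de-standardization, and the fledging-mass ANOVA;
* a fully seeded synthetic-data generator with ground-truth records
  (`simulate_dataset`), MARK-dialect `.inp` and covariate-CSV I/O
  (`read_inp`, `read_year_covariates`), and a one-call orchestration of
  the whole protocol (`run_protocol`).

## Worked example

Simulate a study at the published scale (10 seasons, seven fledgling
cohorts of 150 plus 100 adults per year, fledging-year survival 0.33,
older survival 0.89, detection 0.99/0.88/0.15 by gateway effort) and
refit the generating model:

```r
library(mscmr)

sim <- simulate_dataset(simulation_config(seed = 42,
                                          fledglings_per_cohort = 150,
                                          adults_per_year = 100))
sim$dataset
#> cmr_dataset: 1950 animals over 10 occasions (2003-2012)
#>   fledgling-marked: 1050 (1050 with mass)  adult-marked: 900

fit <- fit_model(sim$truth$structure, sim$dataset, n_restarts = 2, seed = 1)
fit
#> cmr_fit: phi(a2 mass:i pred_pressure*a lsst_lag1) p(T3) psi(3)
#>   deviance 6039.717, k = 12, n = 1950, converged: TRUE, c-hat 1
#>                      estimate     se
#> phi_int_c1            -0.6738 0.0839
#> phi_int_c2             2.0624 0.0493
#> phi_mass               0.4574 0.0813
#> phi_pred_pressure_c1  -0.4963 0.1010
#> phi_pred_pressure_c2  -0.2564 0.0541
#> phi_lsst_lag1          0.2261 0.0510
#> p_eff_working_well     4.4706 0.2138
#> p_eff_intermittent     1.6705 0.1214
#> p_eff_not_working     -1.8493 0.1421
#> psi_a1                -2.0425 0.1750
#> psi_a2                -0.0793 0.1338
#> psi_a3                 0.9275 0.2520
```

The intercepts back-transform to fledging-year survival
`plogis(-0.674) = 0.34` and older survival `plogis(2.06) = 0.89`,
recovering the generating truths (0.33 / 0.89); the mass, predation and
SST slopes (per SD, logit scale) likewise bracket their generating values
(0.41, −0.68/−0.20, 0.14).  Predicted fledging-year survival at covariate
means, the cumulative first-return curve, and per-SD sensitivities:

```r
predict_survival(fit, age_class = 1)
#> $phi 0.338, 95% CI (0.302, 0.375)

psi <- realize_parameters(fit$beta_hat, fit$design)$psi
round(cumulative_first_return(psi[1:3]), 3)
#> [1] 0.115 0.540 0.870 1.000     # ~11% back by age 1, all by age 4

sensitivity_table(fit)
#>   age_class     covariate           S
#> 1         1          mass  0.10230164
#> 2         1 pred_pressure -0.11098739
#> 3         1     lsst_lag1  0.05056967
#> 4         2 pred_pressure -0.02565910
#> 5         2     lsst_lag1  0.02263065
```

Fledging-year survival is most sensitive to predation pressure, then
individual mass, then the environment, and the older class responds much
more weakly — the qualitative pattern the generator encodes.
`run_protocol()` chains the full analysis (global fit → median-ĉ →
structural selection → step-up covariates → CI verification → derived
quantities) into one reproducible JSON-serializable report.

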