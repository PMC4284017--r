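# Experiment drivers used by the acceptance suite.

# ---- independent CJS oracle (closed-form likelihood + grid refinement) ----
# For all-adult data with constant survival and detection, the classical
# CJS likelihood factorizes per animal as
#   phi^(L-m) p^d (1-p)^((L-m)-d) chi(T-L)
# with L the last detection, d the number of post-marking detections and
# chi the never-seen-again probability, chi(0)=1,
# chi(j) = (1-phi) + phi (1-p) chi(j-1).  The MLE is located by iterative
# grid refinement; nothing is shared with the package's hidden-state
# recursion.
cjs_oracle_fit <- function(dataset) {
  det <- dataset$detections
  T <- ncol(det)
  m <- dataset$histories$mark_occasion
  L <- apply(det == 1L, 1, function(r) max(which(r)))
  d <- rowSums(det) - 1L
  steps <- L - m
  tail <- T - L
  nll <- function(phi, p) {
    chi <- numeric(T)
    chi[1] <- 1
    for (j in 2:T) chi[j] <- (1 - phi) + phi * (1 - p) * chi[j - 1]
    -sum(steps * log(phi) + d * log(p) + (steps - d) * log(1 - p) +
           log(chi[tail + 1L]))
  }
  lo <- c(0.01, 0.01); hi <- c(0.99, 0.99)
  centre <- c(0.5, 0.5); width <- 0.98
  for (it in 1:12) {
    g1 <- seq(max(lo[1], centre[1] - width / 2),
              min(hi[1], centre[1] + width / 2), length.out = 25)
    g2 <- seq(max(lo[2], centre[2] - width / 2),
              min(hi[2], centre[2] + width / 2), length.out = 25)
    vals <- outer(g1, g2, Vectorize(function(a, b) nll(a, b)))
    ix <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    centre <- c(g1[ix[1]], g2[ix[2]])
    width <- width * 0.3
  }
  list(phi = centre[1], p = centre[2])
}

# all-adult single-state dataset for the CJS reduction
cjs_sim <- function(n = 500L, T = 4L, phi = 0.7, p = 0.6, seed = 1L) {
  simulate_dataset(simulation_config(
    seed = seed, n_occasions = T,
    fledglings_per_cohort = 0L, fledgling_cohort_occasions = integer(),
    adults_per_year = n %/% (T - 1L), adult_occasions = seq_len(T - 1L),
    phi_mean = c(phi, phi), covariate_effects = list(),
    p_by_group = c(working_well = p, intermittent = p, not_working = p),
    gateway_days = rep(150, T)))$dataset
}

# ---- parameter recovery over replicate simulations ----------------------
recovery_experiment <- function(n_datasets = 20L, fledglings = 214L,
                                adults = 111L, seed0 = 100L,
                                n_restarts = 1L) {
  est <- se <- NULL
  truth <- NULL
  for (r in seq_len(n_datasets)) {
    sim <- simulate_dataset(simulation_config(
      seed = seed0 + r, fledglings_per_cohort = fledglings,
      adults_per_year = adults))
    fit <- fit_model(sim$truth$structure, sim$dataset,
                     n_restarts = n_restarts, seed = r)
    nm <- names(fit$beta_hat)
    if (is.null(truth)) truth <- sim$truth$beta[nm]
    est <- rbind(est, fit$beta_hat[nm])
    se <- rbind(se, sqrt(diag(fit$vcov))[nm])
  }
  bias <- colMeans(est) - truth
  mc_se <- apply(est, 2, sd) / sqrt(nrow(est))
  phi_cols <- grep("^phi_", colnames(est))
  hits <- abs(sweep(est, 2, truth)) <= qnorm(0.975) * se
  list(truth = truth, est = est, se = se,
       bias_z = bias / mc_se,
       coverage_hits = sum(hits[, phi_cols]),
       coverage_n = length(phi_cols) * nrow(est))
}

# ---- LRT type-I error under the null ------------------------------------
lrt_null_experiment <- function(n_reps = 200L, seed0 = 2000L) {
  pvals <- numeric(n_reps)
  base <- NULL
  for (r in seq_len(n_reps)) {
    sim <- simulate_dataset(simulation_config(
      seed = seed0 + r, n_occasions = 6L,
      fledglings_per_cohort = 60L, fledgling_cohort_occasions = 1:3,
      adults_per_year = 40L, adult_occasions = 1:5,
      covariate_effects = list()))
    str0 <- model_structure(survival_spec("a2"), recapture_spec("effort"),
                            transition_spec(3))
    str1 <- model_structure(
      survival_spec("a2", covariates = list(list(name = "mass",
                                                 scope = "individual"))),
      recapture_spec("effort"), transition_spec(3))
    f0 <- fit_model(str0, sim$dataset, n_restarts = 1, seed = r)
    f1 <- fit_model(str1, sim$dataset, n_restarts = 1, seed = r,
                    start = mscmr:::.warm_start(
                      build_design(str1, sim$dataset)$coef_names,
                      f0$beta_hat))
    pvals[r] <- likelihood_ratio_test(f0, f1)$p
  }
  pvals
}

# ---- step-up first-pick power under one active covariate -----------------
stepup_power_experiment <- function(n_reps = 50L, seed0 = 3000L,
                                    beta_active = 1.0) {
  first <- character(n_reps)
  for (r in seq_len(n_reps)) {
    sim <- simulate_dataset(simulation_config(
      seed = seed0 + r, fledglings_per_cohort = 50L,
      adults_per_year = 30L,
      covariate_effects = list(
        pred_pressure = list(scope = "additive", beta = beta_active))))
    base <- model_structure(survival_spec("a2"), recapture_spec("effort"),
                            transition_spec(3))
    rec <- step_up_selection(
      sim$dataset, base,
      annual_covariates = c("pred_pressure", "lsst_lag1", "sam_lag0",
                            "enso_lag2"),
      compare_entry = FALSE, max_annual_steps = 1L,
      fit_options = list(n_restarts = 1L, seed = r))
    an <- rec[rec$test == "ANODEV", ]
    first[r] <- if (nrow(an) >= 1L && an$retained[1L]) an$covariate[1L]
                else ""
  }
  first
}

# ---- median c-hat calibration trials ------------------------------------
chat_trials <- function(cluster_size, n_trials = 10L, replicates = 25L,
                        seed0 = 4000L) {
  vapply(seq_len(n_trials), function(r) {
    # a trial needs a converged global fit; redraw the replicate dataset
    # (fresh seed) on the rare boundary fit
    for (attempt in 0:3) {
      sim <- simulate_dataset(simulation_config(
        seed = seed0 + r + 17L * attempt, n_occasions = 10L,
        fledglings_per_cohort = 60L, adults_per_year = 40L,
        covariate_effects = list(), cluster_size = cluster_size))
      fit <- fit_model(sim$truth$structure, sim$dataset, n_restarts = 2,
                       seed = r + attempt)
      if (fit$converged) break
    }
    estimate_median_chat(fit, replicates = replicates, grid_points = 6L,
                         seed = seed0 + 100L * r)$c_hat
  }, numeric(1))
}

# ---- process-variance recovery -------------------------------------------
process_sd_experiment <- function(n_reps = 50L, sigma = 0.12,
                                  mean_phi = 0.33, n_years = 9L,
                                  sampling_se = 0.04, seed0 = 5000L) {
  vapply(seq_len(n_reps), function(r) {
    set.seed(seed0 + r)
    truth <- pmin(pmax(rnorm(n_years, mean_phi, sigma), 0.02), 0.98)
    obs <- truth + rnorm(n_years, 0, sampling_se)
    variance_components(obs, rep(sampling_se^2, n_years))$sigma_process
  }, numeric(1))
}
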