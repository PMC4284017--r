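test_that("simulation is reproducible and validated", {
  cfg <- simulation_config(seed = 5L, fledglings_per_cohort = 30L,
                           adults_per_year = 20L)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$dataset, s2$dataset)
  expect_identical(s1$truth$states, s2$truth$states)
  expect_no_error(validate_dataset(s1$dataset))
  # a different seed changes the data
  s3 <- simulate_dataset(simulation_config(seed = 6L,
                                           fledglings_per_cohort = 30L,
                                           adults_per_year = 20L))
  expect_false(identical(s1$dataset$detections, s3$dataset$detections))
  expect_error(simulation_config(), "seed")
})

test_that("deterministic limits produce all-ones histories", {
  eps <- 1e-9
  cfg <- simulation_config(seed = 9L, n_occasions = 6L,
                           fledglings_per_cohort = 40L,
                           adults_per_year = 20L,
                           phi_mean = c(1 - eps, 1 - eps),
                           covariate_effects = list(),
                           p_by_group = c(working_well = 1,
                                          intermittent = 1,
                                          not_working = 1),
                           psi = 1)
  sim <- simulate_dataset(cfg)
  ds <- sim$dataset
  for (i in seq_len(n_animals(ds))) {
    m <- ds$histories$mark_occasion[i]
    expect_true(all(ds$detections[i, m:ncol(ds$detections)] == 1L))
  }
})

test_that("observed survival matches the configured rate at large n", {
  cfg <- simulation_config(seed = 15L, n_occasions = 2L,
                           fledglings_per_cohort = 0L,
                           fledgling_cohort_occasions = integer(),
                           adults_per_year = 10000L, adult_occasions = 1L,
                           phi_mean = c(0.33, 0.89),
                           covariate_effects = list(),
                           p_by_group = c(working_well = 1,
                                          intermittent = 1,
                                          not_working = 1),
                           gateway_days = c(150, 150))
  sim <- simulate_dataset(cfg)
  frac <- mean(sim$dataset$detections[, 2])
  expect_lt(abs(frac - 0.89), 3 * sqrt(0.89 * 0.11 / 10000))
})

test_that("first-return ages follow the configured transition rates", {
  cfg <- simulation_config(seed = 21L, n_occasions = 6L,
                           fledglings_per_cohort = 50000L,
                           fledgling_cohort_occasions = 1L,
                           adults_per_year = 0L, adult_occasions = integer(),
                           covariate_effects = list())
  sim <- simulate_dataset(cfg)
  st <- sim$truth$states
  psi <- sim$truth$psi
  # among birds alive at age a that were still pre-return, the fraction
  # transitioning matches psi[a]
  pvals <- numeric(length(psi))
  for (a in seq_along(psi)) {
    at_risk <- st[, a] == 1L & st[, a + 1L] != 3L
    returned <- st[at_risk, a + 1L] == 2L
    pvals[a] <- binom.test(sum(returned), length(returned),
                           psi[a])$p.value
  }
  expect_true(all(pvals > 0.01))
  # and every bird alive past the maximum age has returned
  past <- st[, length(psi) + 2L]
  expect_true(all(past[past != 3L & past != 0L] == 2L))
})

test_that("fate-sharing clusters inflate cohort variance, not the mean", {
  n_rep <- 300L
  surv1 <- numeric(n_rep)
  surv2 <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    base <- list(n_occasions = 2L, fledglings_per_cohort = 0L,
                 fledgling_cohort_occasions = integer(),
                 adults_per_year = 1000L, adult_occasions = 1L,
                 phi_mean = c(0.3, 0.7), covariate_effects = list(),
                 p_by_group = c(working_well = 1, intermittent = 1,
                                not_working = 1),
                 gateway_days = c(150, 150))
    s1 <- simulate_dataset(do.call(simulation_config,
                                   c(base, cluster_size = 1, seed = 1000 + r)))
    s2 <- induce_overdispersion(do.call(simulation_config,
                                        c(base, cluster_size = 2,
                                          seed = 5000 + r)))
    surv1[r] <- sum(s1$truth$states[, 2] != 3L)
    surv2[r] <- sum(s2$truth$states[, 2] != 3L)
  }
  binom_var <- 1000 * 0.7 * 0.3
  expect_lt(abs(var(surv1) / binom_var - 1), 0.35)
  ratio <- var(surv2) / binom_var
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
  # marginal rate preserved under clustering
  expect_lt(abs(mean(surv2) - mean(surv1)), 3 * sqrt(2 * binom_var / n_rep))
})

test_that("the truth vector aligns with the fitted design", {
  sim <- small_sim(seed = 25L, fledglings = 30L, adults = 20L)
  d <- build_design(sim$truth$structure, sim$dataset)
  expect_setequal(names(sim$truth$beta), d$coef_names)
  # realized survival in the truth equals the design-mapped parameters
  pars <- realize_parameters(sim$truth$beta[d$coef_names], d)
  idx <- which(d$phi_valid, arr.ind = TRUE)
  expect_equal(pars$phi[idx], sim$truth$phi[idx], tolerance = 1e-12)
})

test_that("simulating from a fit reuses the animals and their covariates", {
  sim <- small_sim(seed = 33L, fledglings = 30L, adults = 20L,
                   covariate_effects = list())
  fit <- fit_model(sim$truth$structure, sim$dataset, n_restarts = 1,
                   seed = 1)
  ds1 <- simulate_from_fit(fit, seed = 4L)
  ds2 <- simulate_from_fit(fit, seed = 4L)
  expect_identical(ds1, ds2)
  expect_identical(ds1$histories, sim$dataset$histories)
  expect_false(identical(ds1$detections, sim$dataset$detections))
  expect_no_error(validate_dataset(ds1))
})
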