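test_that("cumulative first-return follows the product formula", {
  expect_equal(cumulative_first_return(c(1)), c(1, 1))
  psi <- c(0.1, 0.5, 0.78)
  C <- cumulative_first_return(psi)
  expect_equal(C[1], 0.1)
  expect_equal(C[3], 1 - 0.9 * 0.5 * 0.22)
  expect_equal(C[4], 1)                      # fixed-above-max rule
  expect_true(all(diff(C) >= 0))
  # matches exhaustive enumeration of first-return ages
  set.seed(3)
  psi2 <- runif(4)
  C2 <- cumulative_first_return(psi2, through_age = 5)
  pr_age <- numeric(5)
  surv <- 1
  for (a in 1:5) {
    pa <- if (a > 4) 1 else psi2[a]
    pr_age[a] <- surv * pa
    surv <- surv * (1 - pa)
  }
  expect_equal(C2, cumsum(pr_age))
})

test_that("process variance separates sampling noise from temporal signal", {
  # identical estimates: no process variance
  vc <- variance_components(rep(0.4, 6), rep(0.01, 6))
  expect_equal(vc$sigma2_process, 0)
  expect_equal(vc$mean, 0.4)
  # vanishing sampling variance: sigma2 tends to the sample variance
  set.seed(4)
  th <- rnorm(8, 0.5, 0.1)
  vc2 <- variance_components(th, rep(1e-10, 8))
  expect_equal(vc2$sigma2_process, var(th), tolerance = 1e-5)
  expect_equal(vc2$mean, mean(th), tolerance = 1e-5)
  # scale consistency: scaling deviations by sqrt(c) and sampling
  # variances by c scales sigma2 by c
  v <- runif(8, 0.001, 0.01)
  vc3 <- variance_components(th, v)
  cc <- 3.7
  th_s <- mean(th) + sqrt(cc) * (th - mean(th))
  vc4 <- variance_components(th_s, cc * v)
  expect_equal(vc4$sigma2_process, cc * vc3$sigma2_process,
               tolerance = 1e-6)
  # shrunken estimates lie between the raw values and the mean
  expect_true(all(
    (vc3$shrunken - vc3$mean) * (vc3$estimates - vc3$mean) >= -1e-12))
  expect_true(all(abs(vc3$shrunken - vc3$mean) <=
                    abs(vc3$estimates - vc3$mean) + 1e-12))
  expect_error(variance_components(c(0.1, 0.2), c(0.01, 0.01)),
               "at least 3")
})

test_that("survival predictions and sensitivities agree with the link
           arithmetic", {
  sim <- small_sim(seed = 59L, fledglings = 40L, adults = 25L)
  fit <- fit_model(sim$truth$structure, sim$dataset, n_restarts = 1,
                   seed = 1)
  # force known coefficients so expectations are exact
  fit$beta_hat[] <- 0
  fit$beta_hat["phi_int_c1"] <- 0       # phi = 0.5 at covariate means
  fit$beta_hat["phi_mass"] <- 1
  pr <- predict_survival(fit, 1)
  expect_equal(pr$phi, 0.5)
  # sensitivity at the logistic maximum
  expect_equal(sensitivity(fit, 1, "mass"), 0.25)
  # beta = 0 gives zero sensitivity
  expect_equal(sensitivity(fit, 2, "lsst_lag1"), 0)
  # +1 SD in mass shifts the logit by exactly the slope
  std <- fit$design$standardizers$mass
  pr1 <- predict_survival(fit, 1, list(mass = std$center + std$scale))
  expect_equal(pr1$eta - pr$eta, 1)
  # monotone prediction curve under a positive slope
  grid <- seq(std$center - 2 * std$scale, std$center + 2 * std$scale,
              length.out = 9)
  phis <- vapply(grid, function(m)
    predict_survival(fit, 1, list(mass = m))$phi, numeric(1))
  expect_true(all(diff(phis) > 0))
  expect_error(predict_survival(fit, 1, list(bogus = 1)), "not in the model")
  # individual covariate is undefined for the older class
  expect_error(sensitivity(fit, 2, "mass"), "fledging-year")
})

test_that("sensitivity matches finite differences of the prediction", {
  sim <- small_sim(seed = 61L, fledglings = 40L, adults = 25L)
  fit <- fit_model(sim$truth$structure, sim$dataset, n_restarts = 1,
                   seed = 1)
  std <- fit$design$standardizers$pred_pressure
  h <- 1e-4
  for (b in c(-1.2, -0.3, 0.5)) {
    fit$beta_hat["phi_pred_pressure_c1"] <- b
    S <- sensitivity(fit, 1, "pred_pressure")
    up <- predict_survival(fit, 1,
                           list(pred_pressure = std$center + h * std$scale))
    dn <- predict_survival(fit, 1,
                           list(pred_pressure = std$center - h * std$scale))
    expect_equal(S, (up$phi - dn$phi) / (2 * h), tolerance = 1e-6)
  }
})

test_that("de-standardized slopes convert to natural units", {
  s <- standardize(c(3.0, 3.25, 3.5, 3.75))
  expect_equal(destandardize_slope(0.5, list(scale = 0.25)), 2.0)
  expect_equal(destandardize_slope(1, list(scale = 1)), 1)
  b <- destandardize_slope(0.7, s)
  expect_equal(b * s$scale, 0.7, tolerance = 1e-12)
  expect_error(destandardize_slope(1, list(scale = 0)), "scale")
})

test_that("annual survival extraction flags unidentifiable years", {
  sim <- small_sim(seed = 67L, fledglings = 60L, adults = 40L,
                   covariate_effects = list(), year_sigma = 0.3)
  str <- model_structure(survival_spec("a2", "additive"),
                         recapture_spec("effort"), transition_spec(3))
  fit <- fit_model(str, sim$dataset, n_restarts = 1, seed = 1)
  ann <- annual_survival(fit, 2)
  expect_true(all(ann$estimate > 0 & ann$estimate < 1))
  expect_true(all(ann$var >= 0))
  expect_equal(ann$usable, ann$se_logit <= 3)
})

test_that("the mass ANOVA reproduces textbook structure", {
  set.seed(71)
  # identical cohort means: F near zero in expectation, p large
  m0 <- rep(c(3.2, 3.3, 3.4), times = 4)
  a0 <- mass_year_anova(m0, rep(1:4, each = 3))
  expect_equal(a0$F, 0, tolerance = 1e-10)
  # df structure for 8 cohorts of 822 birds
  cohort <- rep(1:8, length.out = 822)
  mass <- rnorm(822, 3.28 + 0.1 * (cohort %in% c(2, 5)), 0.3)
  a <- mass_year_anova(mass, cohort)
  expect_equal(a$df_between, 7L)
  expect_equal(a$df_within, 814L)
  # two cohorts: F equals the squared pooled-variance t statistic
  g <- rep(1:2, each = 30)
  x <- rnorm(60, mean = c(3.2, 3.4)[g], sd = 0.25)
  a2 <- mass_year_anova(x, g)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(a2$F, unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(a2$p, tt$p.value, tolerance = 1e-10)
  expect_error(mass_year_anova(rnorm(5), rep(1, 5)), "2 cohorts")
})
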