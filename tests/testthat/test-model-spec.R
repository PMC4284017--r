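test_that("model labels round-trip through the parser", {
  cands <- enumerate_candidates()
  labels <- vapply(cands, function(s) s$label, character(1))
  expect_equal(anyDuplicated(labels), 0L)
  for (s in cands)
    expect_equal(parse_model_label(s$label)$label, s$label)
  # covariate-laden labels
  lab <- "phi(a2 a+t mass:i pred_pressure*a lsst_lag1) p(T3) psi(4 ln)"
  expect_equal(parse_model_label(lab)$label, lab)
  lab2 <- "phi(a1 t) p(=1) psi(3)"
  expect_equal(parse_model_label(lab2)$label, lab2)
  expect_error(parse_model_label("phi(a2"), "unparseable")
})

test_that("the candidate generator spans the screened structures", {
  labels <- vapply(enumerate_candidates(),
                   function(s) s$label, character(1))
  screened <- c("phi(a2 a+t) p(T3) psi(4 ln)",
                "phi(a2 a*t) p(T3) psi(4 ln)",
                "phi(a2 a*t) p(t) psi(4 ln)",
                "phi(a2 a*t) p(t) psi(4 lin)",
                "phi(a2 a*t) p(t) psi(5)",
                "phi(a2 a*t) p(t) psi(4)",
                "phi(a2 a*t) p(t) psi(3)",
                "phi(a3 a*t) p(t) psi(5)",
                "phi(a1 t) p(t) psi(5)",
                "phi(a2 a*t) p(.) psi(4 ln)")
  expect_true(all(screened %in% labels))
  # restricting the age structures restricts the labels
  only_a2 <- vapply(enumerate_candidates(ages = "a2"),
                    function(s) s$label, character(1))
  expect_false(any(grepl("a3", only_a2)))
  # psi maxima alone give three variants
  expect_length(enumerate_candidates(ages = "a2",
                                     time_effects = "additive",
                                     p_structures = "effort",
                                     psi_trends = "free"), 3L)
})

test_that("spec invariants are enforced", {
  expect_error(survival_spec("a1", "interactive"), "2 age classes")
  expect_error(survival_spec("a1", covariates = list(
    list(name = "mass", scope = "individual"))), "a2 or a3")
  expect_error(recapture_spec("fixed"), "fixed_value")
  expect_error(transition_spec(0), ">= 1")
})

test_that("effort groups follow the gateway-day thresholds", {
  expect_equal(effort_groups(c(120, 150, 0, 101, 50, 1, 100)),
               c("working_well", "working_well", "not_working",
                 "working_well", "intermittent", "intermittent",
                 "intermittent"))
})

test_that("a log-age transition trend needs exactly 2 coefficients", {
  sim <- small_sim(seed = 3L, fledglings = 20L, adults = 10L)
  str_free <- model_structure(survival_spec("a2"), recapture_spec("effort"),
                              transition_spec(4, "free"))
  str_ln <- model_structure(survival_spec("a2"), recapture_spec("effort"),
                            transition_spec(4, "ln"))
  d_free <- build_design(str_free, sim$dataset)
  d_ln <- build_design(str_ln, sim$dataset)
  expect_equal(sum(grepl("^psi_", d_free$coef_names)), 4L)
  expect_equal(sum(grepl("^psi_", d_ln$coef_names)), 2L)
  expect_equal(d_free$k - d_ln$k, 2L)
  # ln trend encodes logit(psi_a) = b0 + b1 log(a)
  beta <- numeric(d_ln$k)
  names(beta) <- d_ln$coef_names
  beta["psi_b0"] <- 0.3; beta["psi_b1"] <- -0.5
  psi <- realize_parameters(beta, d_ln)$psi
  expect_equal(psi[1:4], plogis(0.3 - 0.5 * log(1:4)))
  expect_equal(psi[5:9], rep(1, 5))   # fixed above the maximum
})

test_that("recapture design maps occasions to effort groups", {
  T <- 8L
  gw <- c(120, 150, 0, 130, 50, 200, 110, 140)
  yc <- tiny_year_covariates(T, gateway_days = gw)
  ds <- tiny_dataset(c("10000000", "01000000"), c("adult", "adult"),
                     year_covariates = yc)
  str <- model_structure(survival_spec("a1"), recapture_spec("effort"),
                         transition_spec(3))
  d <- build_design(str, ds)
  expect_equal(sum(grepl("^p_eff", d$coef_names)), 3L)
  expect_equal(d$occ_groups, effort_groups(gw))
  # the occasion-group indicator rows match the thresholds
  expect_equal(which(d$X_p[, "p_eff_not_working"] == 1), 3L)
  expect_equal(which(d$X_p[, "p_eff_intermittent"] == 1), 5L)
  expect_equal(which(d$X_p[, "p_eff_working_well"] == 1),
               c(2L, 4L, 6L, 7L, 8L))
})

test_that("coefficient counting excludes fixed parameters", {
  # constant survival, constant recapture, all-adult data (psi vacuous):
  # one intercept each
  ds <- tiny_dataset(c("1010", "0110", "0011"), rep("adult", 3))
  k <- count_parameters(model_structure(survival_spec("a1"),
                                        recapture_spec("constant"),
                                        transition_spec(3)), ds)
  expect_equal(k, 2L)
  # fixing p removes its coefficient
  k_fixed <- count_parameters(model_structure(survival_spec("a1"),
                                              recapture_spec("fixed", 1),
                                              transition_spec(3)), ds)
  expect_equal(k_fixed, 1L)
})

test_that("adding covariates and time effects grows k as expected", {
  sim <- small_sim(seed = 13L, fledglings = 30L, adults = 20L)
  ds <- sim$dataset
  base <- model_structure(survival_spec("a2"), recapture_spec("effort"),
                          transition_spec(3))
  k0 <- count_parameters(base, ds)
  with_cov <- model_structure(
    survival_spec("a2", covariates = list(list(name = "lsst_lag1",
                                               scope = "additive"))),
    recapture_spec("effort"), transition_spec(3))
  expect_equal(count_parameters(with_cov, ds), k0 + 1L)
  # nested time structures have strictly increasing k
  k_add <- count_parameters(model_structure(survival_spec("a2", "additive"),
                                            recapture_spec("effort"),
                                            transition_spec(3)), ds)
  k_int <- count_parameters(model_structure(survival_spec("a2", "interactive"),
                                            recapture_spec("effort"),
                                            transition_spec(3)), ds)
  expect_true(k0 < k_add && k_add < k_int)
})

test_that("structural k matches the numeric design rank", {
  sim <- small_sim(seed = 17L, fledglings = 40L, adults = 30L)
  str <- sim$truth$structure
  expect_no_warning(k <- count_parameters(str, sim$dataset,
                                          check_rank = TRUE))
  expect_equal(k, length(sim$truth$beta))
})
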