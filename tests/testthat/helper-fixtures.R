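# Fixture builders shared across test files.

# Tiny dataset from history strings, e.g. tiny_dataset(c("1010", "0011"),
# classes = c("fledgling", "adult"), masses = c(3.4, NA))
tiny_dataset <- function(histories, classes, masses = NULL,
                         first_season = 2003L, year_covariates = NULL) {
  det <- do.call(rbind, lapply(strsplit(histories, ""), as.integer))
  n <- nrow(det)
  if (is.null(masses)) masses <- rep(NA_real_, n)
  cmr_dataset(study_calendar(first_season, ncol(det)),
              data.frame(animal_id = sprintf("A%05d", seq_len(n)),
                         mark_occasion = apply(det == 1L, 1, which.max),
                         mark_class = classes, mass = masses,
                         stringsAsFactors = FALSE),
              det, year_covariates)
}

# Random real-parameter set for a T-occasion study
random_params <- function(T, interior = TRUE) {
  lo <- if (interior) 0.05 else 0
  hi <- if (interior) 0.95 else 1
  list(phi = runif(T - 1, lo, hi),
       p = runif(T, lo, hi),
       psi = runif(T - 1, lo, hi))
}

# Random single encounter record (marking + arbitrary later detections)
random_animal <- function(T) {
  m <- sample.int(T, 1)
  cls <- sample(c("fledgling", "adult"), 1)
  det <- integer(T)
  det[m] <- 1L
  if (m < T) det[(m + 1):T] <- rbinom(T - m, 1, 0.4)
  list(animal_id = "X", mark_occasion = m, mark_class = cls,
       mass = if (cls == "fledgling") 3.3 else NA_real_,
       detections = det)
}

# Annual covariate table with all canonical columns
tiny_year_covariates <- function(T, first_season = 2003L,
                                 gateway_days = NULL, seed = 99L) {
  set.seed(seed)
  if (is.null(gateway_days)) {
    gateway_days <- rep(150, T)
    if (T >= 5) gateway_days[5] <- 0
    if (T >= 7) gateway_days[7] <- 50
  }
  data.frame(season = first_season + seq_len(T) - 1L,
             pred_pressure = pmax(0, round(rnorm(T, 25, 8))),
             lsst_lag0 = rnorm(T, 0, 0.5), lsst_lag1 = rnorm(T, 0, 0.5),
             enso_lag2 = rnorm(T), enso_lag3 = rnorm(T),
             sam_lag0 = rnorm(T, 0, 1.5), sam_lag1 = rnorm(T, 0, 1.5),
             gateway_days = gateway_days,
             mean_fledging_mass = rnorm(T, 3.28, 0.15))
}

# A small simulated dataset reused by several estimation/selection tests
small_sim <- function(seed = 11L, fledglings = 60L, adults = 40L,
                      n_occasions = 10L, ...) {
  simulate_dataset(simulation_config(
    seed = seed, n_occasions = n_occasions,
    fledglings_per_cohort = fledglings, adults_per_year = adults, ...))
}

# Fake fitted-model stub for selection arithmetic tests
fake_fit <- function(label, deviance, k, ess = 2000L) {
  structure(list(structure = list(label = label), deviance = deviance,
                 k = k, ess = ess, converged = TRUE, c_hat = 1),
            class = "cmr_fit")
}
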