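#' Simulation configuration
#'
#' Describes the generating process for synthetic encounter-history
#' datasets.  Defaults emulate the decade-long macaroni penguin PIT-tag
#' study the model family was developed for: 10 annual occasions, seven
#' fledgling cohorts of ~150 chicks plus ~100 adults tagged per year,
#' fledging-year survival 0.33 and older survival 0.89, detection 0.99 /
#' 0.88 / 0.15 by gateway effort level (one season with the reader down,
#' one intermittent), first return at ages 1-3 (0.10 / 0.50 / 0.756, so 10%
#' back by age 1 and 89% cumulatively by age 3; fixed 1 above), mean
#' fledging mass 3.28 kg, and logit-scale covariate effects on survival
#' sized so that predation pressure dominates fledging mass, which
#' dominates the local SST anomaly.
#'
#' Covariate effects are expressed per standard deviation of the covariate
#' as realized in the simulated dataset (the same standardization the
#' fitting code applies), so fitted coefficients estimate the configured
#' slopes directly.
#'
#' @param n_occasions Number of annual occasions.
#' @param first_season Year label of occasion 1.
#' @param fledglings_per_cohort Chicks tagged per fledgling cohort.
#' @param fledgling_cohort_occasions Occasions with a tagged fledgling cohort.
#' @param adults_per_year Adults tagged per tagging occasion.
#' @param adult_occasions Occasions at which adults are tagged.
#' @param phi_mean Mean survival per age class (youngest first); length
#'   gives the number of age classes.
#' @param covariate_effects Named list of
#'   \code{list(scope =, beta =)} survival effects; scope as in
#'   \code{\link{survival_spec}} (interactive betas: one per age class).
#' @param year_sigma SD of an extra additive logit-scale year effect on
#'   survival (0 = none).
#' @param p_by_group Detection probability per gateway effort group.
#' @param psi True first-return probabilities for ages 1..max (fixed 1
#'   above).
#' @param mass_mean,mass_sd Overall fledging-mass distribution (kg).
#' @param cohort_mass_sd Between-cohort SD of cohort mean mass (kg).
#' @param pred_mean,pred_sd Giant-petrel fledged-chick count distribution
#'   (rounded, truncated at 0).
#' @param env_sd Named SDs for the zero-mean environmental covariates.
#' @param gateway_days Reader operation days per occasion (default: 150
#'   everywhere, occasion 5 down, occasion 7 intermittent at 50 days,
#'   mimicking the 2007 failure and 2009 intermittency).
#' @param cluster_size Overdispersion cluster size (1 = independent fates;
#'   may be non-integer, realized as a mixture of adjacent integer sizes).
#' @param seed Mandatory integer seed.
#' @return A \code{simulation_config}.
#' @export
simulation_config <- function(n_occasions = 10L,
                              first_season = 2003L,
                              fledglings_per_cohort = 150L,
                              fledgling_cohort_occasions = NULL,
                              adults_per_year = 100L,
                              adult_occasions = NULL,
                              phi_mean = c(0.33, 0.89),
                              covariate_effects = list(
                                mass = list(scope = "individual", beta = 0.41),
                                pred_pressure = list(scope = "interactive",
                                                     beta = c(-0.68, -0.20)),
                                lsst_lag1 = list(scope = "additive",
                                                 beta = 0.14)),
                              year_sigma = 0,
                              p_by_group = c(working_well = 0.99,
                                             intermittent = 0.88,
                                             not_working = 0.15),
                              psi = c(0.10, 0.50, 0.756),
                              mass_mean = 3.28, mass_sd = 0.30,
                              cohort_mass_sd = 0.15,
                              pred_mean = 25, pred_sd = 8,
                              env_sd = c(lsst_lag0 = 0.5, lsst_lag1 = 0.5,
                                         enso_lag2 = 1, enso_lag3 = 1,
                                         sam_lag0 = 1.5, sam_lag1 = 1.5),
                              gateway_days = NULL,
                              cluster_size = 1,
                              seed) {
  if (missing(seed)) stop("a seed is mandatory")
  T <- as.integer(n_occasions)
  if (T < 2L) stop("n_occasions must be >= 2")
  if (is.null(fledgling_cohort_occasions))
    fledgling_cohort_occasions <- seq_len(max(1L, min(7L, T - 3L)))
  if (is.null(adult_occasions))
    adult_occasions <- seq_len(T - 1L)
  if (is.null(gateway_days)) {
    gateway_days <- rep(150, T)
    if (T >= 5L) gateway_days[5L] <- 0
    if (T >= 7L) gateway_days[7L] <- 50
  }
  if (length(gateway_days) != T)
    stop("gateway_days must have one value per occasion")
  if (any(phi_mean <= 0 | phi_mean >= 1) || any(psi <= 0 | psi > 1))
    stop("phi_mean and psi must be probabilities in (0, 1]")
  if (cluster_size < 1) stop("cluster_size must be >= 1")
  structure(list(n_occasions = T, first_season = as.integer(first_season),
                 fledglings_per_cohort = as.integer(fledglings_per_cohort),
                 fledgling_cohort_occasions = as.integer(fledgling_cohort_occasions),
                 adults_per_year = as.integer(adults_per_year),
                 adult_occasions = as.integer(adult_occasions),
                 phi_mean = phi_mean, covariate_effects = covariate_effects,
                 year_sigma = year_sigma, p_by_group = p_by_group, psi = psi,
                 mass_mean = mass_mean, mass_sd = mass_sd,
                 cohort_mass_sd = cohort_mass_sd,
                 pred_mean = pred_mean, pred_sd = pred_sd, env_sd = env_sd,
                 gateway_days = gateway_days, cluster_size = cluster_size,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Partition a cohort of N animals into fate-sharing clusters whose
# animal-weighted mean size is `size` (sum s_j^2 / sum s_j = size), using a
# mixture of the two adjacent integer sizes.  Returns cluster sizes.
.cluster_sizes <- function(N, size) {
  if (size > N) stop("cluster_size exceeds cohort size (", N, ")")
  c1 <- floor(size); c2 <- ceiling(size)
  if (c1 == c2) {
    sizes <- rep(c1, N %/% c1)
    if (N %% c1 > 0L) sizes <- c(sizes, N %% c1)
    return(sizes)
  }
  n2 <- round(N * (size - c1))          # animals in size-c2 clusters
  n2 <- min(N, (n2 %/% c2) * c2)
  n1 <- N - n2
  sizes <- c(rep(c2, n2 %/% c2), rep(c1, n1 %/% c1))
  if (n1 %% c1 > 0L) sizes <- c(sizes, n1 %% c1)
  sizes
}

# Core latent-process simulator.  phi: n x (T-1) survival per animal and
# interval; p: detection per occasion (observable state); psi: first-return
# probability per age (fixed 1 above length).  cluster_id: animals sharing
# an id share the survival and first-return uniforms (comonotone fates);
# detection draws are always independent.  Assumes the RNG state is set.
# Returns detections (n x T) and latent states (n x T; 0 pre-marking,
# 1 pre-return, 2 returned, 3 dead).
.simulate_histories <- function(phi, p, psi, mark, fled, cluster_id) {
  n <- length(mark)
  T <- ncol(phi) + 1L
  nclust <- max(cluster_id)
  det <- matrix(0L, n, T)
  states <- matrix(0L, n, T)
  state <- integer(n)                   # 0 = not yet marked
  for (i in seq_len(n)) det[i, mark[i]] <- 1L
  state[mark == 1L] <- ifelse(fled[mark == 1L], 1L, 2L)
  states[, 1L] <- state
  for (t in seq_len(T - 1L)) {
    u_surv <- stats::runif(nclust)[cluster_id]
    u_ret <- stats::runif(nclust)[cluster_id]
    u_det <- stats::runif(n)
    alive <- state %in% c(1L, 2L)
    survives <- alive & (u_surv < phi[, t])
    state[alive & !survives] <- 3L
    age <- t + 1L - mark
    psival <- ifelse(age > length(psi), 1, psi[pmin(pmax(age, 1L), length(psi))])
    ret <- state == 1L & survives & (u_ret < psival)
    state[ret] <- 2L
    newly <- mark == t + 1L
    state[newly] <- ifelse(fled[newly], 1L, 2L)
    states[, t + 1L] <- state
    seen <- state == 2L & !newly & (u_det < p[t + 1L])
    det[seen, t + 1L] <- 1L
  }
  list(detections = det, states = states)
}

#' Simulate a capture-mark-recapture dataset
#'
#' Draws annual covariates and fledging masses, computes per-animal
#' survival on the logit scale from the configured age-class means and
#' covariate effects (covariates entering as within-dataset z-scores, the
#' same standardization the fitting code uses), simulates latent
#' survival/first-return paths and effort-dependent detection, and returns
#' a validated dataset together with the full generating truth.
#'
#' With \code{cluster_size > 1}, animals within a tagging cohort are
#' grouped into clusters that share the survival and first-return uniform
#' draws (and, for fledglings, the mass draw), leaving marginal rates
#' unchanged while inflating the variance of cohort fate counts by about
#' the cluster size — the overdispersion mechanism used by the median c-hat
#' machinery.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return List with \code{dataset} (a \code{cmr_dataset}) and \code{truth}
#'   (generating parameters: \code{structure}, named \code{beta} on the
#'   fitted parameterization, realized real parameters, latent state
#'   paths).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  T <- config$n_occasions
  nc <- length(config$phi_mean)
  # annual covariates -----------------------------------------------------
  yc <- data.frame(season = config$first_season + seq_len(T) - 1L)
  yc$pred_pressure <- pmax(0, round(stats::rnorm(T, config$pred_mean,
                                                 config$pred_sd)))
  for (nm in names(config$env_sd))
    yc[[nm]] <- stats::rnorm(T, 0, config$env_sd[[nm]])
  yc$gateway_days <- config$gateway_days
  # animals ----------------------------------------------------------------
  cohorts <- config$fledgling_cohort_occasions
  nf_per <- config$fledglings_per_cohort
  mark <- c(rep(cohorts, each = nf_per),
            rep(config$adult_occasions, each = config$adults_per_year))
  fled <- c(rep(TRUE, length(cohorts) * nf_per),
            rep(FALSE, length(config$adult_occasions) * config$adults_per_year))
  n <- length(mark)
  ids <- sprintf("A%05d", seq_len(n))
  # clusters: chunk within (occasion, class) cohorts
  cluster_id <- integer(n)
  nxt <- 0L
  for (grp in split(seq_len(n), list(mark, fled))) {
    if (length(grp) == 0L) next
    sizes <- .cluster_sizes(length(grp), config$cluster_size)
    cluster_id[grp] <- nxt + rep(seq_along(sizes), times = sizes)
    nxt <- nxt + length(sizes)
  }
  # masses: cohort means vary; cluster members share a mass draw
  cohort_mu <- stats::rnorm(length(cohorts), config$mass_mean,
                            config$cohort_mass_sd)
  names(cohort_mu) <- as.character(cohorts)
  mass <- rep(NA_real_, n)
  fidx <- which(fled)
  mass_draw <- stats::rnorm(n, 0, config$mass_sd)
  u <- !duplicated(cluster_id)
  for (i in fidx) {
    src <- if (u[i]) i else match(cluster_id[i], cluster_id)
    mass[i] <- pmax(0.5, cohort_mu[[as.character(mark[i])]] + mass_draw[src])
  }
  yc$mean_fledging_mass <- NA_real_
  for (co in cohorts)
    yc$mean_fledging_mass[co] <- mean(mass[fled & mark == co])
  yc$mean_fledging_mass[is.na(yc$mean_fledging_mass)] <-
    if (length(fidx)) mean(mass[fled]) else config$mass_mean
  # survival logits --------------------------------------------------------
  z_mass <- rep(0, n)
  if (length(fidx) >= 2L) z_mass[fidx] <- standardize(mass[fidx])$z
  eta <- matrix(NA_real_, n, T - 1L)
  year_eff <- if (config$year_sigma > 0)
    stats::rnorm(T - 1L, 0, config$year_sigma) else numeric(T - 1L)
  z_annual <- list()
  for (t in seq_len(T - 1L)) {
    age <- ifelse(fled, t - mark, NA_integer_)
    cls <- age_class(age, nc)
    e <- stats::qlogis(config$phi_mean)[cls] + year_eff[t]
    for (nm in names(config$covariate_effects)) {
      ce <- config$covariate_effects[[nm]]
      if (ce$scope == "individual") {
        e <- e + ce$beta * z_mass * (cls == 1L)
      } else {
        if (is.null(z_annual[[nm]]))
          z_annual[[nm]] <- standardize(yc[[nm]][seq_len(T - 1L)])$z
        zt <- z_annual[[nm]][t]
        if (ce$scope == "additive") e <- e + ce$beta * zt
        else e <- e + ce$beta[cls] * zt
      }
    }
    eta[, t] <- e
  }
  phi <- stats::plogis(eta)
  # detection and transition ----------------------------------------------
  p <- config$p_by_group[effort_groups(config$gateway_days)]
  sim <- .simulate_histories(phi, p, config$psi, mark, fled, cluster_id)
  dataset <- cmr_dataset(study_calendar(config$first_season, T),
                         data.frame(animal_id = ids, mark_occasion = mark,
                                    mark_class = ifelse(fled, "fledgling",
                                                        "adult"),
                                    mass = mass, stringsAsFactors = FALSE),
                         sim$detections, yc)
  truth <- list(config = config,
                structure = .truth_structure(config),
                beta = .truth_beta(config),
                phi = phi, p = unname(p), psi = config$psi,
                year_effects = year_eff,
                cluster_id = cluster_id,
                states = sim$states)
  list(dataset = dataset, truth = truth)
}

# model_structure matching the generating process
.truth_structure <- function(config) {
  nc <- length(config$phi_mean)
  covs <- lapply(names(config$covariate_effects), function(nm) {
    sc <- config$covariate_effects[[nm]]$scope
    list(name = if (sc == "individual") "mass" else nm, scope = sc)
  })
  te <- if (config$year_sigma > 0) "additive" else "none"
  model_structure(survival_spec(paste0("a", nc), te, covs),
                  recapture_spec("effort"),
                  transition_spec(length(config$psi), "free"))
}

# named true coefficient vector on the fitted parameterization
.truth_beta <- function(config) {
  nc <- length(config$phi_mean)
  beta <- stats::qlogis(config$phi_mean)
  names(beta) <- sprintf("phi_int_c%d", seq_len(nc))
  for (nm in names(config$covariate_effects)) {
    ce <- config$covariate_effects[[nm]]
    if (ce$scope == "individual") {
      beta["phi_mass"] <- ce$beta
    } else if (ce$scope == "additive") {
      beta[sprintf("phi_%s", nm)] <- ce$beta
    } else {
      for (cc in seq_len(nc))
        beta[sprintf("phi_%s_c%d", nm, cc)] <- ce$beta[cc]
    }
  }
  grp <- effort_groups(config$gateway_days)
  for (g in c("working_well", "intermittent", "not_working")) {
    if (any(grp[-1L] == g))
      beta[sprintf("p_eff_%s", g)] <- stats::qlogis(config$p_by_group[[g]])
  }
  for (a in seq_along(config$psi))
    beta[sprintf("psi_a%d", a)] <- stats::qlogis(config$psi[a])
  beta
}

#' Simulate a dataset with overdispersed fates
#'
#' \code{\link{simulate_dataset}} with \code{cluster_size > 1}: animals are
#' generated in fate-sharing clusters so that the variance of cohort
#' survivor counts is inflated by about the cluster size while marginal
#' rates are unchanged.
#'
#' @param config A \code{simulation_config} with \code{cluster_size >= 1}.
#' @return As \code{\link{simulate_dataset}}.
#' @export
induce_overdispersion <- function(config) {
  simulate_dataset(config)
}

#' Simulate replicate detection data from a fitted model
#'
#' Parametric-bootstrap style simulator used by the median c-hat machinery:
#' keeps the observed animals (marking occasions, classes, masses,
#' covariates) and redraws their fates and detections from the fitted
#' parameters, optionally in fate-sharing clusters of a given size.
#'
#' @param fit A converged \code{cmr_fit}.
#' @param cluster_size Overdispersion cluster size (>= 1).
#' @param seed Integer seed.
#' @return A \code{cmr_dataset} with simulated detections.
#' @export
simulate_from_fit <- function(fit, cluster_size = 1, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  design <- fit$design
  pars <- realize_parameters(fit$beta_hat, design)
  phi <- pars$phi
  phi[is.na(phi)] <- 0.5                # masked entries, never used
  n <- design$n
  mark <- design$mark
  fled <- design$is_fledgling
  cluster_id <- integer(n)
  nxt <- 0L
  for (grp in split(seq_len(n), list(mark, fled))) {
    if (length(grp) == 0L) next
    sizes <- .cluster_sizes(length(grp), min(cluster_size, length(grp)))
    cluster_id[grp] <- nxt + rep(seq_along(sizes), times = sizes)
    nxt <- nxt + length(sizes)
  }
  sim <- .simulate_histories(phi, pars$p, pars$psi, mark, fled, cluster_id)
  ds <- fit$dataset
  ds$detections <- sim$detections
  ds
}
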