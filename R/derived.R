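#' Predict survival for an age class at given covariate values
#'
#' Builds the logit-scale linear predictor for the requested age class with
#' covariates supplied on their raw scale (standardized internally with the
#' standardizers stored in the fit's design; omitted covariates sit at
#' their mean, z = 0).  Year effects, if present in the model, are held at
#' the reference year.  The confidence interval is Wald on the logit scale
#' (delta method), using the fit's possibly c-hat-inflated covariance.
#'
#' @param fit A \code{cmr_fit}.
#' @param age_class Age class index (1 = fledging year).
#' @param covariate_values Named list/vector of raw-scale covariate values.
#' @param level Confidence level.
#' @return List with \code{phi}, \code{se_logit}, \code{ci_low},
#'   \code{ci_high}, \code{eta}.
#' @export
predict_survival <- function(fit, age_class = 1L, covariate_values = list(),
                             level = 0.95) {
  design <- fit$design
  x <- numeric(design$k)
  names(x) <- design$coef_names
  intc <- sprintf("phi_int_c%d", age_class)
  if (!intc %in% design$coef_names)
    stop("age class ", age_class, " has no intercept in this fit")
  x[intc] <- 1
  covs <- fit$structure$survival$covariates
  known <- vapply(covs, `[[`, character(1), "name")
  bad <- setdiff(names(covariate_values), known)
  if (length(bad))
    stop("covariate(s) not in the model: ", paste(bad, collapse = ", "))
  for (cv in covs) {
    std <- design$standardizers[[cv$name]]
    z <- if (cv$name %in% names(covariate_values))
      (as.numeric(covariate_values[[cv$name]]) - std$center) / std$scale
    else 0
    if (cv$scope == "individual") {
      if (age_class == 1L) x[sprintf("phi_%s", cv$name)] <- z
    } else if (cv$scope == "additive") {
      x[sprintf("phi_%s", cv$name)] <- z
    } else {
      nm <- sprintf("phi_%s_c%d", cv$name, age_class)
      if (nm %in% design$coef_names) x[nm] <- z
    }
  }
  eta <- sum(x * fit$beta_hat)
  v <- as.numeric(x %*% fit$vcov %*% x)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  list(phi = stats::plogis(eta), se_logit = sqrt(v),
       ci_low = stats::plogis(eta - zq * sqrt(v)),
       ci_high = stats::plogis(eta + zq * sqrt(v)),
       eta = eta)
}

#' Cumulative probability of first return by age
#'
#' \code{C(a) = 1 - prod_(i<=a) (1 - psi_i)}: the probability that a
#' surviving bird has returned to the colony at least once by age a.
#' Ages beyond \code{length(psi)} take psi = 1 (the fixed-above-maximum
#' rule), so the curve reaches 1 at the age after the maximum.
#'
#' @param psi First-return probabilities for ages 1..max.
#' @param through_age Last age of the curve (default: one past the
#'   maximum).
#' @return Numeric vector \code{C(1..through_age)}.
#' @export
cumulative_first_return <- function(psi, through_age = length(psi) + 1L) {
  if (any(psi < 0 | psi > 1)) stop("psi entries must be in [0, 1]")
  full <- c(psi, rep(1, max(0L, through_age - length(psi))))[seq_len(through_age)]
  1 - cumprod(1 - full)
}

#' Temporal process variance of annual estimates
#'
#' Intercept-only random-effects moment estimator: finds the process
#' variance sigma^2 >= 0 and weighted mean (weights
#' \code{1 / (sigma^2 + v_t)}) such that the weighted sum of squared
#' deviations equals T - 1, separating true temporal variation from
#' sampling variance.  Shrunken annual estimates lie between the raw
#' estimates and the mean.
#'
#' @param estimates Annual estimates (>= 3).
#' @param sampling_vcov Sampling covariance matrix of the estimates, or a
#'   vector of sampling variances (off-diagonals are not used).
#' @param max_iter Unused (root finding is direct); kept for API
#'   stability.
#' @return A \code{process_variance}: \code{mean}, \code{se_mean},
#'   \code{sigma2_process}, \code{sigma_process}, \code{shrunken}.
#' @export
variance_components <- function(estimates, sampling_vcov, max_iter = 100L) {
  th <- as.numeric(estimates)
  Tn <- length(th)
  if (Tn < 3L) stop("need at least 3 annual estimates")
  v <- if (is.matrix(sampling_vcov)) diag(sampling_vcov)
       else as.numeric(sampling_vcov)
  if (length(v) != Tn) stop("sampling variances do not match estimates")
  if (anyNA(th) || anyNA(v) || any(!is.finite(th)) || any(!is.finite(v)))
    stop("estimates and sampling variances must be finite")
  if (any(v < 0)) stop("negative sampling variance")
  v <- pmax(v, 1e-12)
  crit <- function(s2) {
    w <- 1 / (s2 + v)
    mu <- sum(w * th) / sum(w)
    sum(w * (th - mu)^2) - (Tn - 1)
  }
  if (crit(0) <= 0) {
    s2 <- 0
  } else {
    upper <- stats::var(th) * 10 + max(v)
    while (crit(upper) > 0) upper <- upper * 10
    s2 <- stats::uniroot(crit, c(0, upper), tol = 1e-12)$root
  }
  w <- 1 / (s2 + v)
  mu <- sum(w * th) / sum(w)
  shrink <- mu + (s2 / (s2 + v)) * (th - mu)
  structure(list(mean = mu, se_mean = sqrt(1 / sum(w)),
                 sigma2_process = s2, sigma_process = sqrt(s2),
                 estimates = th, sampling_var = v, shrunken = shrink),
            class = "process_variance")
}

#' @export
print.process_variance <- function(x, ...) {
  cat(sprintf("process variance: mean %.4f (SE %.4f), sigma %.4f\n",
              x$mean, x$se_mean, x$sigma_process))
  invisible(x)
}

#' Annual survival estimates from an additive-time fit
#'
#' Extracts per-interval survival for one age class from a model with year
#' effects, at covariate means, with delta-method sampling variances on the
#' probability scale.  Estimates whose logit-scale standard error exceeds
#' \code{se_limit} are flagged non-identifiable (\code{usable = FALSE}); the
#' penguin analysis similarly excluded a cohort whose confidence interval
#' was uninformative.
#'
#' @param fit A \code{cmr_fit} whose survival structure has year effects.
#' @param age_class Age class index.
#' @param se_limit Logit-scale SE above which an estimate is flagged.
#' @return Data frame: interval, estimate, var (probability scale),
#'   se_logit, usable.
#' @export
annual_survival <- function(fit, age_class = 1L, se_limit = 3) {
  design <- fit$design
  T <- design$calendar$n_occasions
  cm <- design$class_matrix
  rows <- list()
  for (t in seq_len(T - 1L)) {
    if (!any(cm[, t] == age_class, na.rm = TRUE)) next
    x <- numeric(design$k)
    names(x) <- design$coef_names
    x[sprintf("phi_int_c%d", age_class)] <- 1
    for (nm in c(sprintf("phi_t%d", t), sprintf("phi_t%d_c%d", t, age_class)))
      if (nm %in% design$coef_names) x[nm] <- 1
    eta <- sum(x * fit$beta_hat)
    vl <- as.numeric(x %*% fit$vcov %*% x)
    if (!is.finite(vl) || vl < 0) vl <- Inf
    phi <- stats::plogis(eta)
    rows[[length(rows) + 1L]] <-
      data.frame(interval = t, estimate = phi,
                 var = (phi * (1 - phi))^2 * vl,
                 se_logit = sqrt(vl), usable = sqrt(vl) <= se_limit)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sensitivity of survival to a covariate
#'
#' Partial derivative of survival with respect to the covariate (per
#' standard deviation): \code{S = beta * phi * (1 - phi)} under the logit
#' link, evaluated by default with all standardized covariates at zero
#' (their means), i.e. at the age class's fitted mean survival.
#'
#' @param fit A \code{cmr_fit}.
#' @param age_class Age class index.
#' @param covariate Covariate name as used in the model.
#' @param at Named list of raw-scale covariate values for the evaluation
#'   point (default: means).
#' @return The sensitivity S.
#' @export
sensitivity <- function(fit, age_class, covariate, at = list()) {
  beta <- .covariate_coef(fit, age_class, covariate)
  phi <- predict_survival(fit, age_class, at)$phi
  beta * phi * (1 - phi)
}

.covariate_coef <- function(fit, age_class, covariate) {
  covs <- fit$structure$survival$covariates
  idx <- which(vapply(covs, `[[`, character(1), "name") == covariate)
  if (length(idx) == 0L)
    stop("covariate '", covariate, "' is not in the model")
  cv <- covs[[idx[1L]]]
  if (cv$scope == "individual" && age_class != 1L)
    stop("individual covariate '", covariate,
         "' only enters the fledging-year class")
  nm <- switch(cv$scope,
               individual = sprintf("phi_%s", covariate),
               additive = sprintf("phi_%s", covariate),
               interactive = sprintf("phi_%s_c%d", covariate, age_class))
  if (!nm %in% names(fit$beta_hat))
    stop("no coefficient for covariate '", covariate,
         "' in age class ", age_class)
  fit$beta_hat[[nm]]
}

#' Sensitivity table across age classes and covariates
#'
#' @param fit A \code{cmr_fit}.
#' @param age_classes Age class indices to evaluate.
#' @return Data frame (age_class, covariate, S), skipping covariates
#'   absent from a class.
#' @export
sensitivity_table <- function(fit,
                              age_classes = seq_len(fit$structure$survival$n_classes)) {
  covs <- fit$structure$survival$covariates
  rows <- list()
  for (ac in age_classes) for (cv in covs) {
    S <- try(sensitivity(fit, ac, cv$name), silent = TRUE)
    if (inherits(S, "try-error")) next
    rows[[length(rows) + 1L]] <-
      data.frame(age_class = ac, covariate = cv$name, S = S)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' De-standardize a per-SD slope to natural covariate units
#'
#' @param beta_per_sd Logit-scale slope per standard deviation.
#' @param standardizer The covariate's \code{standardized_covariate}.
#' @return Slope per natural unit: \code{beta_per_sd / scale}.
#' @export
destandardize_slope <- function(beta_per_sd, standardizer) {
  if (standardizer$scale <= 0) stop("standardizer has nonpositive scale")
  beta_per_sd / standardizer$scale
}

#' One-way ANOVA of fledging mass across cohort years
#'
#' Fixed-effects analysis of variance testing year-to-year variation in
#' observed fledging mass.
#'
#' @param masses Numeric vector of fledging masses.
#' @param cohort Parallel vector of cohort labels.
#' @return List with \code{F}, \code{df_between}, \code{df_within},
#'   \code{p}.
#' @export
mass_year_anova <- function(masses, cohort) {
  ok <- !is.na(masses)
  masses <- masses[ok]; cohort <- factor(cohort[ok])
  if (nlevels(cohort) < 2L) stop("need at least 2 cohorts")
  if (any(table(cohort) < 2L)) stop("each cohort needs at least 2 masses")
  a <- stats::anova(stats::lm(masses ~ cohort))
  list(F = a$`F value`[1L], df_between = a$Df[1L], df_within = a$Df[2L],
       p = a$`Pr(>F)`[1L])
}
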