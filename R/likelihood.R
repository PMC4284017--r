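#' Realized real parameters for one animal (or the whole design)
#'
#' Applies the inverse-logit link to each linear predictor of the design and
#' then the fixed-value overrides: detection in the unobservable state is 0
#' (structural, never represented), first return above the maximum age is 1,
#' and a fixed observable detection value replaces the link when specified.
#'
#' @param beta Coefficient vector matching the design.
#' @param design A \code{cmr_design}.
#' @param animal Optional animal index; when given, returns that animal's
#'   parameter set.
#' @return With \code{animal}: list with \code{phi} (survival per interval,
#'   NA before marking), \code{p} (detection per occasion in the observable
#'   state) and \code{psi} (first-return probability per age).  Without:
#'   the same quantities for all animals (\code{phi} is an n x (T-1)
#'   matrix).
#' @export
realize_parameters <- function(beta, design, animal = NULL) {
  if (length(beta) != design$k)
    stop("beta has length ", length(beta), "; design expects ", design$k)
  T <- design$calendar$n_occasions
  n <- design$n
  phi <- matrix(stats::plogis(as.vector(design$X_phi %*% beta)),
                n, T - 1L, byrow = TRUE)
  phi[!design$phi_valid] <- NA_real_
  p <- if (!is.null(design$p_fixed)) rep(design$p_fixed, T)
       else stats::plogis(as.vector(design$X_p %*% beta))
  psi <- stats::plogis(as.vector(design$X_psi %*% beta))
  psi[design$psi_fixed_one] <- 1
  if (is.null(animal))
    return(list(phi = phi, p = p, psi = psi))
  list(phi = phi[animal, ], p = p, psi = psi,
       mark_occasion = design$mark[animal],
       mark_class = if (design$is_fledgling[animal]) "fledgling" else "adult")
}

#' Log-likelihood of one encounter history by forward recursion
#'
#' Hidden-state forward recursion over \{pre-return, returned, dead\},
#' conditional on marking.  Fledgling-marked animals start in the
#' unobservable pre-return state, adult-marked animals in the returned
#' state.  Within each interval the animal first survives (age-class
#' survival phi), then a surviving pre-return animal of arrival age a
#' returns for the first time with probability psi[a]; detection happens at
#' the arrival occasion with probability p (returned state) or 0
#' (pre-return, dead).  Death is absorbing and the returned state never
#' reverts.
#'
#' @param animal List with \code{mark_occasion}, \code{mark_class} and
#'   \code{detections} (0/1 vector over all occasions).
#' @param params List with \code{phi} (per interval), \code{p} (per
#'   occasion) and \code{psi} (per age, 1-based).
#' @return Log-likelihood of the detections after marking (0 when marked at
#'   the final occasion; \code{-Inf} for an impossible history).
#' @export
individual_loglik <- function(animal, params) {
  y <- animal$detections
  T <- length(y)
  m <- animal$mark_occasion
  if (y[m] != 1L) stop("no detection at marking occasion")
  phi <- params$phi; p <- params$p; psi <- params$psi
  .check_prob <- function(v, nm) {
    v <- v[!is.na(v)]
    if (any(v < 0 | v > 1)) stop(nm, " outside [0, 1]")
  }
  .check_prob(phi, "phi"); .check_prob(p, "p"); .check_prob(psi, "psi")
  if (m == T) return(0)
  a1 <- if (animal$mark_class == "fledgling") 1 else 0
  a2 <- 1 - a1
  aD <- 0
  for (t in m:(T - 1L)) {
    ph <- phi[t]
    if (is.na(ph)) stop("phi undefined at interval ", t)
    age <- t + 1L - m
    ps <- if (animal$mark_class == "fledgling") {
      if (age > length(psi)) 1 else psi[age]
    } else 0
    s1 <- a1 * ph
    s2 <- a2 * ph
    dies <- (a1 + a2) * (1 - ph)
    n1 <- s1 * (1 - ps)
    n2 <- s2 + s1 * ps
    if (y[t + 1L] == 1L) {
      a1 <- 0
      a2 <- n2 * p[t + 1L]
      aD <- 0
    } else {
      a1 <- n1
      a2 <- n2 * (1 - p[t + 1L])
      aD <- aD + dies
    }
  }
  L <- a1 + a2 + aD
  if (L <= 0) -Inf else log(L)
}

#' Log-likelihood of one encounter history by latent-path enumeration
#'
#' Brute-force testing oracle: sums the probability of every latent state
#' sequence \{pre-return, returned, dead\} consistent with the observed
#' detections.  Refuses histories with more than 12 post-marking occasions.
#'
#' @inheritParams individual_loglik
#' @return Log-likelihood, as \code{\link{individual_loglik}}.
#' @export
brute_force_loglik <- function(animal, params) {
  y <- animal$detections
  T <- length(y)
  m <- animal$mark_occasion
  steps <- T - m
  if (steps > 12L) stop("history too long for enumeration (", steps, " steps)")
  if (steps == 0L) return(0)
  phi <- params$phi; p <- params$p; psi <- params$psi
  start <- if (animal$mark_class == "fledgling") 1L else 2L
  # states: 1 pre-return, 2 returned, 3 dead
  paths <- as.matrix(expand.grid(rep(list(1:3), steps)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    pr <- 1
    s <- start
    for (j in seq_len(steps)) {
      t <- m + j - 1L            # interval t -> t+1
      s2 <- paths[r, j]
      age <- t + 1L - m
      ps <- if (age > length(psi)) 1 else psi[age]
      step_pr <-
        if (s == 3L) { if (s2 == 3L) 1 else 0 }
        else if (s == 1L) {
          if (s2 == 3L) 1 - phi[t]
          else if (s2 == 2L) phi[t] * ps
          else phi[t] * (1 - ps)
        } else {
          if (s2 == 3L) 1 - phi[t]
          else if (s2 == 2L) phi[t]
          else 0
        }
      obs <- y[t + 1L]
      emit <- if (s2 == 2L) { if (obs == 1L) p[t + 1L] else 1 - p[t + 1L] }
              else { if (obs == 1L) 0 else 1 }
      pr <- pr * step_pr * emit
      if (pr == 0) break
      s <- s2
    }
    total <- total + pr
  }
  if (total <= 0) -Inf else log(total)
}

# Vectorized dataset log-likelihood: forward recursion run across all
# animals simultaneously.  params from realize_parameters(beta, design).
.dataset_loglik <- function(beta, design) {
  T <- design$calendar$n_occasions
  n <- design$n
  phi <- matrix(stats::plogis(as.vector(design$X_phi %*% beta)),
                T - 1L, n)                       # phi[t, i]
  p <- if (!is.null(design$p_fixed)) rep(design$p_fixed, T)
       else stats::plogis(as.vector(design$X_p %*% beta))
  psi <- stats::plogis(as.vector(design$X_psi %*% beta))
  psi[design$psi_fixed_one] <- 1
  mark <- design$mark
  cache <- design$cache
  a1 <- numeric(n); a2 <- numeric(n); aD <- numeric(n)
  for (t in seq_len(T - 1L)) {
    cc <- cache[[t]]
    if (length(cc$newf)) a1[cc$newf] <- 1
    if (length(cc$newa)) a2[cc$newa] <- 1
    ph <- phi[t, ]
    ps <- psi[cc$psi_idx]
    y <- cc$y
    act <- cc$act
    s1 <- a1 * ph
    trans <- s1 * ps
    n2 <- a2 * ph + trans
    dies <- (a1 + a2) * (1 - ph)
    pp <- p[t + 1L]
    u1 <- (s1 - trans) * (1 - y)
    u2 <- n2 * ((1 - pp) + y * (2 * pp - 1))
    uD <- (aD + dies) * (1 - y)
    a1 <- a1 + act * (u1 - a1)
    a2 <- a2 + act * (u2 - a2)
    aD <- aD + act * (uD - aD)
  }
  L <- a1 + a2 + aD
  L[mark == T] <- 1
  if (any(L <= 0)) return(-Inf)
  sum(log(L))
}

#' Pearson dispersion of detection counts under a fitted model
#'
#' Goodness-of-fit dispersion statistic used by the median c-hat
#' machinery.  Animals are grouped into tagging cohorts (marking occasion
#' by marking class); for every cohort and later occasion the observed
#' detection count is compared with its expectation and exact variance
#' under the fitted model's marginal state distribution (animals
#' independent).  The statistic is the mean of
#' \code{(O - E)^2 / V} over cells; it is near 1 for well-specified
#' independent data and scales with the variance-inflation factor when
#' fates are positively correlated within cohorts.
#'
#' @param fit A \code{cmr_fit}.
#' @return The dispersion statistic (mean Pearson contribution per cell).
#' @export
pearson_dispersion <- function(fit) {
  design <- fit$design
  T <- design$calendar$n_occasions
  n <- design$n
  pars <- realize_parameters(fit$beta_hat, design)
  phi <- pars$phi; phi[is.na(phi)] <- 0
  p <- pars$p; psi <- pars$psi
  mark <- design$mark
  fled <- design$is_fledgling
  # marginal (unconditional) detection probabilities per animal, occasion
  q <- matrix(0, n, T)
  s1 <- as.numeric(fled & mark == 1L)
  s2 <- as.numeric(!fled & mark == 1L)
  for (t in seq_len(T - 1L)) {
    new <- mark == t
    if (t > 1L && any(new)) {
      s1[new & fled] <- 1
      s2[new & !fled] <- 1
    }
    age <- pmin(pmax(t + 1L - mark, 1L), T - 1L)
    ps <- psi[age]
    tr <- s1 * phi[, t] * ps
    s1 <- s1 * phi[, t] - tr
    s2 <- s2 * phi[, t] + tr
    q[, t + 1L] <- s2 * p[t + 1L]
  }
  grp <- interaction(mark, fled, drop = TRUE)
  stat <- 0
  cells <- 0L
  det <- design$detections
  for (g in levels(grp)) {
    idx <- which(grp == g)
    m <- mark[idx[1L]]
    if (m >= T) next
    for (t in (m + 1L):T) {
      E <- sum(q[idx, t])
      V <- sum(q[idx, t] * (1 - q[idx, t]))
      if (V < 1e-8) next
      O <- sum(det[idx, t])
      stat <- stat + (O - E)^2 / V
      cells <- cells + 1L
    }
  }
  if (cells == 0L) stop("no informative cohort-occasion cells")
  stat / cells
}

#' Dataset deviance
#'
#' Minus twice the summed individual log-likelihoods over all encounter
#' histories.  Deviance is defined relative to zero (not to a saturated
#' model); every selection statistic used downstream depends only on
#' deviance differences between models fitted to the same data.
#'
#' @param beta Coefficient vector.
#' @param design A \code{cmr_design} built on the dataset.
#' @return The deviance, \code{-2 * log-likelihood}.
#' @export
dataset_deviance <- function(beta, design) {
  -2 * .dataset_loglik(beta, design)
}

#' Per-animal encounter record from a dataset
#'
#' Convenience accessor returning the list form consumed by
#' \code{\link{individual_loglik}}.
#'
#' @param dataset A \code{cmr_dataset}.
#' @param i Animal index.
#' @return List with \code{animal_id}, \code{mark_occasion},
#'   \code{mark_class}, \code{mass} and \code{detections}.
#' @export
encounter_history <- function(dataset, i) {
  h <- dataset$histories
  list(animal_id = h$animal_id[i],
       mark_occasion = h$mark_occasion[i],
       mark_class = h$mark_class[i],
       mass = h$mass[i],
       detections = as.integer(dataset$detections[i, ]))
}
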