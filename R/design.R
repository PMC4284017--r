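#' Build the coefficient-to-parameter design mapping
#'
#' Translates a \code{\link{model_structure}} into the linear-predictor
#' layout used by the likelihood: one logit-scale design row per estimable
#' real parameter.  Survival rows are indexed by (animal, interval),
#' recapture rows by occasion, first-return rows by age.  Annual covariates
#' enter as z-scores standardized over survival intervals 1..T-1; the
#' individual fledging-mass covariate enters the fledging-year class as the
#' pooled z-score across retained fledglings.  Fixed parameters (detection
#' in the unobservable state, first return above the maximum age, a fixed
#' observable detection value) carry no coefficients.
#'
#' @param structure A \code{model_structure}.
#' @param dataset A \code{cmr_dataset}.
#' @return A \code{cmr_design} holding the design matrices, coefficient
#'   names, fixed-parameter overrides and the standardizers used.
#' @export
build_design <- function(structure, dataset) {
  stopifnot(inherits(structure, "model_structure"),
            inherits(dataset, "cmr_dataset"))
  cal <- dataset$calendar
  T <- cal$n_occasions
  h <- dataset$histories
  n <- nrow(h)
  if (n == 0L) stop("empty dataset")
  sv <- structure$survival
  nc <- sv$n_classes
  mark <- h$mark_occasion
  fled <- h$mark_class == "fledgling"

  # age-class matrix: class of animal i over interval t (NA when t < mark)
  classM <- matrix(NA_integer_, n, T - 1L)
  for (t in seq_len(T - 1L)) {
    ok <- mark <= t
    age <- ifelse(fled, t - mark, NA_integer_)
    cls <- age_class(age, nc)
    cls[!ok] <- NA_integer_
    classM[, t] <- cls
  }
  valid <- !is.na(classM)

  cols <- list()   # each: list(name, phi = n x (T-1) matrix or NULL, p = T vec, psi = (T-1) vec)
  zero_phi <- matrix(0, n, T - 1L)
  add_col <- function(name, phi = NULL, p = NULL, psi = NULL) {
    cols[[length(cols) + 1L]] <<- list(
      name = name,
      phi = if (is.null(phi)) zero_phi else phi,
      p = if (is.null(p)) numeric(T) else p,
      psi = if (is.null(psi)) numeric(T - 1L) else psi)
  }

  # --- survival block ---------------------------------------------------
  classes_present <- sort(unique(classM[valid]))
  for (cc in classes_present) {
    add_col(sprintf("phi_int_c%d", cc), phi = (classM == cc) * 1)
  }
  if (sv$time_effect != "none") {
    if (sv$time_effect == "additive") {
      ts <- sort(unique(which(apply(valid, 2, any))))
      for (t in ts[-1L]) {   # reference: earliest realized interval
        ph <- zero_phi; ph[, t] <- 1
        add_col(sprintf("phi_t%d", t), phi = ph * valid)
      }
    } else {
      for (cc in classes_present) {
        ts <- sort(unique(which(apply(valid & classM == cc, 2, any))))
        for (t in ts[-1L]) {
          add_col(sprintf("phi_t%d_c%d", t, cc),
                  phi = (classM == cc & col(classM) == t) * 1)
        }
      }
    }
  }
  standardizers <- list()
  for (cv in sv$covariates) {
    if (cv$scope == "individual") {
      std <- dataset$mass_standardizer
      if (is.null(std))
        stop("individual covariate '", cv$name,
             "' requires fledgling masses in the dataset")
      if (any(fled & is.na(h$mass)))
        stop("fledglings with missing mass present; run ",
             "filter_missing_mass() before fitting a mass model")
      z <- ifelse(fled, (h$mass - std$center) / std$scale, 0)
      standardizers[[cv$name]] <- std
      add_col(sprintf("phi_%s", cv$name),
              phi = matrix(z, n, T - 1L) * (classM == 1L))
    } else {
      std <- standardized_year_covariate(dataset, cv$name)
      standardizers[[cv$name]] <- std
      zrow <- matrix(std$z, n, T - 1L, byrow = TRUE)
      if (cv$scope == "additive") {
        add_col(sprintf("phi_%s", cv$name), phi = zrow * valid)
      } else {
        for (cc in classes_present)
          add_col(sprintf("phi_%s_c%d", cv$name, cc),
                  phi = zrow * (classM == cc))
      }
    }
  }
  n_phi <- length(cols)

  # --- recapture block --------------------------------------------------
  rc <- structure$recapture
  p_fixed <- NULL
  occ_groups <- NULL
  if (rc$structure == "fixed") {
    p_fixed <- rc$fixed_value
  } else if (rc$structure == "constant") {
    add_col("p_const", p = rep(1, T))
  } else if (rc$structure == "time") {
    for (t in 2:T) {
      v <- numeric(T); v[t] <- 1
      add_col(sprintf("p_occ%d", t), p = v)
    }
  } else {
    yc <- dataset$year_covariates
    if (is.null(yc) || !"gateway_days" %in% names(yc))
      stop("effort-grouped recapture needs a gateway_days covariate column")
    occ_groups <- effort_groups(yc$gateway_days)
    for (g in c("working_well", "intermittent", "not_working")) {
      occs <- which(occ_groups == g)
      occs <- occs[occs >= 2L]            # occasion 1 detection = marking
      if (length(occs) == 0L) next
      v <- numeric(T); v[occs] <- 1
      add_col(sprintf("p_eff_%s", g), p = v)
    }
  }
  n_p <- length(cols) - n_phi

  # --- first-return block ----------------------------------------------
  tr <- structure$transition
  ages <- seq_len(T - 1L)
  psi_fixed_one <- ages > tr$max_age
  est_ages <- ages[!psi_fixed_one]
  if (any(fled) && length(est_ages) > 0L) {
    if (tr$trend == "free") {
      for (a in est_ages) {
        v <- numeric(T - 1L); v[a] <- 1
        add_col(sprintf("psi_a%d", a), psi = v)
      }
    } else {
      xa <- if (tr$trend == "ln") log(ages) else ages
      v0 <- numeric(T - 1L); v0[est_ages] <- 1
      v1 <- numeric(T - 1L); v1[est_ages] <- xa[est_ages]
      add_col("psi_b0", psi = v0)
      add_col("psi_b1", psi = v1)
    }
  }

  k <- length(cols)
  coef_names <- vapply(cols, `[[`, character(1), "name")
  # stack into matrices: X_phi has rows ordered interval-major within animal
  X_phi <- matrix(0, n * (T - 1L), k)
  X_p <- matrix(0, T, k)
  X_psi <- matrix(0, T - 1L, k)
  for (j in seq_len(k)) {
    v <- as.vector(t(cols[[j]]$phi))           # row (i-1)*(T-1)+t
    v[is.na(v)] <- 0                           # pre-marking rows, never used
    X_phi[, j] <- v
    X_p[, j] <- cols[[j]]$p
    X_psi[, j] <- cols[[j]]$psi
  }
  colnames(X_phi) <- colnames(X_p) <- colnames(X_psi) <- coef_names

  # per-interval index cache for the vectorized forward recursion
  det <- dataset$detections
  cache <- vector("list", T - 1L)
  for (t in seq_len(T - 1L)) {
    age <- t + 1L - mark
    cache[[t]] <- list(
      act = as.numeric(mark <= t),
      newf = which(mark == t & fled),
      newa = which(mark == t & !fled),
      psi_idx = pmin(pmax(age, 1L), T - 1L),
      y = as.numeric(det[, t + 1L]))
  }

  structure(list(structure = structure, calendar = cal, n = n, k = k,
                 coef_names = coef_names,
                 X_phi = X_phi, X_p = X_p, X_psi = X_psi,
                 phi_valid = valid, class_matrix = classM,
                 p_fixed = p_fixed, psi_fixed_one = psi_fixed_one,
                 occ_groups = occ_groups,
                 n_phi_coefs = n_phi, n_p_coefs = n_p,
                 mark = mark, is_fledgling = fled,
                 detections = dataset$detections, cache = cache,
                 standardizers = standardizers),
            class = "cmr_design")
}

#' @export
print.cmr_design <- function(x, ...) {
  cat(sprintf("cmr_design: %s\n  %d coefficients over %d animals, %d occasions\n",
              x$structure$label, x$k, x$n, x$calendar$n_occasions))
  cat("  ", paste(x$coef_names, collapse = " "), "\n")
  invisible(x)
}

#' Count structural coefficients of a model on a dataset
#'
#' Returns the length of the coefficient vector after reference-level
#' coding; fixed parameters are excluded.  With \code{check_rank = TRUE} the
#' numeric rank of the stacked realized design rows is compared against the
#' structural count and a warning identifies non-identifiable structures.
#'
#' @param structure A \code{model_structure}.
#' @param dataset A \code{cmr_dataset}.
#' @param check_rank Verify the design has full column rank.
#' @return Integer coefficient count k.
#' @export
count_parameters <- function(structure, dataset, check_rank = FALSE) {
  d <- build_design(structure, dataset)
  if (check_rank && d$k > 0L) {
    rows <- rbind(d$X_phi[as.vector(t(d$phi_valid)), , drop = FALSE],
                  if (is.null(d$p_fixed))
                    d$X_p[-1L, , drop = FALSE],
                  d$X_psi[!d$psi_fixed_one, , drop = FALSE])
    r <- qr(rows)$rank
    if (r < d$k)
      warning("design rank ", r, " < structural coefficient count ", d$k,
              "; structure is not identifiable on this dataset")
  }
  d$k
}
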