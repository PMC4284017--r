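#' Survival (phi) model specification
#'
#' Survival is modelled on the logit scale with 1, 2 or 3 age classes
#' (a1: no age effect; a2: fledging year vs older; a3: fledging year,
#' second year, older), an optional time effect (additive with age class, or
#' interactive: separate year effects per class) and covariates.  Covariate
#' scopes: \code{"individual"} (fledgling-only individual covariate, i.e.
#' fledging mass, entering only the fledging-year class), \code{"additive"}
#' (annual covariate, one slope shared across classes) and
#' \code{"interactive"} (annual covariate, one slope per age class).
#' Adult-marked animals, of unknown age, always occupy the oldest class.
#'
#' @param age_structure One of "a1", "a2", "a3".
#' @param time_effect One of "none", "additive", "interactive".
#' @param covariates List of \code{list(name =, scope =)} entries.
#' @return A \code{survival_spec}.
#' @export
survival_spec <- function(age_structure = "a2", time_effect = "none",
                          covariates = list()) {
  age_structure <- match.arg(age_structure, c("a1", "a2", "a3"))
  time_effect <- match.arg(time_effect, c("none", "additive", "interactive"))
  n_classes <- as.integer(substring(age_structure, 2L))
  if (time_effect == "interactive" && n_classes < 2L)
    stop("interactive time effect requires at least 2 age classes")
  for (cv in covariates) {
    if (!all(c("name", "scope") %in% names(cv)))
      stop("each covariate needs 'name' and 'scope'")
    cv$scope <- match.arg(cv$scope, c("individual", "additive", "interactive"))
    if (cv$scope == "individual" && n_classes < 2L)
      stop("an individual fledgling covariate requires a separate ",
           "fledging-year age class (a2 or a3)")
  }
  structure(list(age_structure = age_structure, n_classes = n_classes,
                 time_effect = time_effect, covariates = covariates),
            class = "survival_spec")
}

#' Recapture (p) model specification
#'
#' Detection probability of animals in the unobservable pre-return state is
#' identically zero and never estimated.  For the observable state the
#' structure is per-year (\code{"time"}), grouped by gateway-reader effort
#' (\code{"effort"}: 0 days, 1-100 days, >100 days of operation),
#' \code{"constant"}, or \code{"fixed"} at a known value (useful in tests
#' and reductions).
#'
#' @param structure One of "effort", "time", "constant", "fixed".
#' @param fixed_value Detection probability when \code{structure = "fixed"}.
#' @return A \code{recapture_spec}.
#' @export
recapture_spec <- function(structure = "effort", fixed_value = NULL) {
  structure <- match.arg(structure, c("effort", "time", "constant", "fixed"))
  if (structure == "fixed") {
    if (is.null(fixed_value) || fixed_value < 0 || fixed_value > 1)
      stop("fixed recapture structure needs fixed_value in [0, 1]")
  } else fixed_value <- NULL
  structure(list(structure = structure, fixed_value = fixed_value),
            class = "recapture_spec")
}

#' First-return transition (psi) model specification
#'
#' Psi[a] is the probability that a surviving bird first returns to the
#' colony at age a.  Ages 1..max_age are estimated (free one-per-age, or a
#' 2-parameter linear / natural-log age trend on the logit scale); the
#' return probability above max_age is fixed to one, and the reverse
#' transition (observable back to unobservable) is fixed to zero.
#'
#' @param max_age Oldest estimated age of first return (3, 4 or 5).
#' @param trend One of "free", "linear", "ln".
#' @return A \code{transition_spec}.
#' @export
transition_spec <- function(max_age = 4L, trend = "free") {
  max_age <- as.integer(max_age)
  if (max_age < 1L) stop("max_age must be >= 1")
  trend <- match.arg(trend, c("free", "linear", "ln"))
  structure(list(max_age = max_age, trend = trend),
            class = "transition_spec")
}

#' Full model structure
#'
#' Combines survival, recapture and transition specifications; the canonical
#' label round-trips through \code{\link{parse_model_label}}.
#'
#' @param survival A \code{survival_spec}.
#' @param recapture A \code{recapture_spec}.
#' @param transition A \code{transition_spec}.
#' @return A \code{model_structure} with a canonical \code{label}.
#' @export
model_structure <- function(survival = survival_spec(),
                            recapture = recapture_spec(),
                            transition = transition_spec()) {
  stopifnot(inherits(survival, "survival_spec"),
            inherits(recapture, "recapture_spec"),
            inherits(transition, "transition_spec"))
  x <- structure(list(survival = survival, recapture = recapture,
                      transition = transition),
                 class = "model_structure")
  x$label <- model_label(x)
  x
}

#' @export
print.model_structure <- function(x, ...) {
  cat("model_structure:", x$label, "\n")
  invisible(x)
}

#' Canonical model label
#'
#' Notation: \code{phi(<age> [time] [covariates]) p(<structure>)
#' psi(<max> [trend])}.  Time tokens: \code{t} (a1), \code{a+t} (additive),
#' \code{a*t} (interactive).  Covariate tokens: bare name for an additive
#' annual covariate, \code{name*a} for interactive, \code{name:i} for an
#' individual fledgling covariate.  p tokens: \code{t}, \code{T3}, \code{.},
#' \code{=v} (fixed at v).  psi trend tokens: \code{ln}, \code{lin}.
#'
#' @param structure A \code{model_structure}.
#' @return The label string.
#' @export
model_label <- function(structure) {
  sv <- structure$survival
  toks <- sv$age_structure
  if (sv$time_effect == "additive")
    toks <- c(toks, if (sv$n_classes == 1L) "t" else "a+t")
  if (sv$time_effect == "interactive") toks <- c(toks, "a*t")
  for (cv in sv$covariates) {
    toks <- c(toks, switch(cv$scope,
                           individual = paste0(cv$name, ":i"),
                           additive = cv$name,
                           interactive = paste0(cv$name, "*a")))
  }
  rc <- structure$recapture
  ptok <- switch(rc$structure,
                 time = "t", effort = "T3", constant = ".",
                 fixed = sprintf("=%g", rc$fixed_value))
  tr <- structure$transition
  psitok <- as.character(tr$max_age)
  if (tr$trend == "ln") psitok <- paste(psitok, "ln")
  if (tr$trend == "linear") psitok <- paste(psitok, "lin")
  sprintf("phi(%s) p(%s) psi(%s)", paste(toks, collapse = " "), ptok, psitok)
}

#' Parse a canonical model label
#'
#' Inverse of \code{\link{model_label}}.
#'
#' @param label A label string such as
#'   \code{"phi(a2 a+t mass:i pred*a) p(T3) psi(4 ln)"}.
#' @return A \code{model_structure}.
#' @export
parse_model_label <- function(label) {
  m <- regmatches(label,
                  regexec("^phi\\((.*)\\) p\\((.*)\\) psi\\((.*)\\)$", label))[[1]]
  if (length(m) != 4L) stop("unparseable model label: ", label)
  phitoks <- strsplit(trimws(m[2]), "\\s+")[[1]]
  if (!phitoks[1] %in% c("a1", "a2", "a3"))
    stop("phi() must start with an age structure token: ", label)
  age <- phitoks[1]
  time_effect <- "none"
  covs <- list()
  for (tok in phitoks[-1]) {
    if (tok %in% c("t", "a+t")) time_effect <- "additive"
    else if (tok == "a*t") time_effect <- "interactive"
    else if (grepl(":i$", tok))
      covs <- c(covs, list(list(name = sub(":i$", "", tok),
                                scope = "individual")))
    else if (grepl("\\*a$", tok))
      covs <- c(covs, list(list(name = sub("\\*a$", "", tok),
                                scope = "interactive")))
    else covs <- c(covs, list(list(name = tok, scope = "additive")))
  }
  ptok <- trimws(m[3])
  rec <- if (ptok == "t") recapture_spec("time")
         else if (ptok == "T3") recapture_spec("effort")
         else if (ptok == ".") recapture_spec("constant")
         else if (startsWith(ptok, "="))
           recapture_spec("fixed", as.numeric(substring(ptok, 2L)))
         else stop("unknown p() token: ", ptok)
  psitoks <- strsplit(trimws(m[4]), "\\s+")[[1]]
  trend <- "free"
  if (length(psitoks) > 1L)
    trend <- switch(psitoks[2], ln = "ln", lin = "linear",
                    stop("unknown psi trend token: ", psitoks[2]))
  model_structure(survival_spec(age, time_effect, covs), rec,
                  transition_spec(as.integer(psitoks[1]), trend))
}

#' Age class of an animal at a given interval
#'
#' Age is occasion minus marking occasion for fledgling-marked animals
#' (age 0 in the fledging year); adult-marked animals map to the oldest
#' class at every interval.  The class is that of the age at the start of
#' the survival interval.
#'
#' @param age Age in years at the start of the interval (NA for adults).
#' @param n_classes 1, 2 or 3.
#' @return Integer class index in 1..n_classes.
#' @export
age_class <- function(age, n_classes) {
  if (n_classes == 1L) return(rep(1L, length(age)))
  cls <- rep(n_classes, length(age))
  cls[!is.na(age) & age == 0L] <- 1L
  if (n_classes == 3L) cls[!is.na(age) & age == 1L] <- 2L
  cls
}

#' Gateway effort groups
#'
#' Maps annual gateway-reader operation days to the three detection-effort
#' levels: \code{not_working} (0 days), \code{intermittent} (1-100 days) and
#' \code{working_well} (more than 100 days).
#'
#' @param gateway_days Nonnegative numeric vector of operation days.
#' @return Character vector of group names, same length.
#' @export
effort_groups <- function(gateway_days) {
  if (anyNA(gateway_days) || any(gateway_days < 0))
    stop("gateway_days must be nonnegative and complete")
  ifelse(gateway_days == 0, "not_working",
         ifelse(gateway_days <= 100, "intermittent", "working_well"))
}

#' Enumerate candidate model structures
#'
#' Generates, in deterministic order, the cross of survival age/time
#' structures, recapture structures and first-return maxima/trends screened
#' during structural model selection.
#'
#' @param ages Age structures to include.
#' @param time_effects Time effects on survival.
#' @param p_structures Recapture structures.
#' @param psi_max First-return maxima.
#' @param psi_trends First-return trends.
#' @return List of \code{model_structure} objects.
#' @export
enumerate_candidates <- function(ages = c("a1", "a2", "a3"),
                                 time_effects = c("additive", "interactive"),
                                 p_structures = c("time", "effort", "constant"),
                                 psi_max = c(3L, 4L, 5L),
                                 psi_trends = c("free", "ln", "linear")) {
  out <- list()
  for (age in ages) {
    tes <- if (age == "a1") "additive" else time_effects
    for (te in unique(tes)) for (ps in p_structures)
      for (mx in psi_max) for (tr in psi_trends) {
        if (tr != "free" && mx < 2L) next
        out[[length(out) + 1L]] <-
          model_structure(survival_spec(age, te),
                          recapture_spec(ps),
                          transition_spec(mx, tr))
      }
  }
  out
}
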