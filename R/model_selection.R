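#' Rank fitted models by (Q)AICc with the parsimony rule
#'
#' Sorts candidate fits by QAICc (AICc when \code{c_hat = 1} and
#' \code{use_qaicc = FALSE}) and applies the selection rule: models within
#' 2 units of the best receive similar support, and among those the model
#' with the fewest parameters wins; ties break by label order.
#'
#' @param fits List of \code{cmr_fit} objects on the same dataset.
#' @param c_hat Overdispersion factor applied to every candidate.
#' @param use_qaicc Rank by QAICc (default) or plain AICc.
#' @return A \code{ranking_table} data frame (label, criterion, delta, k,
#'   deviance) with the winner flagged.
#' @export
rank_models <- function(fits, c_hat = 1, use_qaicc = c_hat > 1) {
  if (length(fits) == 0L) stop("no fits to rank")
  ess <- vapply(fits, `[[`, numeric(1), "ess")
  if (length(unique(ess)) != 1L)
    stop("fits come from datasets of different sizes; rank within one dataset")
  crit <- vapply(fits, function(f) {
    ic <- information_criteria(f, c_hat)
    if (use_qaicc) ic$qaicc else ic$aicc
  }, numeric(1))
  tab <- data.frame(
    label = vapply(fits, function(f) f$structure$label, character(1)),
    criterion = crit,
    k = vapply(fits, `[[`, numeric(1), "k"),
    deviance = vapply(fits, `[[`, numeric(1), "deviance"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE)
  ord <- order(tab$criterion, tab$k, tab$label)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab$delta <- tab$criterion - tab$criterion[1L]
  close <- which(tab$delta <= 2)
  win <- close[order(tab$k[close], tab$label[close])][1L]
  tab$selected <- seq_len(nrow(tab)) == win
  attr(tab, "criterion") <- if (use_qaicc) "QAICc" else "AICc"
  attr(tab, "c_hat") <- c_hat
  class(tab) <- c("ranking_table", "data.frame")
  tab
}

#' @export
print.ranking_table <- function(x, ...) {
  cat(sprintf("Model ranking by %s (c-hat %.3g)\n",
              attr(x, "criterion"), attr(x, "c_hat")))
  df <- as.data.frame(x)
  df$criterion <- round(df$criterion, 2)
  df$delta <- round(df$delta, 2)
  df$deviance <- round(df$deviance, 2)
  print(df)
  invisible(x)
}

#' Structure label of the model selected by a ranking
#' @param ranking A \code{ranking_table}.
#' @return The selected label string.
#' @export
selected_model <- function(ranking) ranking$label[ranking$selected][1L]

#' Likelihood ratio test between nested fits
#'
#' Chi-square statistic is the deviance difference, degrees of freedom the
#' coefficient-count difference.  A materially negative statistic signals
#' an optimization failure of the general model and is an error; tiny
#' negative values from numerical noise are clamped to zero.
#'
#' @param nested_fit Fit of the restricted model.
#' @param general_fit Fit of the general model (superset of coefficients).
#' @return List with \code{chi2}, \code{df}, \code{p}.
#' @export
likelihood_ratio_test <- function(nested_fit, general_fit) {
  if (nested_fit$ess != general_fit$ess)
    stop("fits are not on the same dataset")
  chi2 <- nested_fit$deviance - general_fit$deviance
  df <- general_fit$k - nested_fit$k
  if (df < 0) stop("general model has fewer coefficients than nested model")
  if (chi2 < -1e-4)
    stop("negative LRT statistic (", format(chi2),
         "): the general model is underfitted, refit with more restarts")
  chi2 <- max(chi2, 0)
  p <- if (df == 0L) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Analysis of deviance for an annual covariate
#'
#' Compares nested fits with constant, covariate and full temporal
#' variation in survival.  The deviance fraction
#' \code{r2_dev = [DEV(.) - DEV(cov)] / [DEV(.) - DEV(t)]} measures the
#' share of temporal deviance the covariate captures; the F statistic is
#' \code{([DEV(.) - DEV(cov)]/df1) / ([DEV(cov) - DEV(t)]/df2)} with
#' \code{df1 = k(cov) - k(.)} and \code{df2 = k(t) - k(cov)}.  A covariate
#' explaining more than 20 percent of the temporal deviance is conventionally
#' taken as influential.
#'
#' @param fit_constant Fit with no temporal variation (beyond covariates
#'   already retained).
#' @param fit_covariate Fit adding the candidate covariate.
#' @param fit_timedep Fit with full year effects.
#' @return List with \code{F}, \code{df1}, \code{df2}, \code{p},
#'   \code{r2_dev}.
#' @export
anodev <- function(fit_constant, fit_covariate, fit_timedep) {
  d0 <- fit_constant$deviance
  dc <- fit_covariate$deviance
  dt <- fit_timedep$deviance
  if (abs(d0 - dt) < 1e-8)
    stop("constant and time-dependent deviances coincide; ",
         "no temporal deviance to explain")
  df1 <- fit_covariate$k - fit_constant$k
  df2 <- fit_timedep$k - fit_covariate$k
  if (df1 <= 0 || df2 <= 0)
    stop("models are not strictly nested (df1 = ", df1, ", df2 = ", df2, ")")
  r2 <- (d0 - dc) / (d0 - dt)
  Fst <- ((d0 - dc) / df1) / ((dc - dt) / df2)
  p <- if (is.finite(Fst) && Fst >= 0)
    stats::pf(Fst, df1, df2, lower.tail = FALSE) else NA_real_
  list(F = Fst, df1 = df1, df2 = df2, p = p, r2_dev = r2)
}

# append a covariate to a survival spec
.add_covariate <- function(structure, name, scope) {
  sv <- structure$survival
  covs <- c(sv$covariates, list(list(name = name, scope = scope)))
  model_structure(survival_spec(sv$age_structure, sv$time_effect, covs),
                  structure$recapture, structure$transition)
}

# the full-temporal reference model: current individual covariates kept,
# annual covariates replaced by year effects.  The year effects enter
# interactively with age class when candidate covariates may do so, so the
# reference always nests the covariate models.
.time_reference <- function(base_structure, individual_retained,
                            interactive = FALSE) {
  sv <- base_structure$survival
  covs <- Filter(function(cv) cv$scope == "individual", sv$covariates)
  covs <- c(covs, individual_retained)
  te <- if (interactive && sv$n_classes >= 2L) "interactive" else "additive"
  model_structure(survival_spec(sv$age_structure, te, covs),
                  base_structure$recapture, base_structure$transition)
}

# zero start vector with entries copied from a previous fit by name
.warm_start <- function(coef_names, beta_old) {
  v <- stats::setNames(numeric(length(coef_names)), coef_names)
  common <- intersect(coef_names, names(beta_old))
  v[common] <- beta_old[common]
  v
}

#' Step-up covariate selection on survival
#'
#' Implements the step-up protocol: the constant base model is fitted
#' first; individual covariates (fledging mass) are tested in isolation by
#' likelihood ratio test and retained when significant; then, at each
#' step, every remaining annual covariate is fitted on top of the current
#' model (entering additively or interactively with age class, the better
#' form chosen by QAICc), its ANODEV is computed against the current model
#' as the constant reference and the full additive-year model as the
#' temporal reference, and the candidate explaining the largest fraction
#' of the remaining temporal deviance is retained if that fraction exceeds
#' the threshold; otherwise the procedure stops.  Ties break by fewer
#' parameters, then label order.  Scope can be forced per covariate (e.g.
#' to keep a predation-by-age interaction on extra-statistical grounds).
#'
#' @param dataset A \code{cmr_dataset}.
#' @param base_structure The covariate-free \code{model_structure} (its
#'   survival time effect is ignored; the base is fitted time-constant).
#' @param individual_covariates Character vector of individual covariates
#'   to test by LRT (only \code{"mass"} is defined).
#' @param annual_covariates Character vector of annual covariate names.
#' @param c_hat Overdispersion factor for the QAICc entry-form choice.
#' @param r2_threshold Retention threshold on \code{r2_dev}.
#' @param alpha LRT significance level for individual covariates.
#' @param forced_scope Named list forcing the entry scope ("additive" or
#'   "interactive") of specific annual covariates.
#' @param compare_entry Try both additive and interactive entry and pick
#'   by QAICc (FALSE: additive only).
#' @param max_annual_steps Cap on the number of annual-covariate steps
#'   (useful in simulation studies that only need the first selection).
#' @param fit_options List passed to \code{\link{fit_model}}
#'   (\code{n_restarts}, \code{seed}).
#' @return A \code{selection_record} data frame, one row per step.
#' @export
step_up_selection <- function(dataset, base_structure,
                              individual_covariates = character(),
                              annual_covariates = character(),
                              c_hat = 1, r2_threshold = 0.20, alpha = 0.05,
                              forced_scope = list(),
                              compare_entry = TRUE,
                              max_annual_steps = Inf,
                              fit_options = list(n_restarts = 2L, seed = 1L)) {
  fit1 <- function(str, warm_from = NULL) {
    start <- if (!is.null(warm_from))
      .warm_start(build_design(str, dataset)$coef_names,
                  warm_from$beta_hat)
    do.call(fit_model, c(list(structure = str, dataset = dataset,
                              start = start), fit_options))
  }
  sv <- base_structure$survival
  base <- model_structure(survival_spec(sv$age_structure, "none", list()),
                          base_structure$recapture, base_structure$transition)
  current_fit <- fit1(base)
  rec <- list()
  add_rec <- function(step, covariate, scope, test, statistic, df, p, r2,
                      retained, label, k) {
    rec[[length(rec) + 1L]] <<- data.frame(
      step = step, covariate = covariate, scope = scope, test = test,
      statistic = statistic, df = df, p = p, r2_dev = r2,
      retained = retained, label = label, k = k, stringsAsFactors = FALSE)
  }
  add_rec(1L, "(base)", "", "", NA_real_, NA_integer_, NA_real_, NA_real_,
          TRUE, current_fit$structure$label, current_fit$k)
  step <- 1L
  individual_retained <- list()
  for (nm in individual_covariates) {
    step <- step + 1L
    cand <- .add_covariate(current_fit$structure, nm, "individual")
    cand_fit <- fit1(cand, warm_from = current_fit)
    lrt <- likelihood_ratio_test(current_fit, cand_fit)
    keep <- lrt$p < alpha
    add_rec(step, nm, "individual", "LRT", lrt$chi2, lrt$df, lrt$p,
            NA_real_, keep, cand$label, cand_fit$k)
    if (keep) {
      current_fit <- cand_fit
      individual_retained <- c(individual_retained,
                               list(list(name = nm, scope = "individual")))
    }
  }
  remaining <- annual_covariates
  annual_steps <- 0L
  time_fit <- NULL
  while (length(remaining) > 0L && annual_steps < max_annual_steps) {
    annual_steps <- annual_steps + 1L
    if (is.null(time_fit)) {
      use_int <- compare_entry ||
        any(vapply(forced_scope, identical, logical(1), "interactive"))
      time_fit <- fit1(.time_reference(base, individual_retained,
                                       interactive = use_int),
                       warm_from = current_fit)
    }
    cands <- list()
    for (nm in remaining) {
      scopes <- if (!is.null(forced_scope[[nm]])) forced_scope[[nm]]
                else if (compare_entry) c("additive", "interactive")
                else "additive"
      if (base_structure$survival$n_classes < 2L)
        scopes <- setdiff(scopes, "interactive")
      fits <- list()
      for (sc in scopes) {
        str <- .add_covariate(current_fit$structure, nm, sc)
        ft <- try(fit1(str, warm_from = current_fit), silent = TRUE)
        if (!inherits(ft, "try-error")) fits[[sc]] <- ft
      }
      if (length(fits) == 0L) {
        warning("all fits failed for candidate '", nm, "'; skipped")
        next
      }
      qa <- vapply(fits, function(f)
        information_criteria(f, c_hat)$qaicc, numeric(1))
      ft <- fits[[which.min(qa)]]
      an <- anodev(current_fit, ft, time_fit)
      cands[[nm]] <- list(fit = ft, anodev = an,
                          scope = names(fits)[which.min(qa)])
    }
    if (length(cands) == 0L) break
    r2s <- vapply(cands, function(cd) cd$anodev$r2_dev, numeric(1))
    ks <- vapply(cands, function(cd) cd$fit$k, numeric(1))
    lbl <- vapply(cands, function(cd) cd$fit$structure$label, character(1))
    best <- order(-r2s, ks, lbl)[1L]
    cd <- cands[[best]]
    nm <- names(cands)[best]
    step <- step + 1L
    keep <- cd$anodev$r2_dev > r2_threshold
    add_rec(step, nm, cd$scope, "ANODEV", cd$anodev$F,
            cd$anodev$df1, cd$anodev$p, cd$anodev$r2_dev, keep,
            cd$fit$structure$label, cd$fit$k)
    if (!keep) break
    current_fit <- cd$fit
    remaining <- setdiff(remaining, nm)
  }
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  attr(out, "final_fit") <- current_fit
  class(out) <- c("selection_record", "data.frame")
  out
}

#' Final fit retained by a step-up procedure
#' @param records A \code{selection_record}.
#' @return The \code{cmr_fit} of the last retained model.
#' @export
final_fit <- function(records) attr(records, "final_fit")

#' Wald confidence interval for a fitted coefficient
#'
#' Confidence interval on the logit scale from the (c-hat inflated)
#' coefficient covariance, with a flag for whether it excludes zero —
#' the convention for verifying retained covariates.
#'
#' @param fit A \code{cmr_fit} (inflate with \code{\link{inflate_by_chat}}
#'   first if an overdispersion adjustment applies).
#' @param covariate_name Coefficient name (e.g. \code{"phi_mass"}).
#' @param level Confidence level.
#' @return List with \code{estimate}, \code{se}, \code{ci_low},
#'   \code{ci_high}, \code{excludes_zero}.
#' @export
verify_coefficient <- function(fit, covariate_name, level = 0.95) {
  if (!covariate_name %in% names(fit$beta_hat))
    stop("no coefficient named '", covariate_name, "' in the fit")
  est <- fit$beta_hat[[covariate_name]]
  se <- sqrt(fit$vcov[covariate_name, covariate_name])
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- est - z * se
  hi <- est + z * se
  list(estimate = est, se = se, ci_low = lo, ci_high = hi,
       excludes_zero = is.finite(lo) && is.finite(hi) && (lo > 0 || hi < 0))
}
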