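#' Protocol configuration
#'
#' Options driving \code{\link{run_protocol}}.  Defaults mirror the
#' analysis protocol of the penguin study: a global model with three age
#' classes, age-by-year interactive survival, fully time-dependent
#' detection and free first return through age 5; median c-hat
#' goodness-of-fit with lack of fit flagged above 3; structural selection
#' over first-return maxima/trends, then detection structures, then
#' survival age/time structures; and step-up covariate selection with the
#' 20 percent deviance-fraction threshold.
#'
#' @param seed Top-level seed; every stochastic stage derives its seed
#'   from it.
#' @param global_label Label of the global model.
#' @param chat_replicates,chat_grid_points,chat_bounds Median c-hat
#'   settings.
#' @param c_hat Fixed overdispersion factor; when non-NULL the c-hat
#'   stage is skipped.
#' @param psi_candidates Transition candidates, as
#'   \code{list(list(max =, trend =))}.
#' @param p_candidates Recapture structures to screen.
#' @param survival_candidates Survival age/time candidates, as
#'   \code{list(list(age =, time =))}.
#' @param individual_covariates,annual_covariates Covariates for the
#'   step-up stage.
#' @param forced_scope Forced entry scopes (see
#'   \code{\link{step_up_selection}}).
#' @param compare_entry Compare additive vs interactive covariate entry by
#'   QAICc.
#' @param r2_threshold,alpha Step-up retention thresholds.
#' @param n_restarts Optimizer restarts per fit.
#' @return A named list of settings.
#' @export
protocol_config <- function(seed = 1L,
                            global_label = "phi(a3 a*t) p(t) psi(5)",
                            chat_replicates = 100L,
                            chat_grid_points = 7L,
                            chat_bounds = c(1, 4),
                            c_hat = NULL,
                            psi_candidates = list(
                              list(max = 3L, trend = "free"),
                              list(max = 4L, trend = "free"),
                              list(max = 5L, trend = "free"),
                              list(max = 4L, trend = "ln"),
                              list(max = 4L, trend = "linear")),
                            p_candidates = c("time", "effort", "constant"),
                            survival_candidates = list(
                              list(age = "a1", time = "additive"),
                              list(age = "a2", time = "additive"),
                              list(age = "a2", time = "interactive"),
                              list(age = "a3", time = "additive"),
                              list(age = "a3", time = "interactive")),
                            individual_covariates = "mass",
                            annual_covariates = c("pred_pressure",
                                                  "lsst_lag1"),
                            forced_scope = list(),
                            compare_entry = TRUE,
                            r2_threshold = 0.20,
                            alpha = 0.05,
                            n_restarts = 2L) {
  list(seed = as.integer(seed), global_label = global_label,
       chat_replicates = chat_replicates,
       chat_grid_points = chat_grid_points, chat_bounds = chat_bounds,
       c_hat = c_hat,
       psi_candidates = psi_candidates, p_candidates = p_candidates,
       survival_candidates = survival_candidates,
       individual_covariates = individual_covariates,
       annual_covariates = annual_covariates,
       forced_scope = forced_scope, compare_entry = compare_entry,
       r2_threshold = r2_threshold, alpha = alpha,
       n_restarts = n_restarts)
}

.fit_summary <- function(fit) {
  list(label = fit$structure$label,
       beta = as.list(fit$beta_hat),
       se = as.list(sqrt(diag(fit$vcov))),
       deviance = fit$deviance, k = fit$k, ess = fit$ess,
       converged = fit$converged)
}

#' Run the full analysis protocol
#'
#' Executes, in order: (1) global-model fit; (2) median c-hat
#' goodness-of-fit (lack of fit flagged when c-hat > 3); (3) structural
#' selection by QAICc with the parsimony rule — first-return structure,
#' then detection structure, then survival age/time structure; (4)
#' step-up covariate selection on the winning structure; (5) Wald
#' verification of retained coefficients under the c-hat-inflated
#' covariance; (6) derived quantities: temporal process variance per age
#' class, covariate sensitivities and the cumulative first-return curve.
#' A stage failure is recorded and dependent stages are skipped with
#' explicit markers.
#'
#' @param dataset A validated \code{cmr_dataset}.
#' @param config A \code{\link{protocol_config}} list.
#' @return A \code{protocol_report} list.
#' @export
run_protocol <- function(dataset, config = protocol_config()) {
  report <- list(seed = config$seed, n_animals = n_animals(dataset),
                 stages = list(), models = list())
  fits <- list()
  fit1 <- function(label_or_str) {
    key <- if (is.character(label_or_str)) label_or_str
           else label_or_str$label
    if (!is.null(fits[[key]])) return(fits[[key]])
    ft <- fit_model(label_or_str, dataset, n_restarts = config$n_restarts,
                    seed = config$seed)
    fits[[key]] <<- ft
    report$models[[key]] <<- .fit_summary(ft)
    ft
  }
  # 1. global model -------------------------------------------------------
  global_fit <- tryCatch(fit1(config$global_label), error = function(e) e)
  if (inherits(global_fit, "error")) {
    report$stages$global <- paste("failed:", conditionMessage(global_fit))
    return(structure(report, class = "protocol_report"))
  }
  report$stages$global <- "ok"
  report$global <- .fit_summary(global_fit)
  # 2. median c-hat --------------------------------------------------------
  if (!is.null(config$c_hat)) {
    c_hat <- config$c_hat
    report$stages$chat <- "fixed by config"
  } else {
    chat <- tryCatch(
      estimate_median_chat(global_fit, bounds = config$chat_bounds,
                           replicates = config$chat_replicates,
                           grid_points = config$chat_grid_points,
                           seed = config$seed),
      error = function(e) e)
    if (inherits(chat, "error")) {
      report$stages$chat <- paste("failed:", conditionMessage(chat))
      c_hat <- 1
    } else {
      report$stages$chat <- "ok"
      report$chat <- list(c_hat = chat$c_hat, se = chat$se,
                          replicates = chat$replicates,
                          lack_of_fit = chat$lack_of_fit)
      c_hat <- max(1, chat$c_hat)
    }
  }
  report$c_hat_used <- c_hat
  # 3. structural selection ------------------------------------------------
  parse <- parse_model_label
  g <- parse(config$global_label)
  stage_rank <- function(cands) {
    fl <- lapply(cands, fit1)
    rank_models(fl, c_hat = c_hat)
  }
  res <- tryCatch({
    psis <- lapply(config$psi_candidates, function(pc)
      model_structure(g$survival, g$recapture,
                      transition_spec(pc$max, pc$trend)))
    r_psi <- stage_rank(psis)
    best_psi <- parse(selected_model(r_psi))$transition
    ps <- lapply(config$p_candidates, function(pp)
      model_structure(g$survival, recapture_spec(pp), best_psi))
    r_p <- stage_rank(ps)
    best_p <- parse(selected_model(r_p))$recapture
    svs <- lapply(config$survival_candidates, function(sc)
      model_structure(survival_spec(sc$age, sc$time), best_p, best_psi))
    r_sv <- stage_rank(svs)
    list(r_psi = r_psi, r_p = r_p, r_sv = r_sv,
         winner = parse(selected_model(r_sv)))
  }, error = function(e) e)
  if (inherits(res, "error")) {
    report$stages$structural <- paste("failed:", conditionMessage(res))
    return(structure(report, class = "protocol_report"))
  }
  report$stages$structural <- "ok"
  report$ranking <- list(transition = as.data.frame(res$r_psi),
                         recapture = as.data.frame(res$r_p),
                         survival = as.data.frame(res$r_sv))
  report$ranking_all <- as.data.frame(
    rank_models(fits, c_hat = c_hat))
  report$selected_structure <- res$winner$label
  # 4. step-up covariate selection -----------------------------------------
  sel <- tryCatch(
    step_up_selection(dataset, res$winner,
                      individual_covariates = config$individual_covariates,
                      annual_covariates = config$annual_covariates,
                      c_hat = c_hat, r2_threshold = config$r2_threshold,
                      alpha = config$alpha,
                      forced_scope = config$forced_scope,
                      compare_entry = config$compare_entry,
                      fit_options = list(n_restarts = config$n_restarts,
                                         seed = config$seed)),
    error = function(e) e)
  if (inherits(sel, "error")) {
    report$stages$step_up <- paste("failed:", conditionMessage(sel))
    return(structure(report, class = "protocol_report"))
  }
  report$stages$step_up <- "ok"
  report$selection <- as.data.frame(sel)
  fin <- inflate_by_chat(final_fit(sel), c_hat)
  report$final_model <- .fit_summary(fin)
  # 5. coefficient verification --------------------------------------------
  cn <- grep("^phi_(?!int_|t[0-9])", names(fin$beta_hat),
             perl = TRUE, value = TRUE)
  report$coefficients <- lapply(cn, function(nm) {
    ci <- verify_coefficient(fin, nm)
    c(list(name = nm), ci)
  })
  # 6. derived quantities ---------------------------------------------------
  report$stages$derived <- "ok"
  der <- tryCatch({
    sv <- fin$structure$survival
    # fin's survival spec already carries the retained individual covariates
    time_ref <- .time_reference(fin$structure, list())
    tfit <- fit1(time_ref)
    pv <- list()
    for (ac in seq_len(sv$n_classes)) {
      ann <- annual_survival(tfit, ac)
      ann <- ann[ann$usable, , drop = FALSE]
      pv[[sprintf("class_%d", ac)]] <- if (nrow(ann) >= 3L) {
        vc <- variance_components(ann$estimate, ann$var)
        list(mean = vc$mean, se_mean = vc$se_mean,
             sigma_process = vc$sigma_process,
             n_years = nrow(ann))
      } else "too few identifiable annual estimates"
    }
    psihat <- realize_parameters(fin$beta_hat, fin$design)$psi
    maxa <- fin$structure$transition$max_age
    list(process_variance = pv,
         sensitivity = sensitivity_table(fin),
         first_return = data.frame(
           age = seq_len(maxa + 1L),
           cumulative = cumulative_first_return(
             psihat[seq_len(min(maxa, length(psihat)))],
             through_age = maxa + 1L)))
  }, error = function(e) {
    report$stages$derived <<- paste("failed:", conditionMessage(e))
    NULL
  })
  if (!is.null(der)) {
    report$process_variance <- der$process_variance
    report$sensitivity <- der$sensitivity
    report$first_return <- der$first_return
  }
  structure(report, class = "protocol_report")
}

#' @export
print.protocol_report <- function(x, ...) {
  cat("protocol_report\n")
  cat("  stages:", paste(sprintf("%s=%s", names(x$stages),
                                 unlist(x$stages)), collapse = "; "), "\n")
  if (!is.null(x$c_hat_used))
    cat(sprintf("  c-hat used: %.3f\n", x$c_hat_used))
  if (!is.null(x$selected_structure))
    cat("  selected structure:", x$selected_structure, "\n")
  if (!is.null(x$selection)) {
    cat("  step-up:\n")
    print(x$selection[, c("step", "covariate", "test", "statistic",
                          "p", "r2_dev", "retained")])
  }
  invisible(x)
}

#' Write a protocol report to JSON
#'
#' @param report A \code{protocol_report}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_protocol_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null",
                       force = TRUE)
  invisible(path)
}

#' Render a protocol report as text tables
#'
#' Plain-text rendering of the ranking, step-up and sensitivity tables in
#' the style of a published model-selection summary.
#'
#' @param report A \code{protocol_report}.
#' @return Character vector of lines.
#' @export
format_protocol_report <- function(report) {
  out <- c("Analysis protocol report",
           sprintf("seed %d, %d animals", report$seed, report$n_animals),
           sprintf("c-hat used: %s",
                   format(report$c_hat_used %||% NA, digits = 4)))
  if (!is.null(report$ranking_all)) {
    out <- c(out, "", "Model ranking:",
             utils::capture.output(print(report$ranking_all)))
  }
  if (!is.null(report$selection)) {
    out <- c(out, "", "Step-up covariate selection:",
             utils::capture.output(print(report$selection)))
  }
  if (!is.null(report$sensitivity)) {
    out <- c(out, "", "Covariate sensitivities:",
             utils::capture.output(print(report$sensitivity)))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
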