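# Reading and writing the pipeline's file formats: long-format observation
# CSV, model configuration (YAML/JSON), fitted-model JSON, cohort bundles.

#' Read long-format observation data
#'
#' @param path CSV file with columns `subject_id`, `age`, `state`,
#'   `obs_type` and covariate columns.
#' @param validate Run [validate_histories()] (default TRUE).
#' @return A data frame.
#' @export
read_observations <- function(path, validate = TRUE) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  data$subject_id <- as.character(data$subject_id)
  if (validate) validate_histories(data)
  data
}

#' Write long-format observation data
#'
#' @param data Observation data frame.
#' @param path Output CSV path.
#' @export
write_observations <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a model specification from YAML or JSON
#'
#' The file may contain the fields of [model_spec()]: `transitions`,
#' `covariates` (vector, or mapping keyed by transition), `refs`,
#' `centers`, `age_model`, `age_center`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [model_spec()].
#' @export
read_model_spec <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  model_spec(
    transitions = cfg$transitions %||% c("1-2", "1-3", "2-3"),
    covariates = cfg$covariates %||% character(0),
    refs = cfg$refs %||% list(),
    centers = unlist(cfg$centers) %||% numeric(0),
    age_model = cfg$age_model %||% "loglinear",
    age_center = cfg$age_center %||% 50)
}

#' Serialise a fitted model to JSON
#'
#' Writes estimates (flat parameter vector and structured per-transition
#' form), covariance, log-likelihood and convergence diagnostics.
#'
#' @param fit A [fit_model()] result.
#' @param path Output `.json` path.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "cvd_fit"))
  obj <- list(
    par = as.list(fit$par),
    estimates = lapply(fit$estimates$transitions, function(el)
      list(log_baseline = el$log_baseline, beta_age = el$beta_age,
           betas = as.list(el$betas))),
    covariance = fit$covariance,
    loglik = fit$loglik,
    converged = fit$converged,
    n_subjects = fit$n_subjects,
    n_intervals = fit$n_intervals,
    n_transitions = as.list(fit$n_transitions),
    spec = list(transitions = fit$spec$transitions,
                covariates = fit$spec$covariates,
                refs = fit$spec$refs,
                centers = as.list(fit$spec$centers),
                age_model = fit$spec$age_model,
                age_center = fit$spec$age_center),
    options = fit$options[c("step", "exact_onsets")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a fitted model back from JSON
#'
#' Rebuilds a `cvd_fit` written by [write_fit()], sufficient for
#' [le_uncertainty()], [le_difference()] and [hazard_ratios()].
#'
#' @param path `.json` file written by [write_fit()].
#' @return An object of class `cvd_fit`.
#' @export
read_fit <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  spec <- model_spec(
    transitions = obj$spec$transitions,
    covariates = obj$spec$covariates %||% character(0),
    refs = obj$spec$refs %||% list(),
    centers = unlist(obj$spec$centers) %||% numeric(0),
    age_model = obj$spec$age_model,
    age_center = obj$spec$age_center)
  par <- unlist(obj$par)
  covariance <- obj$covariance
  if (!is.null(covariance))
    dimnames(covariance) <- list(names(par), names(par))
  structure(list(
    estimates = .unflatten_params(par, spec),
    covariance = covariance,
    loglik = obj$loglik,
    converged = obj$converged,
    n_subjects = obj$n_subjects,
    n_intervals = obj$n_intervals,
    n_transitions = unlist(obj$n_transitions),
    par = par,
    spec = spec,
    options = obj$options), class = "cvd_fit")
}

#' Write hazard-ratio tables for every transition
#'
#' @param fit A [fit_model()] result.
#' @param path Output `.csv` path.
#' @return The combined table, invisibly.
#' @export
write_hazard_ratios <- function(fit, path) {
  tabs <- lapply(fit$spec$transitions, function(tr) {
    h <- hazard_ratios(fit, tr)
    if (nrow(h)) cbind(transition = tr, h) else NULL
  })
  out <- do.call(rbind, tabs)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Write a simulated cohort bundle
#'
#' Emits the analysis-ready records CSV, a truth JSON (the generating
#' parameters) and a run manifest (seed and design settings) into a
#' directory.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param path Output directory (created if needed).
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cvd_cohort"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_observations(cohort$data, file.path(path, "cohort.csv"))
  truth <- lapply(cohort$truth$transitions, function(el)
    list(log_baseline = el$log_baseline, beta_age = el$beta_age,
         betas = as.list(el$betas)))
  jsonlite::write_json(
    list(transitions = truth, age_center = cohort$truth$age_center),
    file.path(path, "truth.json"), auto_unbox = TRUE, digits = NA)
  cfg <- cohort$config
  jsonlite::write_json(
    list(seed = cohort$seed, n_subjects = cfg$n_subjects,
         recontact_offsets = cfg$recontact_offsets,
         admin_censoring_age = cfg$admin_censoring_age,
         cvd_observation = cfg$cvd_observation,
         sim_grid = cfg$sim_grid,
         baseline_age = cfg$baseline_age,
         covariate_update_rules = cfg$covariate_update_rules),
    file.path(path, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a truth JSON back into a parameter set
#'
#' @param path `truth.json` written by [write_cohort()].
#' @return A [param_set()].
#' @export
read_truth <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  trs <- lapply(obj$transitions, function(el)
    list(log_baseline = el$log_baseline, beta_age = el$beta_age,
         betas = unlist(el$betas) %||% NULL))
  param_set(trs, age_center = obj$age_center %||% 50)
}
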