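# Model specification and transition-intensity parameter sets.

.cvd_transitions <- c("1-2", "1-3", "2-3")

#' Specify an illness-death model
#'
#' Defines the structure of the three-state illness-death model: which of
#' the allowed transitions (1-2 disease onset, 1-3 death while disease free,
#' 2-3 death after onset) carry parameters, which covariates act on each
#' transition, reference levels, and how age enters the intensities.
#'
#' Transitions omitted from `transitions` have intensity identically zero
#' (structural zeros are encoded by omission, never by degenerate
#' parameters).
#'
#' @param transitions Character vector, subset of
#'   `c("1-2", "1-3", "2-3")`.
#' @param covariates Covariate names applied to every transition, or a named
#'   list (names = transitions) of per-transition covariate vectors.
#' @param refs Named list of reference-level overrides for factor
#'   covariates.
#' @param centers Named numeric vector of centring overrides for numeric
#'   covariates.
#' @param age_model `"loglinear"` for Gompertz-type log-linear age
#'   dependence of each intensity, or `"none"` for time-homogeneous
#'   intensities.
#' @param age_center Age (years) at which baseline intensities are defined;
#'   default 50.
#' @return An object of class `cvd_model_spec`.
#' @export
model_spec <- function(transitions = c("1-2", "1-3", "2-3"),
                       covariates = character(0),
                       refs = list(),
                       centers = numeric(0),
                       age_model = c("loglinear", "none"),
                       age_center = 50) {
  age_model <- match.arg(age_model)
  if (!all(transitions %in% .cvd_transitions))
    stop("transitions must be a subset of: ",
         paste(.cvd_transitions, collapse = ", "), call. = FALSE)
  if (length(transitions) == 0L)
    stop("at least one transition is required", call. = FALSE)
  transitions <- .cvd_transitions[.cvd_transitions %in% transitions]
  if (!is.list(covariates))
    covariates <- stats::setNames(
      rep(list(as.character(covariates)), length(transitions)), transitions)
  if (!all(names(covariates) %in% transitions))
    stop("per-transition covariate list names must be transitions",
         call. = FALSE)
  for (tr in transitions)
    covariates[[tr]] <- as.character(covariates[[tr]] %||% character(0))
  covariates <- covariates[transitions]
  unknown <- setdiff(unique(unlist(covariates)),
                     names(.cvd_covariate_catalogue))
  if (length(unknown))
    stop("unknown covariates: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(refs)) {
    info <- .cvd_covariate_catalogue[[nm]]
    if (is.null(info) || info$type != "factor" ||
        !(refs[[nm]] %in% info$levels))
      stop("invalid reference level for '", nm, "'", call. = FALSE)
  }
  structure(list(transitions = transitions, covariates = covariates,
                 refs = refs, centers = centers,
                 age_model = age_model, age_center = age_center),
            class = "cvd_model_spec")
}

# Dummy names for the covariates acting on one transition under a spec.
.spec_dummies <- function(spec, transition) {
  covs <- spec$covariates[[transition]]
  if (length(covs) == 0L) return(character(0))
  unlist(lapply(covs, function(cov)
    dummy_names(cov, ref = spec$refs[[cov]])), use.names = FALSE)
}

#' Create a transition-intensity parameter set
#'
#' Houses, for each allowed transition, the log baseline intensity (per
#' year, at the centring age and reference covariate levels), the log-linear
#' age slope, and named log hazard ratios for covariate dummies.
#'
#' @param transitions Named list keyed by transition (`"1-2"`, `"1-3"`,
#'   `"2-3"`); each element a list with components `log_baseline` (required),
#'   `beta_age` (default 0) and `betas` (named numeric, default none).
#'   Transitions not listed have intensity identically zero.
#' @param age_center Centring age for the baseline intensities (years).
#' @param centers Named numeric centring overrides for numeric covariates.
#' @return An object of class `cvd_params`.
#' @examples
#' param_set(list(
#'   "1-2" = list(log_baseline = log(0.02)),
#'   "1-3" = list(log_baseline = log(0.03), beta_age = 0.1),
#'   "2-3" = list(log_baseline = log(0.10),
#'                betas = c(smoking_never = -0.5))))
#' @export
param_set <- function(transitions = list(), age_center = 50,
                      centers = numeric(0)) {
  if (!is.list(transitions) ||
      (length(transitions) && is.null(names(transitions))))
    stop("'transitions' must be a named list", call. = FALSE)
  bad <- setdiff(names(transitions), .cvd_transitions)
  if (length(bad))
    stop("disallowed transitions: ", paste(bad, collapse = ", "),
         " (no recovery, state 3 absorbing)", call. = FALSE)
  out <- list()
  for (tr in .cvd_transitions[.cvd_transitions %in% names(transitions)]) {
    el <- transitions[[tr]]
    el$beta_age <- el$beta_age %||% 0
    el$betas <- el$betas %||% stats::setNames(numeric(0), character(0))
    vals <- c(el$log_baseline, el$beta_age, el$betas)
    if (is.null(el$log_baseline) || any(!is.finite(vals)))
      stop("non-finite or missing parameter for transition ", tr,
           call. = FALSE)
    if (length(el$betas) && is.null(names(el$betas)))
      stop("betas must be named by covariate dummies for transition ", tr,
           call. = FALSE)
    out[[tr]] <- el[c("log_baseline", "beta_age", "betas")]
  }
  structure(list(transitions = out, age_center = age_center,
                 centers = centers),
            class = "cvd_params")
}

#' @export
print.cvd_params <- function(x, ...) {
  cat("Illness-death transition intensity parameters",
      sprintf("(age centred at %g)\n", x$age_center))
  for (tr in names(x$transitions)) {
    el <- x$transitions[[tr]]
    cat(sprintf("  %s: baseline %.5g /yr, age slope %.4g /yr\n", tr,
                exp(el$log_baseline), el$beta_age))
    if (length(el$betas))
      cat(sprintf("      log HR: %s\n",
                  paste(sprintf("%s=%.3f", names(el$betas), el$betas),
                        collapse = ", ")))
  }
  invisible(x)
}

# ---- flat parameter vector <-> cvd_params -------------------------------
# Canonical ordering per transition: log_baseline, beta_age (loglinear age
# model only), then covariate dummies in spec order.

.par_names <- function(spec) {
  unlist(lapply(spec$transitions, function(tr) {
    nms <- c("log_baseline",
             if (spec$age_model == "loglinear") "beta_age",
             .spec_dummies(spec, tr))
    paste(tr, nms, sep = ".")
  }), use.names = FALSE)
}

.flatten_params <- function(params, spec) {
  nms <- .par_names(spec)
  out <- stats::setNames(numeric(length(nms)), nms)
  for (tr in spec$transitions) {
    el <- params$transitions[[tr]]
    if (is.null(el))
      stop("parameter set lacks transition ", tr, call. = FALSE)
    out[paste0(tr, ".log_baseline")] <- el$log_baseline
    if (spec$age_model == "loglinear")
      out[paste0(tr, ".beta_age")] <- el$beta_age
    for (d in .spec_dummies(spec, tr))
      out[paste(tr, d, sep = ".")] <-
        if (d %in% names(el$betas)) el$betas[[d]] else 0
  }
  out
}

.unflatten_params <- function(par, spec) {
  trs <- list()
  for (tr in spec$transitions) {
    dn <- .spec_dummies(spec, tr)
    trs[[tr]] <- list(
      log_baseline = unname(par[paste0(tr, ".log_baseline")]),
      beta_age = if (spec$age_model == "loglinear")
        unname(par[paste0(tr, ".beta_age")]) else 0,
      betas = stats::setNames(
        unname(par[paste(tr, dn, sep = ".", recycle0 = TRUE)]), dn))
  }
  param_set(trs, age_center = spec$age_center,
            centers = as.list(spec$centers))
}

# Linear predictors (excluding the age term) of one parameter set under a
# profile: named numeric c(`1-2`, `1-3`, `2-3`), -Inf for transitions with
# structural zero intensity.  Also the age slopes.
.profile_lp <- function(params, profile) {
  lp <- stats::setNames(rep(-Inf, 3L), .cvd_transitions)
  ba <- stats::setNames(numeric(3L), .cvd_transitions)
  for (tr in names(params$transitions)) {
    el <- params$transitions[[tr]]
    x <- if (length(el$betas))
      .dummy_values(names(el$betas), profile, params$centers) else numeric(0)
    lp[tr] <- el$log_baseline + sum(el$betas * x)
    ba[tr] <- el$beta_age
  }
  list(lp = lp, beta_age = ba, age_center = params$age_center)
}
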