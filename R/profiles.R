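# Covariate catalogue and evaluation profiles.
#
# Every covariate the model knows about is described here once: its levels,
# its reference level (the level absorbed into the baseline intensity), or,
# for numeric covariates, the value the model is centred at.  Reference
# levels follow the tabulation convention of the life-expectancy tables:
# current smoker, no vigorous PA, normal BMI, light/moderate alcohol.

.cvd_covariate_catalogue <- list(
  sex          = list(type = "factor",
                      levels = c("male", "female"), ref = "male"),
  smoking      = list(type = "factor",
                      levels = c("never", "former", "current"),
                      ref = "current"),
  vigorous_pa  = list(type = "factor",
                      levels = c("yes", "no"), ref = "no"),
  bmi_cat      = list(type = "factor",
                      levels = c("underweight", "normal", "overweight",
                                 "obese"),
                      ref = "normal"),
  alcohol_cat  = list(type = "factor",
                      levels = c("abstainer", "light_moderate", "heavy"),
                      ref = "light_moderate"),
  diabetes     = list(type = "factor",
                      levels = c("yes", "no"), ref = "no"),
  hypertension = list(type = "factor",
                      levels = c("yes", "no"), ref = "no"),
  tc_hdl_ratio = list(type = "numeric", center = 4.5)
)

#' Covariate catalogue
#'
#' Returns the catalogue of covariates understood by the model: factor
#' covariates with their levels and reference level, and numeric covariates
#' with their centring value.  Dummy variables are named
#' `<covariate>_<level>` for each non-reference level; numeric covariates
#' keep their own name and enter the linear predictor centred.
#'
#' @return A named list, one entry per covariate.
#' @export
covariate_catalogue <- function() .cvd_covariate_catalogue

#' Dummy-variable names for a covariate
#'
#' @param covariate Covariate name from [covariate_catalogue()].
#' @param ref Optional reference level override (factor covariates).
#' @return Character vector of dummy names.
#' @export
dummy_names <- function(covariate, ref = NULL) {
  info <- .cvd_covariate_catalogue[[covariate]]
  if (is.null(info))
    stop("unknown covariate: ", covariate, call. = FALSE)
  if (info$type == "numeric") return(covariate)
  ref <- ref %||% info$ref
  paste(covariate, setdiff(info$levels, ref), sep = "_")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Centring value for a numeric covariate, with catalogue fallback; safe for
# empty or unnamed `centers`.
.center_of <- function(centers, covariate, default) {
  if (!is.null(centers) && covariate %in% names(centers))
    centers[[covariate]]
  else default
}

# Map a dummy name back to (covariate, level).  Numeric covariates map to
# (covariate, NA).  Returns NULL for unknown names.
.parse_dummy <- function(name) {
  for (cov in names(.cvd_covariate_catalogue)) {
    info <- .cvd_covariate_catalogue[[cov]]
    if (info$type == "numeric") {
      if (name == cov) return(list(covariate = cov, level = NA_character_))
    } else if (startsWith(name, paste0(cov, "_"))) {
      lev <- substring(name, nchar(cov) + 2L)
      if (lev %in% info$levels)
        return(list(covariate = cov, level = lev))
    }
  }
  NULL
}

#' Create a covariate profile
#'
#' A covariate profile fixes the covariate vector at which transition
#' intensities and life expectancies are evaluated.  Factor covariates may be
#' given as a single level (`smoking = "never"`) or as named fractions over
#' levels (`smoking = c(never = 0.4, former = 0.3, current = 0.3)`), the
#' latter representing a population-mean profile.  Numeric covariates are
#' given on their natural scale.
#'
#' @param ... Named covariate values; names must appear in
#'   [covariate_catalogue()].
#' @return An object of class `cvd_profile`.
#' @examples
#' covariate_profile(sex = "male", smoking = "never", vigorous_pa = "yes",
#'                   bmi_cat = "normal", alcohol_cat = "light_moderate",
#'                   diabetes = "no", hypertension = "no",
#'                   tc_hdl_ratio = 4.5)
#' @export
covariate_profile <- function(...) {
  vals <- list(...)
  if (length(vals) == 1L && is.null(names(vals)) && is.list(vals[[1L]]))
    vals <- vals[[1L]]
  if (is.null(names(vals)) || any(!nzchar(names(vals))))
    stop("all profile entries must be named", call. = FALSE)
  for (nm in names(vals)) {
    info <- .cvd_covariate_catalogue[[nm]]
    if (is.null(info))
      stop("unknown covariate in profile: ", nm, call. = FALSE)
    v <- vals[[nm]]
    if (info$type == "numeric") {
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
        stop("covariate '", nm, "' must be a finite number", call. = FALSE)
      if (nm == "tc_hdl_ratio" && v <= 0)
        stop("tc_hdl_ratio must be positive", call. = FALSE)
    } else if (is.character(v)) {
      if (length(v) != 1L || !(v %in% info$levels))
        stop("covariate '", nm, "' must be one of: ",
             paste(info$levels, collapse = ", "), call. = FALSE)
    } else if (is.numeric(v)) {
      if (is.null(names(v)) || !all(names(v) %in% info$levels))
        stop("fractional values for '", nm,
             "' must be named by its levels", call. = FALSE)
      if (any(v < 0) || sum(v) > 1 + 1e-8)
        stop("fractional values for '", nm,
             "' must be nonnegative and sum to at most 1", call. = FALSE)
    } else {
      stop("invalid value for covariate '", nm, "'", call. = FALSE)
    }
  }
  structure(vals, class = "cvd_profile")
}

#' @export
print.cvd_profile <- function(x, ...) {
  cat("Covariate profile:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.character(v)) {
      cat(sprintf("  %-13s %s\n", nm, v))
    } else if (!is.null(names(v))) {
      cat(sprintf("  %-13s %s\n", nm,
                  paste(sprintf("%s=%.3g", names(v), v), collapse = ", ")))
    } else {
      cat(sprintf("  %-13s %.4g\n", nm, v))
    }
  }
  invisible(x)
}

#' Set covariates in a profile
#'
#' @param profile A `cvd_profile` (or named list of covariate values).
#' @param ... Named replacement values, as in [covariate_profile()].
#' @return The modified `cvd_profile`.
#' @export
set_profile <- function(profile, ...) {
  vals <- unclass(profile)
  repl <- list(...)
  for (nm in names(repl)) vals[[nm]] <- repl[[nm]]
  do.call(covariate_profile, vals)
}

# Value of one dummy variable under a profile (fraction in [0,1] for factor
# dummies, centred value for numeric covariates).  `values` is a cvd_profile
# or a plain named list of covariate values; `centers` overrides catalogue
# centring for numeric covariates.
.dummy_value <- function(name, values, centers = NULL) {
  pd <- .parse_dummy(name)
  if (is.null(pd))
    stop("unknown model covariate: ", name, call. = FALSE)
  cov <- pd$covariate
  v <- values[[cov]]
  if (is.null(v))
    stop("profile is missing covariate '", cov, "' required by the model",
         call. = FALSE)
  info <- .cvd_covariate_catalogue[[cov]]
  if (info$type == "numeric")
    return(as.numeric(v) - .center_of(centers, cov, info$center))
  if (is.character(v)) return(as.numeric(v == pd$level))
  frac <- v[pd$level]
  if (is.na(frac)) 0 else as.numeric(frac)
}

# Vector of dummy values for several dummy names.
.dummy_values <- function(names, values, centers = NULL) {
  vapply(names, .dummy_value, numeric(1), values = values,
         centers = centers)
}

#' Cohort-mean covariate profile
#'
#' Computes the population-mean covariate profile from the baseline records
#' of an analysis dataset: factor covariates become fractional (the observed
#' level frequencies), numeric covariates their mean.  Used to evaluate life
#' expectancy "with the other covariates at the cohort means".
#'
#' @param data Long-format observation data (one row per contact).
#' @param covariates Covariate names to include; defaults to every catalogue
#'   covariate present in `data`.
#' @param baseline_only If `TRUE` (default), only each subject's first record
#'   is used.
#' @return A `cvd_profile` with fractional factor entries.
#' @export
cohort_mean_profile <- function(data, covariates = NULL,
                                baseline_only = TRUE) {
  if (baseline_only)
    data <- data[!duplicated(data$subject_id), , drop = FALSE]
  covariates <- covariates %||%
    intersect(names(.cvd_covariate_catalogue), names(data))
  vals <- list()
  for (cov in covariates) {
    info <- .cvd_covariate_catalogue[[cov]]
    col <- data[[cov]]
    if (info$type == "numeric") {
      vals[[cov]] <- mean(as.numeric(col))
    } else {
      tab <- table(factor(col, levels = info$levels))
      vals[[cov]] <- as.numeric(tab) / sum(tab)
      names(vals[[cov]]) <- info$levels
    }
  }
  do.call(covariate_profile, vals)
}
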