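# Synthetic cohorts with the statistical structure the analysis assumes:
# continuous-time illness-death trajectories under a known parameter set,
# lifestyle covariate mixes resembling ageing cohorts, and the
# baseline-plus-recontact observation design with register-dated deaths.

#' Default true parameter set for the cohort generator
#'
#' Gompertz-type baseline intensities and lifestyle/clinical hazard ratios
#' chosen so that the implied life expectancies at age 50 fall in the
#' 20-40-year range typical of ageing cohorts (so scale errors are visible),
#' with protective never-smoker / physically-active effects and the usual
#' overweight-survival quirk after disease onset.  These are the generator's
#' documented defaults, not estimates from any cohort.
#'
#' @return A [param_set()].
#' @export
default_true_params <- function() {
  param_set(list(
    "1-2" = list(log_baseline = log(0.007), beta_age = 0.07,
                 betas = c(sex_female = -0.45, smoking_never = -0.55,
                           smoking_former = -0.40, vigorous_pa_yes = -0.25,
                           bmi_cat_underweight = 0.10, bmi_cat_overweight = 0.15,
                           bmi_cat_obese = 0.35, alcohol_cat_abstainer = 0.10,
                           alcohol_cat_heavy = 0.30, diabetes_yes = 0.45,
                           hypertension_yes = 0.30, tc_hdl_ratio = 0.08)),
    "1-3" = list(log_baseline = log(0.006), beta_age = 0.09,
                 betas = c(sex_female = -0.40, smoking_never = -0.60,
                           smoking_former = -0.45, vigorous_pa_yes = -0.30,
                           bmi_cat_underweight = 0.55, bmi_cat_overweight = -0.10,
                           bmi_cat_obese = 0.10, alcohol_cat_abstainer = 0.12,
                           alcohol_cat_heavy = 0.35, diabetes_yes = 0.40,
                           hypertension_yes = 0.20, tc_hdl_ratio = 0.03)),
    "2-3" = list(log_baseline = log(0.035), beta_age = 0.07,
                 betas = c(sex_female = -0.30, smoking_never = -0.20,
                           smoking_former = -0.15, vigorous_pa_yes = -0.20,
                           bmi_cat_underweight = 0.30, bmi_cat_overweight = -0.10,
                           bmi_cat_obese = -0.15, alcohol_cat_abstainer = 0.10,
                           alcohol_cat_heavy = 0.25, diabetes_yes = 0.30,
                           hypertension_yes = 0.15, tc_hdl_ratio = 0.02))),
    age_center = 50)
}

#' Default baseline covariate frequencies
#'
#' Loosely matches the baseline lifestyle mix of 50+ European cohorts:
#' roughly a third current smokers and a third vigorously active, BMI mass
#' in the normal/overweight categories, light/moderate drinking dominant.
#'
#' @return Named list of level-probability vectors (factors) and
#'   mean/sd/min (numeric covariates).
#' @export
default_covariate_frequencies <- function() {
  list(sex = c(male = 0.45, female = 0.55),
       smoking = c(never = 0.40, former = 0.28, current = 0.32),
       vigorous_pa = c(yes = 0.33, no = 0.67),
       bmi_cat = c(underweight = 0.015, normal = 0.42, overweight = 0.42,
                   obese = 0.145),
       alcohol_cat = c(abstainer = 0.24, light_moderate = 0.72,
                       heavy = 0.04),
       diabetes = c(yes = 0.05, no = 0.95),
       hypertension = c(yes = 0.45, no = 0.55),
       tc_hdl_ratio = c(mean = 4.5, sd = 1.5, min = 1.5))
}

#' Simulation configuration
#'
#' Describes the cohort to generate: its size, true transition parameters,
#' baseline age distribution (truncated normal, >= 50), baseline covariate
#' mix, the observation design (re-contact offsets bracketing the 5-7-year
#' spacing of real cohorts, administrative censoring), covariate update
#' rules applied at re-contacts, and whether nonfatal disease onsets are
#' registry dated (`"exact"`) or only seen at the next contact (`"panel"`).
#'
#' @param n_subjects Cohort size.
#' @param seed Default RNG seed used by [simulate_cohort()].
#' @param true_params True [param_set()].
#' @param baseline_age List `mean`, `sd`, `min`, `max` of the truncated
#'   normal baseline age distribution.
#' @param covariate_frequencies See [default_covariate_frequencies()].
#' @param recontact_offsets Years after baseline of each re-contact.
#' @param admin_censoring_age Age at which follow-up ends.
#' @param covariate_update_rules List; `smoking_cessation_prob` is the
#'   per-re-contact probability that a current smoker has quit (-> former).
#' @param cvd_observation `"exact"` or `"panel"`.
#' @param sim_grid Width (years) of the piecewise-constant thinning grid
#'   used to sample event times (default 0.05; hazard variation over such a
#'   cell is negligible at age slopes <= 0.15/yr).
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_subjects = 2000L, seed = 1L,
                              true_params = default_true_params(),
                              baseline_age = list(mean = 62, sd = 7,
                                                  min = 50, max = 80),
                              covariate_frequencies =
                                default_covariate_frequencies(),
                              recontact_offsets = c(6, 12),
                              admin_censoring_age = 85,
                              covariate_update_rules =
                                list(smoking_cessation_prob = 0.1),
                              cvd_observation = c("exact", "panel"),
                              sim_grid = 0.05) {
  cvd_observation <- match.arg(cvd_observation)
  if (n_subjects <= 0) stop("n_subjects must be positive", call. = FALSE)
  if (is.unsorted(recontact_offsets, strictly = TRUE) ||
      any(recontact_offsets <= 0))
    stop("recontact_offsets must be positive and increasing",
         call. = FALSE)
  p <- covariate_update_rules$smoking_cessation_prob %||% 0
  if (p < 0 || p > 1)
    stop("smoking_cessation_prob must be in [0, 1]", call. = FALSE)
  if (admin_censoring_age <= baseline_age$max)
    stop("admin_censoring_age must exceed the maximum baseline age",
         call. = FALSE)
  stopifnot(inherits(true_params, "cvd_params"))
  structure(list(n_subjects = as.integer(n_subjects), seed = seed,
                 true_params = true_params, baseline_age = baseline_age,
                 covariate_frequencies = covariate_frequencies,
                 recontact_offsets = recontact_offsets,
                 admin_censoring_age = admin_censoring_age,
                 covariate_update_rules = covariate_update_rules,
                 cvd_observation = cvd_observation, sim_grid = sim_grid),
            class = "sim_config")
}

# Vectorised continuous-time simulation of first exit from state 1 and
# subsequent death, by competing-risk sampling with piecewise-constant
# hazards on a fine age grid: within each cell the exit probability is
# 1 - exp(-a w); conditional on exit the time is drawn from the truncated
# exponential and the cause with probability q12/a.  lp12/lp13/lp23 are
# n x E matrices of linear predictors per covariate epoch (epochs change at
# baseline + offsets).
.sim_engine <- function(baseline_age, censor_age, lp12, lp13, lp23, bage,
                        age_center, offsets, grid) {
  n <- length(baseline_age)
  state <- rep(1L, n)
  cvd_age <- rep(NA_real_, n)
  death_age <- rep(NA_real_, n)
  edges <- seq(min(baseline_age), max(censor_age) + grid, by = grid)
  for (k in seq_len(length(edges) - 1L)) {
    u0 <- edges[k]; u1 <- edges[k + 1L]
    act <- which(state == 1L & baseline_age < u1 & censor_age > u0)
    if (length(act)) {
      s <- pmax(u0, baseline_age[act])
      e <- pmin(u1, censor_age[act])
      keep <- e > s
      act <- act[keep]; s <- s[keep]; e <- e[keep]
    }
    if (length(act)) {
      w <- e - s
      mid <- (s + e) / 2
      ep <- findInterval(mid - baseline_age[act], offsets) + 1L
      q12 <- exp(lp12[cbind(act, ep)] + bage[1L] * (mid - age_center))
      q13 <- exp(lp13[cbind(act, ep)] + bage[2L] * (mid - age_center))
      a <- q12 + q13
      U <- stats::runif(length(act))
      ex <- a > 0 & U < -expm1(-a * w)
      if (any(ex)) {
        i <- act[ex]
        texit <- s[ex] - log1p(-U[ex]) / a[ex]
        to2 <- stats::runif(length(i)) < q12[ex] / a[ex]
        cvd_age[i[to2]] <- texit[to2]
        state[i[to2]] <- 2L
        death_age[i[!to2]] <- texit[!to2]
        state[i[!to2]] <- 0L
      }
    }
    # state-2 risk, including the remainder of the cell for subjects whose
    # onset fell inside it
    act <- which(state == 2L & cvd_age < u1 & censor_age > u0)
    if (length(act)) {
      s <- pmax(u0, cvd_age[act])
      e <- pmin(u1, censor_age[act])
      keep <- e > s
      act <- act[keep]; s <- s[keep]; e <- e[keep]
    }
    if (length(act)) {
      w <- e - s
      mid <- (s + e) / 2
      ep <- findInterval(mid - baseline_age[act], offsets) + 1L
      q23 <- exp(lp23[cbind(act, ep)] + bage[3L] * (mid - age_center))
      U <- stats::runif(length(act))
      ex <- q23 > 0 & U < -expm1(-q23 * w)
      if (any(ex)) {
        i <- act[ex]
        death_age[i] <- s[ex] - log1p(-U[ex]) / q23[ex]
        state[i] <- 0L
      }
    }
  }
  list(cvd_age = cvd_age, death_age = death_age)
}

# Per-epoch linear predictor matrices (n x E) for a cohort covariate table.
# `epochs` is a list of data frames (one per epoch, n rows each).
.epoch_lp <- function(params, epochs) {
  E <- length(epochs)
  n <- nrow(epochs[[1L]])
  out <- list()
  for (tr in .cvd_transitions) {
    el <- params$transitions[[tr]]
    if (is.null(el)) {
      out[[tr]] <- matrix(-Inf, n, E)
    } else {
      m <- matrix(el$log_baseline, n, E)
      if (length(el$betas)) {
        for (e in seq_len(E)) {
          X <- .data_design(epochs[[e]], names(el$betas), params$centers)
          m[, e] <- m[, e] + as.vector(X %*% el$betas)
        }
      }
      out[[tr]] <- m
    }
  }
  out
}

#' Simulate one true trajectory
#'
#' Exact continuous-time simulation of a single subject's illness-death
#' trajectory under a known parameter set and a piecewise-constant
#' covariate path.
#'
#' @param true_params A [param_set()].
#' @param covariate_path Data frame with a column `age` (change ages, first
#'   row at the baseline age) and covariate columns; values hold from each
#'   age until the next.
#' @param baseline_age Age at entry (years).
#' @param censor_age Administrative censoring age.
#' @param sim_grid Thinning grid width (years).
#' @return An object of class `cvd_trajectory`: `baseline_age`,
#'   `covariate_path`, `cvd_age` (NA if none), `death_age` (NA if censored)
#'   and `censor_age`.
#' @export
simulate_trajectory <- function(true_params, covariate_path, baseline_age,
                                censor_age = 115, sim_grid = 0.05) {
  stopifnot(inherits(true_params, "cvd_params"))
  if (covariate_path$age[1L] > baseline_age)
    stop("covariate_path must start at or before baseline_age",
         call. = FALSE)
  offsets <- covariate_path$age[-1L] - baseline_age
  epochs <- lapply(seq_len(nrow(covariate_path)), function(i)
    covariate_path[i, setdiff(names(covariate_path), "age"),
                   drop = FALSE])
  lp <- .epoch_lp(true_params, epochs)
  bage <- vapply(.cvd_transitions, function(tr)
    true_params$transitions[[tr]]$beta_age %||% 0, numeric(1))
  r <- .sim_engine(baseline_age, censor_age, lp[["1-2"]], lp[["1-3"]],
                   lp[["2-3"]], bage, true_params$age_center,
                   offsets, sim_grid)
  structure(list(baseline_age = baseline_age,
                 covariate_path = covariate_path,
                 cvd_age = r$cvd_age, death_age = r$death_age,
                 censor_age = censor_age), class = "cvd_trajectory")
}

# Most recent covariate-path row at or before `age`.
.path_at <- function(covariate_path, age) {
  i <- max(which(covariate_path$age <= age + 1e-12))
  as.list(covariate_path[i, setdiff(names(covariate_path), "age"),
                         drop = FALSE])
}

#' Apply the panel observation scheme to a true trajectory
#'
#' Converts a continuously observed trajectory into the records a cohort
#' study would see: panel records at baseline and at each re-contact age
#' survived, carrying the covariates measured at that contact; the death
#' age emitted exactly (register design) with the most recent covariates;
#' the nonfatal onset emitted either as an exactly dated transition
#' (`cvd_observation = "exact"`) or only through the state first seen at
#' the following re-contact (`"panel"`).  Nothing is emitted after death
#' or administrative censoring.
#'
#' @param traj A [simulate_trajectory()] result.
#' @param config A [simulation_config()] (re-contact offsets, censoring and
#'   onset observation mode are taken from it).
#' @param subject_id Identifier for the emitted records.
#' @return A long-format data frame of observation records.
#' @export
apply_observation_scheme <- function(traj, config, subject_id = "S1") {
  stopifnot(inherits(traj, "cvd_trajectory"))
  censor <- min(traj$censor_age, config$admin_censoring_age)
  death <- traj$death_age
  cvd <- traj$cvd_age
  end <- if (is.na(death)) censor else min(death, censor)
  contacts <- traj$baseline_age + c(0, config$recontact_offsets)
  contacts <- contacts[contacts <= censor &
                         (is.na(death) | contacts < death)]
  rows <- lapply(contacts, function(a) {
    st <- if (!is.na(cvd) && cvd <= a) 2L else 1L
    c(list(subject_id = subject_id, age = a, state = st,
           obs_type = "panel"), .path_at(traj$covariate_path, a))
  })
  if (!is.na(cvd) && cvd < end && config$cvd_observation == "exact") {
    rows <- c(rows, list(c(list(subject_id = subject_id, age = cvd,
                                state = 2L, obs_type = "exact_transition"),
                           .path_at(traj$covariate_path, cvd))))
  }
  if (!is.na(death) && death <= censor) {
    rows <- c(rows, list(c(list(subject_id = subject_id, age = death,
                                state = 3L, obs_type = "exact_death"),
                           .path_at(traj$covariate_path, death))))
  } else if (censor > max(contacts)) {
    # end of register follow-up: the death register guarantees the subject
    # is alive at the censoring age; under registry-dated onsets the
    # disease state there is known too, under panel-observed onsets it is
    # not (state NA, "alive" record)
    st <- if (!is.na(cvd) && cvd <= censor) 2L else 1L
    rows <- c(rows, list(
      if (config$cvd_observation == "exact")
        c(list(subject_id = subject_id, age = censor, state = st,
               obs_type = "panel"), .path_at(traj$covariate_path, censor))
      else
        c(list(subject_id = subject_id, age = censor, state = NA_integer_,
               obs_type = "alive"),
          .path_at(traj$covariate_path, censor))))
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out[order(out$age), , drop = FALSE]
}

# Truncated-normal draws by rejection (narrow truncation, cheap).
.rtnorm <- function(n, mean, sd, min, max = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < min | out > max)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < min | out[bad] > max]
  }
  out
}

#' Simulate a panel-observed cohort
#'
#' Draws baseline covariates and ages, simulates true illness-death
#' trajectories under `config$true_params` (with smoking updated at
#' re-contacts per the cessation rule), applies the observation scheme, and
#' returns the analysis-ready long-format dataset together with the truth.
#' Reproducible: the same seed yields byte-identical output.
#'
#' @param config A [simulation_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @param path Optional directory; when given, writes `cohort.csv` (the
#'   records), `truth.json` (the true parameters) and `manifest.json`
#'   (seed and design settings) there.
#' @return An object of class `cvd_cohort`: list with `data` (records),
#'   `truth` (the true [param_set()]), `trajectories` (true event ages),
#'   `config` and `seed`.
#' @export
simulate_cohort <- function(config = simulation_config(),
                            seed = config$seed, path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_subjects
  fr <- config$covariate_frequencies
  draw_factor <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  base <- data.frame(
    sex = draw_factor(fr$sex),
    smoking = draw_factor(fr$smoking),
    vigorous_pa = draw_factor(fr$vigorous_pa),
    bmi_cat = draw_factor(fr$bmi_cat),
    alcohol_cat = draw_factor(fr$alcohol_cat),
    diabetes = draw_factor(fr$diabetes),
    hypertension = draw_factor(fr$hypertension),
    tc_hdl_ratio = round(.rtnorm(n, fr$tc_hdl_ratio[["mean"]],
                                 fr$tc_hdl_ratio[["sd"]],
                                 fr$tc_hdl_ratio[["min"]]), 2),
    stringsAsFactors = FALSE)
  ba <- config$baseline_age
  baseline_age <- round(.rtnorm(n, ba$mean, ba$sd, ba$min, ba$max), 2)
  offsets <- config$recontact_offsets
  E <- length(offsets) + 1L
  # covariate epochs: smoking may flip current -> former at each re-contact
  pq <- config$covariate_update_rules$smoking_cessation_prob %||% 0
  epochs <- vector("list", E)
  epochs[[1L]] <- base
  for (e in seq_len(E - 1L)) {
    prev <- epochs[[e]]
    cur <- prev
    quit <- prev$smoking == "current" & stats::runif(n) < pq
    cur$smoking[quit] <- "former"
    epochs[[e + 1L]] <- cur
  }
  lp <- .epoch_lp(config$true_params, epochs)
  bage <- vapply(.cvd_transitions, function(tr)
    config$true_params$transitions[[tr]]$beta_age %||% 0, numeric(1))
  censor <- rep(config$admin_censoring_age, n)
  r <- .sim_engine(baseline_age, censor, lp[["1-2"]], lp[["1-3"]],
                   lp[["2-3"]], bage, config$true_params$age_center,
                   offsets, config$sim_grid)
  id <- sprintf(paste0("S%0", nchar(n), "d"), seq_len(n))
  end <- ifelse(is.na(r$death_age), censor, pmin(r$death_age, censor))
  # panel contact records
  pieces <- list()
  for (e in seq_len(E)) {
    a <- baseline_age + c(0, offsets)[e]
    keep <- which(a <= censor & (is.na(r$death_age) | a < r$death_age))
    if (!length(keep)) next
    st <- ifelse(!is.na(r$cvd_age[keep]) & r$cvd_age[keep] <= a[keep],
                 2L, 1L)
    pieces[[length(pieces) + 1L]] <-
      cbind(data.frame(subject_id = id[keep], age = a[keep], state = st,
                       obs_type = "panel", stringsAsFactors = FALSE),
            epochs[[e]][keep, , drop = FALSE])
  }
  # exactly dated onsets
  if (config$cvd_observation == "exact") {
    keep <- which(!is.na(r$cvd_age) & r$cvd_age < end)
    if (length(keep)) {
      ep <- findInterval(r$cvd_age[keep] - baseline_age[keep], offsets) + 1L
      cov <- do.call(rbind, lapply(seq_along(keep), function(j)
        epochs[[ep[j]]][keep[j], , drop = FALSE]))
      pieces[[length(pieces) + 1L]] <-
        cbind(data.frame(subject_id = id[keep], age = r$cvd_age[keep],
                         state = 2L, obs_type = "exact_transition",
                         stringsAsFactors = FALSE), cov)
    }
  }
  # register deaths
  keep <- which(!is.na(r$death_age) & r$death_age <= censor)
  if (length(keep)) {
    ep <- findInterval(r$death_age[keep] - baseline_age[keep],
                       offsets) + 1L
    cov <- do.call(rbind, lapply(seq_along(keep), function(j)
      epochs[[ep[j]]][keep[j], , drop = FALSE]))
    pieces[[length(pieces) + 1L]] <-
      cbind(data.frame(subject_id = id[keep], age = r$death_age[keep],
                       state = 3L, obs_type = "exact_death",
                       stringsAsFactors = FALSE), cov)
  }
  # end of register follow-up: survivors are known alive at the censoring
  # age (death register); their disease state there is known only when
  # onsets are registry dated
  last_contact <- baseline_age +
    c(0, offsets)[findInterval(censor - baseline_age, c(0, offsets))]
  keep <- which(is.na(r$death_age) & censor > last_contact)
  if (length(keep)) {
    ep <- findInterval(censor[keep] - baseline_age[keep], offsets) + 1L
    cov <- do.call(rbind, lapply(seq_along(keep), function(j)
      epochs[[ep[j]]][keep[j], , drop = FALSE]))
    if (config$cvd_observation == "exact") {
      st <- ifelse(!is.na(r$cvd_age[keep]) & r$cvd_age[keep] <= censor[keep],
                   2L, 1L)
      pieces[[length(pieces) + 1L]] <-
        cbind(data.frame(subject_id = id[keep], age = censor[keep],
                         state = st, obs_type = "panel",
                         stringsAsFactors = FALSE), cov)
    } else {
      pieces[[length(pieces) + 1L]] <-
        cbind(data.frame(subject_id = id[keep], age = censor[keep],
                         state = NA_integer_, obs_type = "alive",
                         stringsAsFactors = FALSE), cov)
    }
  }
  data <- do.call(rbind, pieces)
  data <- data[order(data$subject_id, data$age), , drop = FALSE]
  rownames(data) <- NULL
  out <- structure(list(data = data, truth = config$true_params,
                        trajectories = data.frame(
                          subject_id = id, baseline_age = baseline_age,
                          cvd_age = r$cvd_age, death_age = r$death_age,
                          censor_age = censor),
                        config = config, seed = seed),
                   class = "cvd_cohort")
  if (!is.null(path)) write_cohort(out, path)
  out
}

#' @export
print.cvd_cohort <- function(x, ...) {
  tr <- x$trajectories
  cat(sprintf("Synthetic illness-death cohort: %d subjects, %d records\n",
              nrow(tr), nrow(x$data)))
  cat(sprintf("  nonfatal CVD events: %d, deaths observed: %d\n",
              sum(!is.na(tr$cvd_age) & tr$cvd_age <= tr$censor_age),
              sum(!is.na(tr$death_age) & tr$death_age <= tr$censor_age)))
  invisible(x)
}
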