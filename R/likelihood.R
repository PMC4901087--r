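# Panel-data likelihood for the illness-death model.
#
# Subjects are observed at a baseline contact plus re-contacts (panel
# observations: the state is known only at the contact ages, transition
# times in between are interval censored), nonfatal disease onsets may be
# registry dated (exact transitions), and deaths are exactly dated with the
# state just before death unknown.  Covariates are piecewise constant,
# carried forward from the most recent contact (the interval's left
# endpoint).
#
# Interval contributions, writing P = P(a0, a1) under the left-endpoint
# covariates and q_ij(a1) for the intensity at the interval's end age:
#   panel r -> s          : log P_rs
#   exact transition 1->2 : log( P_11 q_12(a1) )
#   exact death from r    : log( sum_k P_rk q_k3(a1) ), k in {1,2}
#   alive, state unknown  : log( P_r1 + P_r2 )
# Absorbing-state records contribute nothing further.  The "alive" type
# carries the register fact that no death occurred up to the end of
# follow-up when the disease state there is unobserved; ignoring that fact
# would truncate survivors' exposure at their last contact while still
# counting late deaths, biasing the intensities upward.

.obs_types <- c("panel", "exact_transition", "exact_death", "alive")

#' Construct a single observation record
#'
#' Convenience constructor for one dated sighting of a subject, used by
#' [interval_log_likelihood()].
#'
#' @param age Age at the observation (years).
#' @param state Observed state, 1 (disease free), 2 (nonfatal CVD) or 3
#'   (dead); `NA` for an `"alive"` record (known alive at end of register
#'   follow-up, disease state unobserved).
#' @param obs_type One of `"panel"`, `"exact_transition"`,
#'   `"exact_death"`, `"alive"`.
#' @param covariates Named list of covariate values as measured at the most
#'   recent contact.
#' @return A list of class `cvd_obs`.
#' @export
observation_record <- function(age, state, obs_type = "panel",
                               covariates = list()) {
  obs_type <- match.arg(obs_type, .obs_types)
  if (obs_type == "alive") {
    state <- NA_integer_
  } else if (!state %in% 1:3) {
    stop("state must be 1, 2 or 3", call. = FALSE)
  }
  if (obs_type == "exact_death" && state != 3)
    stop("obs_type 'exact_death' requires state 3", call. = FALSE)
  if (obs_type == "exact_transition" && state != 2)
    stop("obs_type 'exact_transition' requires state 2", call. = FALSE)
  structure(list(age = age, state = as.integer(state),
                 obs_type = obs_type, covariates = covariates),
            class = "cvd_obs")
}

#' Validate long-format observation histories
#'
#' Checks the structural invariants of an analysis dataset: required
#' columns; ages strictly increasing within subject; states non-decreasing
#' in the illness-death order; each subject starting in state 1; at most one
#' death record per subject, always last; observation types consistent with
#' the recorded state.
#'
#' @param data Long-format data frame with columns `subject_id`, `age`,
#'   `state`, `obs_type` and covariate columns.
#' @return Invisibly `TRUE`; otherwise an error identifying the subject.
#' @export
validate_histories <- function(data) {
  req <- c("subject_id", "age", "state", "obs_type")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("data lacks required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(data) == 0L) stop("data is empty", call. = FALSE)
  alive <- data$obs_type == "alive"
  if (!all(data$state[!alive] %in% 1:3))
    stop("states must be 1, 2 or 3", call. = FALSE)
  if (!all(data$obs_type %in% .obs_types))
    stop("obs_type must be one of: ", paste(.obs_types, collapse = ", "),
         call. = FALSE)
  if (any(data$obs_type == "exact_death" & data$state != 3, na.rm = TRUE))
    stop("obs_type 'exact_death' requires state 3", call. = FALSE)
  if (any(data$obs_type == "exact_transition" & data$state != 2,
          na.rm = TRUE))
    stop("obs_type 'exact_transition' requires state 2", call. = FALSE)
  ord <- order(data$subject_id, data$age)
  data <- data[ord, , drop = FALSE]
  id <- data$subject_id
  same <- id[-1L] == id[-length(id)]
  .first_bad <- function(cond) id[-1L][cond & !is.na(cond)][1L]
  if (any(bad <- same & diff(data$age) <= 0))
    stop("ages must be strictly increasing within subject; offender: ",
         .first_bad(bad), call. = FALSE)
  if (any(bad <- same & diff(data$state) < 0, na.rm = TRUE))
    stop("states may not move backwards (no recovery); offender: ",
         .first_bad(bad), call. = FALSE)
  if (any(bad <- same & data$state[-length(id)] == 3, na.rm = TRUE))
    stop("state 3 is absorbing, records after death; offender: ",
         .first_bad(bad), call. = FALSE)
  if (any(bad <- same & alive[ord][-length(id)]))
    stop("an 'alive' end-of-follow-up record must be a subject's last; ",
         "offender: ", .first_bad(bad), call. = FALSE)
  first <- !duplicated(id)
  if (any(is.na(data$state[first])) || any(data$state[first] != 1))
    stop("each subject's first record must be state 1 (disease free); ",
         "offender: ", id[first][data$state[first] != 1][1L],
         call. = FALSE)
  invisible(TRUE)
}

#' Apply cohort entry exclusions
#'
#' Removes subjects whose first record is before age 50 or not in state 1
#' (prevalent disease), mirroring the entry criteria of cohorts of
#' 50+-year-olds free of CVD at baseline.
#'
#' @param data Long-format observation data.
#' @param min_age Minimum baseline age (default 50).
#' @return The filtered data, with an attribute `exclusions` recording the
#'   subject counts removed at each step.
#' @export
apply_exclusions <- function(data, min_age = 50) {
  data <- data[order(data$subject_id, data$age), , drop = FALSE]
  first <- !duplicated(data$subject_id)
  young <- data$subject_id[first][data$age[first] < min_age]
  prevalent <- data$subject_id[first][data$state[first] != 1]
  drop <- unique(c(young, prevalent))
  out <- data[!(data$subject_id %in% drop), , drop = FALSE]
  attr(out, "exclusions") <- c(underage = length(unique(young)),
                               prevalent = length(unique(prevalent)),
                               retained = length(unique(out$subject_id)))
  out
}

# Design matrix (n x p) of dummy values for rows of a data frame of
# covariate columns on their natural scale.
.data_design <- function(data, dummies, centers = NULL) {
  if (length(dummies) == 0L)
    return(matrix(0, nrow(data), 0))
  X <- matrix(0, nrow(data), length(dummies),
              dimnames = list(NULL, dummies))
  for (d in dummies) {
    pd <- .parse_dummy(d)
    if (is.null(pd)) stop("unknown model covariate: ", d, call. = FALSE)
    col <- data[[pd$covariate]]
    if (is.null(col))
      stop("data lacks covariate column '", pd$covariate, "'",
           call. = FALSE)
    if (anyNA(col))
      stop("missing values in covariate '", pd$covariate,
           "' (carry forward before fitting)", call. = FALSE)
    info <- .cvd_covariate_catalogue[[pd$covariate]]
    X[, d] <- if (info$type == "numeric") {
      as.numeric(col) - .center_of(centers, pd$covariate, info$center)
    } else {
      as.numeric(as.character(col) == pd$level)
    }
  }
  X
}

# Preprocess histories into the interval table the likelihood engine
# consumes.  `trans_dummies` is a named list (by transition) of dummy names.
.build_intervals <- function(data, trans_dummies, centers = NULL) {
  validate_histories(data)
  data <- data[order(data$subject_id, data$age), , drop = FALSE]
  n <- nrow(data)
  from <- which(data$subject_id[-n] == data$subject_id[-1L])
  if (length(from) == 0L)
    stop("no observation intervals (every subject has a single record)",
         call. = FALSE)
  to <- from + 1L
  from_state <- data$state[from]
  to_state <- data$state[to]
  type <- data$obs_type[to]
  if (any(bad <- from_state == 1 & type == "exact_transition" &
            to_state != 2))
    stop("exact_transition must enter state 2", call. = FALSE)
  if (any(bad <- from_state == 2 & type == "exact_transition"))
    stop("exact_transition from state 2 is impossible (no recovery); ",
         "offender: ", data$subject_id[from][bad][1L], call. = FALSE)
  fromdat <- data[from, , drop = FALSE]
  X <- lapply(trans_dummies, function(d) .data_design(fromdat, d, centers))
  list(n = length(from),
       a0 = data$age[from], aend = data$age[to],
       tt = data$age[to] - data$age[from],
       from_state = from_state, to_state = to_state, type = type,
       subject = data$subject_id[from],
       X = X,
       n_subjects = length(unique(data$subject_id)))
}

# Flat grid-cell layout for a set of intervals: every interval is split
# into cells of width `step` (last cell truncated), all cells concatenated.
# Depends only on the interval geometry, so it is computed once per fit and
# reused across likelihood evaluations.
.make_cells <- function(a0, tt, step) {
  n <- length(tt)
  nc <- pmax(ceiling(tt / step - 1e-9), 1L)
  idx <- rep.int(seq_len(n), nc)
  cs <- sequence(nc)
  w <- pmin(step, tt[idx] - (cs - 1L) * step)
  mid <- a0[idx] + (cs - 1L) * step + w / 2
  last <- cumsum(nc)
  list(idx = idx, w = w, mid = mid, n = n, last = last)
}

# Interval transition probabilities from a flat cell layout, without any
# cell loop: with per-cell exit rates a = q12+q13 and c = q23,
#   P11 = exp(-sum a w),   P22 = exp(-sum c w),
#   P12 = sum_j exp(-A^-_j) c12_j exp(-C^+_j)
# where A^-_j (C^+_j) are the within-interval partial sums of a w before
# (c w after) cell j; partial sums come from global cumsums differenced at
# the interval boundaries.
.flat_P <- function(cells, lp12, lp13, lp23, bage, age_center, cap) {
  idx <- cells$idx; w <- cells$w
  midc <- cells$mid - age_center
  q12 <- exp(lp12[idx] + bage[1L] * midc)
  q13 <- exp(lp13[idx] + bage[2L] * midc)
  q23 <- exp(lp23[idx] + bage[3L] * midc)
  if (cap) {
    q12 <- pmin(q12, 1e8); q13 <- pmin(q13, 1e8); q23 <- pmin(q23, 1e8)
  }
  a <- q12 + q13
  A <- a * w
  C <- q23 * w
  last <- cells$last
  n <- cells$n
  cA <- cumsum(A)
  cC <- cumsum(C)
  baseA <- c(0, cA[last[-n]])
  baseC <- c(0, cC[last[-n]])
  totA <- cA[last] - baseA
  totC <- cC[last] - baseC
  P11 <- exp(-totA)
  P22 <- exp(-totC)
  u <- (q23 - a) * w
  g <- -expm1(-u) / u       # (1 - e^-u)/u, stable; only u == 0 degenerates
  g[u == 0] <- 1
  term <- q12 * w * exp(-a * w) * g *
    exp(-((cA - A - baseA[idx]) + (totC[idx] - (cC - baseC[idx]))))
  cT <- cumsum(term)
  P12 <- cT[last] - c(0, cT[last[-n]])
  list(p11 = P11, p12 = P12, p13 = pmax(1 - P11 - P12, 0),
       p22 = P22, p23 = pmax(1 - P22, 0))
}

# Should runaway intensities be capped?  Only when the linear predictors
# plus the largest age term could overflow exp().  (-Inf structural zeros
# are harmless under max().)
.need_cap <- function(lps, bage, ages, age_center) {
  lpmax <- max(lps[[1L]], lps[[2L]], lps[[3L]], -Inf)
  amax <- max(abs(range(ages, age_center) - age_center), 0)
  is.finite(lpmax) && lpmax + max(abs(bage)) * amax > log(1e8)
}

# Log-likelihood contributions for an interval table given per-transition
# intercepts lb, age slopes bage, and coefficient vectors (list by
# transition; must match tab$X columns).  Returns the n-vector of
# contributions.  `exact_onsets` states that nonfatal onsets are registry
# dated: a death with no preceding onset record is then known to occur from
# state 1 and the unknown-pre-death-state mixture must not be used (the
# mixture would credit disease paths that would have produced an onset
# record, which is not a proper likelihood for that design and biases the
# age slopes).
.tab_loglik <- function(tab, lb, bage, betas, age_center, step,
                        exact_onsets = FALSE, cells = NULL) {
  lp <- list()
  for (tr in .cvd_transitions) {
    lp[[tr]] <- if (is.finite(lb[[tr]])) {
      b <- betas[[tr]]
      v <- rep(lb[[tr]], tab$n)
      if (length(b)) v <- v + as.vector(tab$X[[tr]][, names(b),
                                                    drop = FALSE] %*% b)
      v
    } else rep(-Inf, tab$n)
  }
  ba <- c(bage[["1-2"]] %||% 0, bage[["1-3"]] %||% 0, bage[["2-3"]] %||% 0)
  if (all(ba == 0)) {
    # time homogeneous: one cell per interval is exact
    P <- .interval_P(tab$a0, tab$tt, lp[["1-2"]], lp[["1-3"]],
                     lp[["2-3"]], ba, age_center, step)
  } else {
    if (is.null(cells)) cells <- .make_cells(tab$a0, tab$tt, step)
    cap <- .need_cap(lp, ba, range(tab$a0, tab$aend), age_center)
    P <- .flat_P(cells, lp[["1-2"]], lp[["1-3"]], lp[["2-3"]], ba,
                 age_center, cap)
  }
  ll <- numeric(tab$n)
  f1 <- tab$from_state == 1L
  panel <- tab$type == "panel"
  aend_c <- tab$aend - age_center
  i <- which(f1 & panel & tab$to_state == 1L); ll[i] <- log(P$p11[i])
  i <- which(f1 & panel & tab$to_state == 2L); ll[i] <- log(P$p12[i])
  i <- which(f1 & panel & tab$to_state == 3L); ll[i] <- log(P$p13[i])
  i <- which(!f1 & panel & tab$to_state == 2L); ll[i] <- log(P$p22[i])
  i <- which(!f1 & panel & tab$to_state == 3L); ll[i] <- log(P$p23[i])
  i <- which(f1 & tab$type == "exact_transition")
  if (length(i))
    ll[i] <- log(P$p11[i]) + lp[["1-2"]][i] + ba[1L] * aend_c[i]
  i <- which(f1 & tab$type == "exact_death")
  if (length(i)) {
    q13e <- exp(lp[["1-3"]][i] + ba[2L] * aend_c[i])
    q13e[!is.finite(q13e)] <- 0
    if (exact_onsets) {
      ll[i] <- log(P$p11[i] * q13e)
    } else {
      q23e <- exp(lp[["2-3"]][i] + ba[3L] * aend_c[i])
      q23e[!is.finite(q23e)] <- 0
      ll[i] <- log(P$p11[i] * q13e + P$p12[i] * q23e)
    }
  }
  i <- which(!f1 & tab$type == "exact_death")
  if (length(i))
    ll[i] <- log(P$p22[i]) + lp[["2-3"]][i] + ba[3L] * aend_c[i]
  i <- which(f1 & tab$type == "alive")
  if (length(i)) ll[i] <- log(P$p11[i] + P$p12[i])
  i <- which(!f1 & tab$type == "alive")
  if (length(i)) ll[i] <- log(P$p22[i])
  ll
}

# Map a cvd_params object onto the engine arguments.
.params_engine_args <- function(params) {
  lb <- stats::setNames(rep(-Inf, 3L), .cvd_transitions)
  ba <- stats::setNames(numeric(3L), .cvd_transitions)
  betas <- stats::setNames(vector("list", 3L), .cvd_transitions)
  for (tr in names(params$transitions)) {
    el <- params$transitions[[tr]]
    lb[[tr]] <- el$log_baseline
    ba[[tr]] <- el$beta_age
    betas[[tr]] <- el$betas
  }
  list(lb = lb, bage = as.list(ba), betas = betas)
}

#' Log-likelihood contribution of one observation interval
#'
#' Evaluates the panel-data likelihood contribution of a pair of consecutive
#' observation records, with covariates fixed at the earlier record's values
#' over the interval.  The contribution depends on the later record's
#' observation type: a panel observation contributes the interval transition
#' probability; an exactly dated disease onset contributes survival free of
#' disease times the onset intensity at the event age; an exactly dated
#' death contributes the density of death, summing over the (unknown) state
#' occupied just before death.
#'
#' @param rec_from,rec_to Observation records ([observation_record()] or
#'   lists with fields `age`, `state`, `obs_type`, `covariates`);
#'   `rec_to$age` must exceed `rec_from$age` and `rec_from$state` must be 1
#'   or 2.
#' @param params A [param_set()].
#' @param step Grid width (years) of the piecewise-constant-in-age
#'   approximation.
#' @param exact_onsets If `TRUE`, nonfatal onsets are registry dated, so a
#'   death record not preceded by an onset record is known to occur from
#'   state 1 and the contribution is `P11 * q13` rather than the
#'   unknown-pre-death-state mixture (which is the correct form when onsets
#'   are only panel observed, and the default).
#' @return The log-likelihood contribution (a single number).
#' @export
interval_log_likelihood <- function(rec_from, rec_to, params, step = 0.25,
                                    exact_onsets = FALSE) {
  stopifnot(inherits(params, "cvd_params"))
  if (!rec_from$state %in% c(1L, 2L))
    stop("interval must start in a transient state (1 or 2)",
         call. = FALSE)
  if (rec_to$age <= rec_from$age)
    stop("records out of order: ages ", rec_from$age, " -> ", rec_to$age,
         call. = FALSE)
  if (!is.na(rec_to$state) && rec_to$state < rec_from$state)
    stop("impossible state pair ", rec_from$state, " -> ", rec_to$state,
         " (no recovery) at ages ", rec_from$age, " -> ", rec_to$age,
         call. = FALSE)
  pl <- .profile_lp(params, rec_from$covariates)
  P <- .interval_P(rec_from$age, rec_to$age - rec_from$age,
                   pl$lp[["1-2"]], pl$lp[["1-3"]], pl$lp[["2-3"]],
                   pl$beta_age, pl$age_center, step)
  aend_c <- rec_to$age - pl$age_center
  qe <- exp(pl$lp + pl$beta_age * aend_c)
  qe[!is.finite(qe)] <- 0
  from1 <- rec_from$state == 1L
  switch(rec_to$obs_type,
    panel = {
      if (from1) {
        log(c(P$p11, P$p12, P$p13)[rec_to$state])
      } else {
        log(c(NA, P$p22, P$p23)[rec_to$state])
      }
    },
    exact_transition = {
      if (!from1 || rec_to$state != 2L)
        stop("exact_transition must be a 1 -> 2 interval", call. = FALSE)
      log(P$p11) + log(qe[["1-2"]])
    },
    exact_death = {
      if (!from1) log(P$p22 * qe[["2-3"]])
      else if (exact_onsets) log(P$p11 * qe[["1-3"]])
      else log(P$p11 * qe[["1-3"]] + P$p12 * qe[["2-3"]])
    },
    alive = if (from1) log(P$p11 + P$p12) else log(P$p22))
}

#' Log-likelihood of a cohort of observation histories
#'
#' Sums [interval_log_likelihood()] over all consecutive record pairs of all
#' subjects (vectorised).  Records in the absorbing state contribute nothing
#' further; a subject with only a baseline record contributes 0.
#'
#' @param data Long-format observation data (see [validate_histories()]).
#' @param params A [param_set()].
#' @param step Grid width (years) for the age discretisation.
#' @inheritParams interval_log_likelihood
#' @return The cohort log-likelihood.
#' @export
cohort_log_likelihood <- function(data, params, step = 0.25,
                                  exact_onsets = FALSE) {
  stopifnot(inherits(params, "cvd_params"))
  if (is.null(data) || nrow(data) == 0L)
    stop("data is empty", call. = FALSE)
  one_rec <- !anyDuplicated(data$subject_id)
  if (one_rec) {
    validate_histories(data)
    return(0)
  }
  td <- lapply(stats::setNames(nm = names(params$transitions)),
               function(tr) names(params$transitions[[tr]]$betas))
  tab <- .build_intervals(data, td, params$centers)
  ea <- .params_engine_args(params)
  sum(.tab_loglik(tab, ea$lb, ea$bage, ea$betas, params$age_center, step,
                  exact_onsets = exact_onsets))
}
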