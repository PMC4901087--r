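# Core of the illness-death model: transition intensity matrices and
# transition probability matrices over age intervals.
#
# States: 1 = disease free, 2 = nonfatal CVD, 3 = all-cause death (absorbing).
# Allowed moves: 1->2, 1->3, 2->3; no recovery.  Intensities follow a
# proportional-hazards form with log-linear (Gompertz-type) age dependence:
#   q_ij(age, z) = exp(log_baseline_ij + beta_age_ij (age - age_center)
#                      + beta_ij' z).

# Constant-intensity transition probabilities over elapsed times `w`
# (vectorised; all arguments recycled to a common length).  Uses the
# analytic solution of the triangular generator:
#   P11 = e^{-a w},  a = q12 + q13
#   P12 = q12 w e^{-a w} g((q23 - a) w),  g(u) = (1 - e^{-u})/u, g(0) = 1
#   P22 = e^{-q23 w}
# with remaining entries by row-stochasticity.  The g() series keeps the
# q23 -> a limit numerically stable.
.p_cells <- function(q12, q13, q23, w) {
  a <- q12 + q13
  e_a <- exp(-a * w)
  e_c <- exp(-q23 * w)
  u <- (q23 - a) * w
  small <- abs(u) < 1e-7
  g <- numeric(length(u))
  g[small] <- 1 - u[small] / 2 + u[small]^2 / 6
  g[!small] <- -expm1(-u[!small]) / u[!small]
  p12 <- q12 * w * e_a * g
  list(p11 = e_a, p12 = p12, p13 = pmax(1 - e_a - p12, 0),
       p22 = e_c, p23 = pmax(1 - e_c, 0))
}

# Transition probabilities over n age intervals with piecewise-constant
# intensities on a grid of width `step`; Q is evaluated at each grid cell's
# midpoint, making the discretisation error O(step^2).  Inputs are the
# interval start ages a0, lengths tt, per-transition linear predictors
# (lp12, lp13, lp23; -Inf encodes a structural zero), age slopes `bage`
# (length 3: 1-2, 1-3, 2-3) and the centring age.  When all age slopes are
# zero the process is time homogeneous and a single cell is exact; set
# `force_grid = TRUE` to multiply over the grid regardless.
#
# This sits in the innermost loop of the likelihood: intervals are sorted
# by cell count so the active set is always a prefix, the cell update is
# inlined with only the entries the product needs (p11, p12, p22), and
# intensities are capped at 1e8/yr (which already saturates every
# probability) only when the parameters could overflow.
.interval_P <- function(a0, tt, lp12, lp13, lp23, bage, age_center, step,
                        force_grid = FALSE) {
  n <- length(tt)
  if (!force_grid && all(bage == 0)) {
    cc <- .p_cells(pmin(exp(lp12), 1e8), pmin(exp(lp13), 1e8),
                   pmin(exp(lp23), 1e8), tt)
    return(cc)
  }
  nc <- pmax(ceiling(tt / step - 1e-9), 0L)
  ord <- order(nc, decreasing = TRUE)
  a0s <- a0[ord]; tts <- tt[ord]; ncs <- nc[ord]
  l12 <- lp12[ord]; l13 <- lp13[ord]; l23 <- lp23[ord]
  p11 <- rep(1, n); p12 <- numeric(n); p22 <- rep(1, n)
  lpmax <- suppressWarnings(
    max(l12[is.finite(l12)], l13[is.finite(l13)], l23[is.finite(l23)],
        -Inf))
  amax <- max(abs(range(a0s, a0s + tts, age_center) - age_center), 0)
  cap <- is.finite(lpmax) && lpmax + max(abs(bage)) * amax > log(1e8)
  m <- n
  maxc <- if (n) ncs[1L] else 0L
  for (k in seq_len(maxc)) {
    while (m > 0L && ncs[m] < k) m <- m - 1L
    if (m == 0L) break
    i <- seq_len(m)
    s0 <- (k - 1) * step
    w <- pmin(step, tts[i] - s0)
    mid <- a0s[i] + s0 + w / 2 - age_center
    q12 <- exp(l12[i] + bage[1L] * mid)
    q13 <- exp(l13[i] + bage[2L] * mid)
    q23 <- exp(l23[i] + bage[3L] * mid)
    if (cap) {
      q12 <- pmin(q12, 1e8); q13 <- pmin(q13, 1e8); q23 <- pmin(q23, 1e8)
    }
    a <- q12 + q13
    e_a <- exp(-a * w)
    e_c <- exp(-q23 * w)
    u <- (q23 - a) * w
    g <- -expm1(-u) / u
    sm <- which(abs(u) < 1e-7)
    if (length(sm)) g[sm] <- 1 - u[sm] / 2 + u[sm]^2 / 6
    c12 <- q12 * w * e_a * g
    t11 <- p11[i]
    p11[i] <- t11 * e_a
    p12[i] <- t11 * c12 + p12[i] * e_c
    p22[i] <- p22[i] * e_c
  }
  P11 <- numeric(n); P12 <- numeric(n); P22 <- numeric(n)
  P11[ord] <- p11; P12[ord] <- p12; P22[ord] <- p22
  list(p11 = P11, p12 = P12, p13 = pmax(1 - P11 - P12, 0),
       p22 = P22, p23 = pmax(1 - P22, 0))
}

.assemble_P <- function(p) {
  matrix(c(p$p11, 0, 0,
           p$p12, p$p22, 0,
           p$p13, p$p23, 1), nrow = 3,
         dimnames = list(paste0("from", 1:3), paste0("to", 1:3)))
}

#' Transition intensity matrix
#'
#' Evaluates the 3x3 generator matrix Q (units 1/year) of the illness-death
#' model at a given age for a covariate profile, under the
#' proportional-hazards intensity model.
#'
#' @param params A [param_set()].
#' @param profile A [covariate_profile()] (or named list of covariate
#'   values) supplying every covariate named in `params`.
#' @param age Age in years at which to evaluate the intensities.
#' @return A 3x3 matrix with nonnegative off-diagonal entries for the
#'   allowed transitions, zero rows sums, and an all-zero absorbing row.
#' @export
intensity_matrix <- function(params, profile, age) {
  stopifnot(inherits(params, "cvd_params"))
  pl <- .profile_lp(params, profile)
  q <- exp(pl$lp + pl$beta_age * (age - pl$age_center))
  q[!is.finite(q)] <- 0  # structural zeros (lp = -Inf)
  Q <- matrix(0, 3, 3, dimnames = list(paste0("from", 1:3),
                                       paste0("to", 1:3)))
  Q[1, 2] <- q[["1-2"]]; Q[1, 3] <- q[["1-3"]]; Q[2, 3] <- q[["2-3"]]
  Q[1, 1] <- -(Q[1, 2] + Q[1, 3]); Q[2, 2] <- -Q[2, 3]
  Q
}

#' Transition probability matrix over an age interval
#'
#' Computes P(a_start, a_end), the matrix of probabilities of occupying each
#' state at age `a_end` given the state at age `a_start`, by
#' product-integration: the interval is split into grid cells of width
#' `step` and Q, evaluated at each cell midpoint, is taken constant within
#' the cell.  When the intensities do not depend on age the result is exact
#' and independent of `step`.
#'
#' @inheritParams intensity_matrix
#' @param a_start,a_end Interval endpoints in years, `a_end >= a_start`.
#' @param step Grid width in years (default 0.25).
#' @return A row-stochastic 3x3 matrix respecting the no-recovery structure.
#' @export
transition_probability <- function(params, profile, a_start, a_end,
                                   step = 0.25) {
  stopifnot(inherits(params, "cvd_params"))
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("'step' must be a positive number", call. = FALSE)
  if (a_end < a_start)
    stop("'a_end' must be >= 'a_start'", call. = FALSE)
  pl <- .profile_lp(params, profile)
  p <- .interval_P(a_start, a_end - a_start,
                   pl$lp[["1-2"]], pl$lp[["1-3"]], pl$lp[["2-3"]],
                   pl$beta_age, pl$age_center, step, force_grid = TRUE)
  .assemble_P(p)
}

#' Closed-form transition probabilities for constant intensities
#'
#' Analytic solution of the time-homogeneous illness-death model, used as an
#' independent oracle for [transition_probability()].  With a = q12 + q13:
#' P11 = exp(-a t); P12 = q12 (exp(-a t) - exp(-q23 t)) / (q23 - a) when
#' q23 != a and q12 t exp(-a t) in the limit q23 = a; P22 = exp(-q23 t);
#' remaining entries by row-stochasticity.
#'
#' @param q12,q13,q23 Constant transition intensities (1/year), nonnegative.
#' @param t Elapsed time in years, nonnegative.
#' @return A row-stochastic 3x3 matrix.
#' @export
closed_form_tpm <- function(q12, q13, q23, t) {
  stopifnot(q12 >= 0, q13 >= 0, q23 >= 0, t >= 0)
  a <- q12 + q13
  p11 <- exp(-a * t)
  p22 <- exp(-q23 * t)
  p12 <- if (abs(q23 - a) < 1e-12 * max(1, a)) {
    q12 * t * p11
  } else {
    q12 * (p11 - p22) / (q23 - a)
  }
  matrix(c(p11, 0, 0,
           p12, p22, 0,
           1 - p11 - p12, 1 - p22, 1), nrow = 3,
         dimnames = list(paste0("from", 1:3), paste0("to", 1:3)))
}
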