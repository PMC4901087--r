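# Maximum-likelihood estimation of the transition intensity parameters.

# Crude event/person-time initial values: deterministic and robust.  Each
# transition's initial baseline rate is (events + 0.5) / person-time at risk
# in the source state; age slopes and covariate effects start at 0.
.crude_init <- function(tab, spec) {
  pt1 <- sum(tab$tt[tab$from_state == 1L])
  pt2 <- sum(tab$tt[tab$from_state == 2L])
  ev <- c("1-2" = sum(tab$from_state == 1L & tab$to_state == 2L,
                      na.rm = TRUE),
          "1-3" = sum(tab$from_state == 1L & tab$to_state == 3L,
                      na.rm = TRUE),
          "2-3" = sum(tab$from_state == 2L & tab$to_state == 3L,
                      na.rm = TRUE))
  pt <- c("1-2" = pt1, "1-3" = pt1, "2-3" = pt2)
  par <- stats::setNames(numeric(length(.par_names(spec))),
                         .par_names(spec))
  for (tr in spec$transitions) {
    if (ev[[tr]] == 0)
      warning("no observed events for transition ", tr,
              "; the corresponding intensity may be driven to the ",
              "boundary (baseline -> 0)", call. = FALSE)
    par[paste0(tr, ".log_baseline")] <-
      log((ev[[tr]] + 0.5) / max(pt[[tr]], 1e-8))
  }
  attr(par, "events") <- ev
  par
}

#' Fit the illness-death model to panel-observed cohort data
#'
#' Maximises the panel-data log-likelihood over the parameters declared by
#' a [model_spec()] using quasi-Newton (BFGS) optimisation, and estimates
#' the parameter covariance as the inverse of the numerically differentiated
#' observed information at the optimum.
#'
#' @param data Long-format observation data (see [validate_histories()]).
#' @param spec A [model_spec()] naming transitions and covariates.
#' @param init Optional initial [param_set()]; the default initialises log
#'   baselines at crude event/person-time rates and all other coefficients
#'   at zero.
#' @param options List of fitting options: `step` (age-discretisation grid
#'   width in years, default 0.5), `maxit` (default 500), `reltol` (default
#'   1e-10), `hessian` (compute the covariance, default TRUE),
#'   `exact_onsets` (are nonfatal onsets registry dated? see
#'   [interval_log_likelihood()]; `NULL`, the default, infers `TRUE` when
#'   the data contain `exact_transition` records).
#' @return An object of class `cvd_fit` with components `estimates` (a
#'   [param_set()]), `covariance`, `loglik`, `converged`, `n_subjects`,
#'   `n_transitions` (observed event counts per transition), `par` (the
#'   flat parameter vector), `spec` and `options`.  Non-convergence is
#'   flagged, not raised.
#' @export
fit_model <- function(data, spec, init = NULL, options = list()) {
  stopifnot(inherits(spec, "cvd_model_spec"))
  opts <- utils::modifyList(
    list(step = 0.5, maxit = 500L, reltol = 1e-10, hessian = TRUE,
         exact_onsets = NULL),
    options, keep.null = TRUE)
  if (is.null(opts$exact_onsets))
    opts$exact_onsets <- any(data$obs_type == "exact_transition")
  td <- lapply(stats::setNames(nm = spec$transitions),
               function(tr) .spec_dummies(spec, tr))
  tab <- .build_intervals(data, td, as.list(spec$centers))
  par0 <- .crude_init(tab, spec)
  ev <- attr(par0, "events")
  attr(par0, "events") <- NULL
  if (!is.null(init)) {
    stopifnot(inherits(init, "cvd_params"))
    par0[] <- .flatten_params(init, spec)
  }
  nms <- names(par0)
  lb_idx <- match(paste0(.cvd_transitions, ".log_baseline"), nms)
  ba_idx <- match(paste0(.cvd_transitions, ".beta_age"), nms)
  beta_idx <- lapply(stats::setNames(nm = spec$transitions), function(tr) {
    d <- td[[tr]]
    stats::setNames(match(paste(tr, d, sep = ".", recycle0 = TRUE), nms),
                    d)
  })
  engine_args <- function(par) {
    lb <- ifelse(is.na(lb_idx), -Inf, par[lb_idx])
    ba <- ifelse(is.na(ba_idx), 0, par[ba_idx])
    names(lb) <- names(ba) <- .cvd_transitions
    betas <- lapply(beta_idx, function(ii) stats::setNames(par[ii],
                                                           names(ii)))
    list(lb = as.list(lb), bage = as.list(ba), betas = betas)
  }
  cells <- .make_cells(tab$a0, tab$tt, opts$step)
  negll <- function(par) {
    ea <- engine_args(par)
    v <- -sum(.tab_loglik(tab, ea$lb, ea$bage, ea$betas,
                          spec$age_center, opts$step,
                          exact_onsets = opts$exact_onsets,
                          cells = cells))
    if (!is.finite(v)) v <- 1e10
    v
  }
  opt <- stats::optim(par0, negll, method = "BFGS",
                      control = list(maxit = opts$maxit,
                                     reltol = opts$reltol))
  par <- stats::setNames(opt$par, nms)
  covariance <- NULL
  if (isTRUE(opts$hessian)) {
    H <- try(stats::optimHess(par, negll), silent = TRUE)
    if (!inherits(H, "try-error")) {
      covariance <- try(solve((H + t(H)) / 2), silent = TRUE)
      if (inherits(covariance, "try-error") ||
          any(diag(covariance) < 0)) {
        warning("observed information is singular or indefinite; using a ",
                "pseudo-inverse for the covariance", call. = FALSE)
        covariance <- MASS::ginv((H + t(H)) / 2)
      }
      dimnames(covariance) <- list(nms, nms)
    } else {
      warning("Hessian computation failed; no covariance available",
              call. = FALSE)
    }
  }
  structure(list(
    estimates = .unflatten_params(par, spec),
    covariance = covariance,
    loglik = -opt$value,
    converged = opt$convergence == 0L,
    n_subjects = tab$n_subjects,
    n_intervals = tab$n,
    n_transitions = ev,
    par = par,
    spec = spec,
    options = opts), class = "cvd_fit")
}

#' @export
print.cvd_fit <- function(x, ...) {
  cat("Illness-death model fit\n")
  cat(sprintf("  subjects: %d, intervals: %d, log-likelihood: %.3f\n",
              x$n_subjects, x$n_intervals, x$loglik))
  cat(sprintf("  converged: %s\n", x$converged))
  cat(sprintf("  observed events: %s\n",
              paste(sprintf("%s: %d", names(x$n_transitions),
                            x$n_transitions), collapse = ", ")))
  print(x$estimates)
  invisible(x)
}

#' Hazard-ratio table for one transition
#'
#' Exponentiates the fitted covariate coefficients of a transition into
#' hazard ratios with Wald 95% confidence intervals,
#' `exp(beta +- 1.96 SE)`.
#'
#' @param fit A converged [fit_model()] result.
#' @param transition `"1-2"`, `"1-3"` or `"2-3"`.
#' @param level Confidence level (default 0.95).
#' @return A data frame with columns `covariate`, `hr`, `lower`, `upper`,
#'   `se_log`.
#' @export
hazard_ratios <- function(fit, transition, level = 0.95) {
  stopifnot(inherits(fit, "cvd_fit"))
  if (!transition %in% fit$spec$transitions)
    stop("unknown transition: ", transition, call. = FALSE)
  dn <- .spec_dummies(fit$spec, transition)
  if (length(dn) == 0L)
    return(data.frame(covariate = character(0), hr = numeric(0),
                      lower = numeric(0), upper = numeric(0),
                      se_log = numeric(0)))
  pn <- paste(transition, dn, sep = ".")
  beta <- fit$par[pn]
  se <- if (!is.null(fit$covariance)) sqrt(diag(fit$covariance)[pn])
        else rep(NA_real_, length(pn))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(covariate = dn,
             hr = exp(unname(beta)),
             lower = exp(unname(beta - z * se)),
             upper = exp(unname(beta + z * se)),
             se_log = unname(se),
             row.names = NULL)
}
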