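# Panel-data likelihood: closed-form oracles, additivity, invariances,
# estimation on degenerate and simulated designs.

rec <- function(age, state, type = "panel")
  observation_record(age, state, type, covariates = list(sex = "male"))

test_that("interval contributions match hand-derived closed forms", {
  p <- toy_params()
  P11 <- exp(-0.5)
  P12 <- 0.4 * (exp(-0.5) - exp(-1))
  expect_equal(interval_log_likelihood(rec(50, 1), rec(60, 1), p),
               log(P11), tolerance = 1e-10)
  expect_equal(interval_log_likelihood(rec(50, 1), rec(60, 2), p),
               log(P12), tolerance = 1e-10)
  expect_equal(
    interval_log_likelihood(rec(50, 1), rec(60, 3, "exact_death"), p),
    log(P11 * 0.03 + P12 * 0.10), tolerance = 1e-10)
  expect_equal(
    interval_log_likelihood(rec(50, 1), rec(60, 2, "exact_transition"), p),
    log(P11 * 0.02), tolerance = 1e-10)
  # registry-dated onsets: a death with no onset record comes from state 1
  expect_equal(
    interval_log_likelihood(rec(50, 1), rec(60, 3, "exact_death"), p,
                            exact_onsets = TRUE),
    log(P11 * 0.03), tolerance = 1e-10)
  # from the diseased state
  expect_equal(interval_log_likelihood(rec(55, 2), rec(60, 2), p),
               -0.5, tolerance = 1e-10)
  expect_equal(
    interval_log_likelihood(rec(55, 2), rec(60, 3, "exact_death"), p),
    log(exp(-0.5) * 0.10), tolerance = 1e-10)
  # known alive, state unobserved
  expect_equal(interval_log_likelihood(rec(50, 1),
                                       rec(60, NA, "alive"), p),
               log(P11 + P12), tolerance = 1e-10)
})

test_that("impossible intervals are rejected with context", {
  p <- toy_params()
  expect_error(interval_log_likelihood(rec(60, 1), rec(50, 1), p),
               "out of order")
  expect_error(interval_log_likelihood(rec(50, 2), rec(60, 1), p),
               "no recovery")
  expect_error(interval_log_likelihood(rec(50, 3, "exact_death"),
                                       rec(60, 3, "exact_death"), p),
               "transient")
})

test_that("cohort log-likelihood is the sum of interval contributions", {
  p <- toy_params()
  d <- toy_histories()
  P11 <- exp(-0.5)
  P12 <- 0.4 * (exp(-0.5) - exp(-1))
  by_hand <- log(P11) +                      # A: panel 1 -> 1 over 10 y
    log(P11 * 0.02) +                        # B: exact onset at 10 y
    log(exp(-0.5) * 0.10)                    # B: exact death 5 y later
  expect_equal(cohort_log_likelihood(d, p), by_hand, tolerance = 1e-10)
  # additivity: k copies give k times the value
  d3 <- do.call(rbind, lapply(1:3, function(k) {
    dk <- toy_histories(); dk$subject_id <- paste0(dk$subject_id, k); dk
  }))
  expect_equal(cohort_log_likelihood(d3, p), 3 * by_hand,
               tolerance = 1e-10)
  # a subject with only a baseline record contributes nothing
  d0 <- data.frame(subject_id = "Z", age = 55, state = 1L,
                   obs_type = "panel", sex = "male")
  expect_equal(cohort_log_likelihood(d0, p), 0)
  expect_error(cohort_log_likelihood(d[0, ], p), "empty")
})

test_that("history validation catches structural violations", {
  d <- toy_histories()
  bad <- d; bad$age[2] <- bad$age[1]   # duplicate contact age
  expect_error(validate_histories(bad), "increasing")
  bad <- d; bad$state[4] <- 1L; bad$obs_type[4] <- "panel"
  bad$state[5] <- 1L; bad$obs_type[5] <- "panel"
  expect_silent(validate_histories(bad))
  bad$state[4] <- 2L
  expect_error(validate_histories(bad), "backwards")
  bad <- d; bad$state[1:2] <- 2L
  expect_error(validate_histories(bad), "first record")
  bad <- rbind(d, data.frame(subject_id = "B", age = 70, state = 3L,
                             obs_type = "exact_death", sex = "male"))
  expect_error(validate_histories(bad), "absorbing")
  bad <- d; bad$obs_type[1] <- "alive"; bad$state[1] <- NA
  expect_error(validate_histories(bad), "last")
})

test_that("time-homogeneous likelihood is invariant to a common age shift", {
  truth <- homogeneous_truth()
  coh <- simulate_cohort(simulation_config(
    n_subjects = 150, true_params = truth), seed = 77)
  d <- coh$data
  ll1 <- cohort_log_likelihood(d, truth)
  d2 <- d; d2$age <- d$age + 8
  truth2 <- truth; truth2$age_center <- truth$age_center + 8
  expect_equal(cohort_log_likelihood(d2, truth2), ll1, tolerance = 1e-10)
})

test_that("exact-death contribution equals the numerical death density", {
  p <- gompertz_truth()
  prof <- list(sex = "female")
  contrib <- exp(interval_log_likelihood(
    observation_record(55, 1, covariates = prof),
    observation_record(63, 3, "exact_death", covariates = prof),
    p, step = 0.005))
  h <- 0.01
  cp <- covariate_profile(sex = "female")
  dens <- (transition_probability(p, cp, 55, 63 + h, step = 0.005)[1, 3] -
           transition_probability(p, cp, 55, 63 - h, step = 0.005)[1, 3]) /
    (2 * h)
  expect_equal(contrib, dens, tolerance = 1e-4)
})

test_that("likelihood matches an independent Gompertz survival likelihood", {
  truth <- param_set(list(
    "1-3" = list(log_baseline = log(0.006), beta_age = 0.09,
                 betas = c(sex_female = -0.40))))
  coh <- simulate_cohort(simulation_config(
    n_subjects = 500, true_params = truth), seed = 303)
  d <- coh$data
  base <- d[!duplicated(d$subject_id), ]
  last <- d[!duplicated(d$subject_id, fromLast = TRUE), ]
  hr <- ifelse(base$sex == "female", exp(-0.40), 1)
  H <- function(x, y) 0.006 / 0.09 * (exp(0.09 * (y - 50)) -
                                        exp(0.09 * (x - 50)))
  dead <- last$state == 3
  by_hand <- sum(-hr * H(base$age, last$age)) +
    sum(log(0.006 * hr[dead] * exp(0.09 * (last$age[dead] - 50))))
  expect_equal(cohort_log_likelihood(d, truth, step = 0.05), by_hand,
               tolerance = 1e-6)
})

test_that("degenerate exponential design has the crude-rate MLE", {
  # two subjects, exact deaths 2 and 3 years after baseline, death-only
  # model without covariates: qhat = events / person-time = 2/5
  d <- data.frame(subject_id = c("A", "A", "B", "B"),
                  age = c(60, 62, 60, 63),
                  state = c(1L, 3L, 1L, 3L),
                  obs_type = c("panel", "exact_death", "panel",
                               "exact_death"),
                  stringsAsFactors = FALSE)
  fit <- fit_model(d, model_spec(transitions = "1-3",
                                 age_model = "none"))
  expect_true(fit$converged)
  expect_equal(exp(fit$par[["1-3.log_baseline"]]), 0.4,
               tolerance = 1e-4)
})

test_that("the optimum is no worse than the generating parameters", {
  truth <- homogeneous_truth()
  coh <- simulate_cohort(simulation_config(
    n_subjects = 400, true_params = truth), seed = 88)
  spec <- model_spec(covariates = c("sex", "vigorous_pa"),
                     age_model = "none")
  fit <- fit_model(coh$data, spec, init = truth,
                   options = list(hessian = FALSE))
  expect_true(fit$converged)
  expect_gte(fit$loglik,
             cohort_log_likelihood(coh$data, truth,
                                   exact_onsets = TRUE) - 1e-6)
})

test_that("a Gompertz fit recovers generating parameters within noise", {
  truth <- gompertz_truth()
  coh <- simulate_cohort(simulation_config(
    n_subjects = 2000, true_params = truth), seed = 11)
  spec <- model_spec(covariates = "sex")
  fit <- fit_model(coh$data, spec, options = list(reltol = 1e-9))
  expect_true(fit$converged)
  tr <- cvdle:::.flatten_params(truth, spec)
  z <- (fit$par - tr) / sqrt(diag(fit$covariance))
  expect_true(all(abs(z) < 4))
})

test_that("hazard ratios exponentiate coefficients with Wald intervals", {
  fake <- structure(list(
    par = c("1-2.log_baseline" = log(0.01), "1-2.smoking_never" = log(2),
            "1-2.smoking_former" = 0),
    covariance = diag(c(0.01, 0.01, 0.04)),
    spec = model_spec(transitions = "1-2", covariates = "smoking",
                      age_model = "none"),
    converged = TRUE), class = "cvd_fit")
  dimnames(fake$covariance) <- list(names(fake$par), names(fake$par))
  h <- hazard_ratios(fake, "1-2")
  i <- match("smoking_never", h$covariate)
  z975 <- stats::qnorm(0.975)
  expect_equal(h$hr[i], 2)
  expect_equal(h$lower[i], 2 * exp(-z975 * 0.1), tolerance = 1e-10)
  expect_equal(h$upper[i], 2 * exp(z975 * 0.1), tolerance = 1e-10)
  expect_equal(round(c(h$lower[i], h$upper[i]), 3), c(1.644, 2.433))
  j <- match("smoking_former", h$covariate)
  expect_equal(h$hr[j], 1)
  expect_true(h$lower[j] < 1 && h$upper[j] > 1)
  expect_error(hazard_ratios(fake, "2-3"), "unknown transition")
})
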