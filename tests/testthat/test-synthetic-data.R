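# Trajectory simulator and the panel observation scheme.

make_traj <- function(baseline_age = 60, cvd_age = NA, death_age = NA,
                      censor_age = 85, covs = list(sex = "male")) {
  path <- cbind(data.frame(age = baseline_age), as.data.frame(covs))
  structure(list(baseline_age = baseline_age, covariate_path = path,
                 cvd_age = cvd_age, death_age = death_age,
                 censor_age = censor_age), class = "cvd_trajectory")
}

test_that("no intensities means censored, disease-free trajectories", {
  p0 <- param_set(list())
  tr <- simulate_trajectory(p0, data.frame(age = 60, sex = "male"),
                            baseline_age = 60, censor_age = 80)
  expect_true(is.na(tr$cvd_age))
  expect_true(is.na(tr$death_age))
  rec <- apply_observation_scheme(tr, simulation_config())
  # baseline, two re-contacts, end of follow-up at the censoring age
  expect_equal(rec$age, c(60, 66, 72, 80))
  expect_true(all(rec$state == 1L))
})

test_that("exponential death times have the analytic truncated mean", {
  set.seed(606)
  n <- 20000
  censor <- 200
  q <- 0.05
  p <- param_set(list("1-3" = list(log_baseline = log(q))))
  lp <- cvdle:::.epoch_lp(p, list(data.frame(sex = rep("male", n))))
  r <- cvdle:::.sim_engine(rep(50, n), rep(50 + censor, n), lp[["1-2"]],
                           lp[["1-3"]], lp[["2-3"]], c(0, 0, 0), 50,
                           numeric(0), 0.05)
  t_obs <- pmin(ifelse(is.na(r$death_age), 50 + censor, r$death_age),
                50 + censor) - 50
  mean_true <- (1 - exp(-q * censor)) / q   # E[min(T, censor)]
  mc_se <- stats::sd(t_obs) / sqrt(n)
  expect_lt(abs(mean(t_obs) - mean_true), 3 * mc_se)
})

test_that("the cause split matches the competing-risk probability", {
  set.seed(607)
  n <- 20000
  p <- param_set(list(
    "1-2" = list(log_baseline = log(0.02)),
    "1-3" = list(log_baseline = log(0.03)),
    "2-3" = list(log_baseline = log(0.10))))
  lp <- cvdle:::.epoch_lp(p, list(data.frame(sex = rep("male", n))))
  r <- cvdle:::.sim_engine(rep(50, n), rep(350, n), lp[["1-2"]],
                           lp[["1-3"]], lp[["2-3"]], c(0, 0, 0), 50,
                           numeric(0), 0.05)
  exited <- !is.na(r$cvd_age) | !is.na(r$death_age)
  expect_gt(mean(exited), 0.999)  # horizon long enough that all exit
  frac <- mean(!is.na(r$cvd_age))
  p_cvd <- 0.02 / 0.05
  mc_se <- sqrt(p_cvd * (1 - p_cvd) / n)
  expect_lt(abs(frac - p_cvd), 3 * mc_se)
})

test_that("empirical occupancy matches transition probabilities", {
  set.seed(608)
  n <- 30000
  configs <- list(
    list(p = toy_params(), prof = data.frame(sex = "male")),
    list(p = gompertz_truth(), prof = data.frame(sex = "male")),
    list(p = gompertz_truth(), prof = data.frame(sex = "female")))
  for (cf in configs) {
    lp <- cvdle:::.epoch_lp(cf$p, list(cf$prof[rep(1, n), , drop = FALSE]))
    ba <- sapply(c("1-2", "1-3", "2-3"), function(tr)
      cf$p$transitions[[tr]]$beta_age)
    r <- cvdle:::.sim_engine(rep(55, n), rep(85, n), lp[["1-2"]],
                             lp[["1-3"]], lp[["2-3"]], ba, 50,
                             numeric(0), 0.05)
    pr <- do.call(covariate_profile, as.list(cf$prof))
    for (h in c(5, 15)) {
      P <- transition_probability(cf$p, pr, 55, 55 + h, step = 0.05)
      at <- 55 + h
      emp <- c(
        mean((is.na(r$cvd_age) | r$cvd_age > at) &
               (is.na(r$death_age) | r$death_age > at)),
        mean(!is.na(r$cvd_age) & r$cvd_age <= at &
               (is.na(r$death_age) | r$death_age > at)),
        mean(!is.na(r$death_age) & r$death_age <= at))
      se <- pmax(sqrt(P[1, ] * (1 - P[1, ]) / n), 1e-4)
      expect_true(all(abs(emp - P[1, ]) < 3.5 * se))
    }
  }
})

test_that("observation scheme emits the records the design implies", {
  cfg_exact <- simulation_config()
  cfg_panel <- simulation_config(cvd_observation = "panel")
  # death after the last re-contact: panel records at all contacts plus one
  # exact death
  tr <- make_traj(death_age = 78)
  rec <- apply_observation_scheme(tr, cfg_exact)
  expect_equal(rec$age, c(60, 66, 72, 78))
  expect_equal(rec$state, c(1L, 1L, 1L, 3L))
  expect_equal(rec$obs_type,
               c("panel", "panel", "panel", "exact_death"))
  # onset between re-contacts, panel mode: state 2 first appears at the
  # following contact, no exactly dated onset record
  tr <- make_traj(cvd_age = 68, death_age = 80)
  rec <- apply_observation_scheme(tr, cfg_panel)
  expect_equal(rec$age, c(60, 66, 72, 80))
  expect_equal(rec$state, c(1L, 1L, 2L, 3L))
  expect_false(any(rec$obs_type == "exact_transition"))
  # same trajectory, registry-dated onsets
  rec <- apply_observation_scheme(tr, cfg_exact)
  expect_equal(rec$age, c(60, 66, 68, 72, 80))
  expect_equal(rec$state[rec$age == 68], 2L)
  expect_equal(rec$obs_type[rec$age == 68], "exact_transition")
  # death before the first re-contact
  tr <- make_traj(death_age = 63)
  rec <- apply_observation_scheme(tr, cfg_exact)
  expect_equal(rec$age, c(60, 63))
  expect_equal(rec$obs_type, c("panel", "exact_death"))
  # survivor: known state at censoring under registry-dated onsets,
  # state-unknown alive record under panel observation
  tr <- make_traj(cvd_age = 74)
  rec <- apply_observation_scheme(tr, cfg_exact)
  expect_equal(rec$age[nrow(rec)], 85)
  expect_equal(rec$state[nrow(rec)], 2L)
  rec <- apply_observation_scheme(tr, cfg_panel)
  expect_equal(rec$obs_type[nrow(rec)], "alive")
  expect_true(is.na(rec$state[nrow(rec)]))
})

test_that("cohorts are reproducible and structurally valid", {
  cfg <- simulation_config(n_subjects = 300, seed = 9)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$data, c2$data)
  expect_silent(validate_histories(c1$data))
  # byte-identical CSV bundles
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(c1, d1); write_cohort(c2, d2)
  expect_identical(readLines(file.path(d1, "cohort.csv")),
                   readLines(file.path(d2, "cohort.csv")))
  # no record after death, ages strictly increasing (validated above),
  # and every record age within follow-up
  tr <- c1$trajectories
  last_age <- tapply(c1$data$age, c1$data$subject_id, max)
  dead <- !is.na(tr$death_age) & tr$death_age <= tr$censor_age
  expect_true(all(last_age[tr$subject_id[dead]] <=
                    tr$death_age[dead] + 1e-12))
  expect_true(all(c1$data$age <= cfg$admin_censoring_age + 1e-12))
})

test_that("certain cessation removes current smokers after re-contact", {
  cfg <- simulation_config(
    n_subjects = 400, seed = 10,
    covariate_update_rules = list(smoking_cessation_prob = 1))
  coh <- simulate_cohort(cfg)
  d <- coh$data
  base <- d[!duplicated(d$subject_id), c("subject_id", "age")]
  first_recontact <- stats::setNames(base$age + cfg$recontact_offsets[1],
                                     base$subject_id)
  after <- d[d$age >= first_recontact[d$subject_id], ]
  expect_false(any(after$smoking == "current", na.rm = TRUE))
})

test_that("fit on a simulated cohort recovers truth and its CI covers the
           true life expectancy", {
  truth <- homogeneous_truth()
  coh <- simulate_cohort(simulation_config(
    n_subjects = 2000, true_params = truth), seed = 2024)
  spec <- model_spec(covariates = c("sex", "vigorous_pa"),
                     age_model = "none")
  fit <- fit_model(coh$data, spec)
  tr <- cvdle:::.flatten_params(truth, spec)
  se <- sqrt(diag(fit$covariance))
  expect_true(all(abs(fit$par - tr) < 3 * se))
  prof <- covariate_profile(sex = "male", vigorous_pa = "no")
  grid <- le_grid(50, 300, 0.5)
  u <- le_uncertainty(fit, prof, grid, n_draws = 500, seed = 31)
  le_true <- life_expectancy(truth, prof, grid)
  expect_gt(le_true$le_total, u$intervals["le_total", "lower"])
  expect_lt(le_true$le_total, u$intervals["le_total", "upper"])
})
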