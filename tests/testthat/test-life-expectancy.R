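# State occupancy and the life-expectancy decomposition.

test_that("occupancy starts at (1, 0, 0) and stays there without risk", {
  p <- toy_params()
  oc <- suppressWarnings(
    state_occupancy_curve(p, toy_profile(), le_grid(50, 60, 0.25)))
  expect_equal(unlist(oc[1, c("p_free", "p_cvd", "p_dead")]),
               c(p_free = 1, p_cvd = 0, p_dead = 0))
  expect_equal(oc$p_free[oc$age == 60], exp(-0.5), tolerance = 1e-10)
  expect_equal(rowSums(oc[, c("p_free", "p_cvd", "p_dead")]),
               rep(1, nrow(oc)), tolerance = 1e-10)
  # no intensities at all: the subject never leaves state 1 (the residual
  # occupancy warning is expected here)
  p0 <- param_set(list())
  oc0 <- suppressWarnings(
    state_occupancy_curve(p0, toy_profile(), le_grid(50, 70, 1)))
  expect_true(all(oc0$p_free == 1))
})

test_that("constant-intensity life expectancy matches the sojourn formulas", {
  # e_free = 1/(q12+q13), e_with = q12 / ((q12+q13) q23)
  p <- toy_params()
  le <- life_expectancy(p, toy_profile(), le_grid(50, 400, 0.25))
  expect_equal(le$le_free, 20, tolerance = 0.005 * 20)
  expect_equal(le$le_with, 4, tolerance = 0.005 * 4)
  expect_equal(le$le_total, 24, tolerance = 0.005 * 24)
  expect_identical(le$le_total, le$le_free + le$le_with)
})

test_that("state 2 unreachable means no years lived with disease", {
  p <- param_set(list("1-3" = list(log_baseline = log(0.05))))
  le <- life_expectancy(p, toy_profile(), le_grid(50, 400, 0.25))
  expect_identical(le$le_with, 0)
  # doubling the death intensities halves total LE
  p2 <- param_set(list("1-3" = list(log_baseline = log(0.10))))
  le2 <- life_expectancy(p2, toy_profile(), le_grid(50, 400, 0.25))
  expect_equal(le2$le_total / le$le_total, 0.5, tolerance = 1e-4)
})

test_that("halving the grid step moves each component by less than 0.2%", {
  p <- gompertz_truth()
  prof <- covariate_profile(sex = "male")
  a <- life_expectancy(p, prof, le_grid(50, 115, 0.25))
  b <- life_expectancy(p, prof, le_grid(50, 115, 0.125))
  for (comp in c("le_total", "le_free", "le_with"))
    expect_lt(abs(a[[comp]] / b[[comp]] - 1), 0.002)
})

test_that("life expectancy agrees with mean sojourn times of simulated
           trajectories", {
  truth <- homogeneous_truth()
  prof <- covariate_profile(sex = "male", vigorous_pa = "no")
  grid <- le_grid(50, 110, 0.25)
  le <- suppressWarnings(life_expectancy(truth, prof, grid))
  set.seed(515)
  n <- 30000
  lp <- cvdle:::.epoch_lp(truth, list(
    data.frame(sex = rep("male", n), vigorous_pa = "no")))
  r <- cvdle:::.sim_engine(rep(50, n), rep(110, n), lp[["1-2"]],
                           lp[["1-3"]], lp[["2-3"]], c(0, 0, 0), 50,
                           numeric(0), 0.05)
  end <- pmin(ifelse(is.na(r$death_age), 110, r$death_age), 110)
  t_free <- pmin(ifelse(is.na(r$cvd_age), end, r$cvd_age), end) - 50
  t_with <- end - 50 - t_free
  for (pair in list(c("le_free", "t_free"), c("le_with", "t_with"))) {
    emp <- get(pair[2])
    mc_se <- stats::sd(emp) / sqrt(n)
    expect_lt(abs(mean(emp) - le[[pair[1]]]), 3 * mc_se)
  }
})

test_that("raising a death intensity strictly lowers total and free LE", {
  base <- gompertz_truth()
  prof <- covariate_profile(sex = "female")
  up <- base
  up$transitions[["1-3"]]$log_baseline <-
    up$transitions[["1-3"]]$log_baseline + 0.4
  le0 <- life_expectancy(base, prof)
  le1 <- life_expectancy(up, prof)
  expect_lt(le1$le_total, le0$le_total)
  expect_lt(le1$le_free, le0$le_free)
})

test_that("percentile intervals are reproducible and collapse with zero
           covariance", {
  truth <- homogeneous_truth()
  coh <- simulate_cohort(simulation_config(
    n_subjects = 600, true_params = truth), seed = 99)
  spec <- model_spec(covariates = c("sex", "vigorous_pa"),
                     age_model = "none")
  fit <- fit_model(coh$data, spec)
  prof <- covariate_profile(sex = "male", vigorous_pa = "no")
  grid <- le_grid(50, 300, 0.5)
  u1 <- le_uncertainty(fit, prof, grid, n_draws = 300, seed = 4)
  u2 <- le_uncertainty(fit, prof, grid, n_draws = 300, seed = 4)
  expect_identical(u1$intervals, u2$intervals)
  expect_lt(u1$intervals["le_total", "lower"], u1$le_total)
  expect_gt(u1$intervals["le_total", "upper"], u1$le_total)
  # per-draw decomposition holds exactly
  expect_equal(u1$draws[, "le_total"],
               u1$draws[, "le_free"] + u1$draws[, "le_with"])
  fit0 <- fit
  fit0$covariance[] <- 0
  u0 <- le_uncertainty(fit0, prof, grid, n_draws = 200, seed = 4)
  expect_equal(unname(u0$intervals["le_total", ]),
               rep(u0$le_total, 2), tolerance = 1e-10)
  expect_warning(le_uncertainty(fit, prof, grid, n_draws = 50, seed = 1),
                 "n_draws")
})

test_that("interval widths shrink with the cohort size", {
  truth <- homogeneous_truth()
  width <- sapply(c(400, 1600), function(n) {
    coh <- simulate_cohort(simulation_config(
      n_subjects = n, true_params = truth), seed = 123)
    fit <- fit_model(coh$data, model_spec(
      covariates = c("sex", "vigorous_pa"), age_model = "none"))
    u <- le_uncertainty(fit, covariate_profile(sex = "male",
                                               vigorous_pa = "no"),
                        le_grid(50, 300, 0.5), n_draws = 400, seed = 7)
    diff(u$intervals["le_total", ])
  })
  expect_lt(width[2], width[1])
})

test_that("paired profile differences decompose and vanish at the
           reference", {
  truth <- harmful_smoking_truth()
  coh <- simulate_cohort(simulation_config(
    n_subjects = 800, true_params = truth), seed = 42)
  spec <- model_spec(covariates = c("sex", "smoking"))
  fit <- fit_model(coh$data, spec, options = list(step = 1))
  never <- covariate_profile(sex = "male", smoking = "never")
  current <- covariate_profile(sex = "male", smoking = "current")
  d0 <- le_difference(fit, current, current, n_draws = 200, seed = 6)
  expect_identical(d0$dif_total, 0)
  expect_true(all(abs(d0$draws) < 1e-12))
  d <- le_difference(fit, never, current, n_draws = 200, seed = 6)
  expect_identical(d$dif_total, d$dif_free + d$dif_with)
  expect_equal(d$draws[, "dif_total"],
               d$draws[, "dif_free"] + d$draws[, "dif_with"])
  # protective never-smoking: longer total and disease-free life
  expect_gt(d$dif_total, 0)
  expect_gt(d$dif_free, 0)
})

test_that("truncation at max_age warns when occupancy remains", {
  p <- toy_params()
  expect_warning(life_expectancy(p, toy_profile(), le_grid(50, 80, 0.25)),
                 "max_age")
})
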