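# Shared fixtures: small parameter sets and cohorts built in code.

# Constant-intensity toy model: q12 = 0.02, q13 = 0.03, q23 = 0.10 per year.
toy_params <- function() {
  param_set(list(
    "1-2" = list(log_baseline = log(0.02)),
    "1-3" = list(log_baseline = log(0.03)),
    "2-3" = list(log_baseline = log(0.10))))
}

toy_profile <- function() covariate_profile(sex = "male")

# Gompertz truth with a sex effect on every transition; baseline rates per
# year at age 50 for a male current-ref profile.
gompertz_truth <- function() {
  param_set(list(
    "1-2" = list(log_baseline = log(0.007), beta_age = 0.07,
                 betas = c(sex_female = -0.45)),
    "1-3" = list(log_baseline = log(0.006), beta_age = 0.09,
                 betas = c(sex_female = -0.40)),
    "2-3" = list(log_baseline = log(0.035), beta_age = 0.07,
                 betas = c(sex_female = -0.30))))
}

# Time-homogeneous truth (sex + vigorous PA on all transitions) used for
# the replicated coverage study.
homogeneous_truth <- function() {
  param_set(list(
    "1-2" = list(log_baseline = log(0.012),
                 betas = c(sex_female = -0.45, vigorous_pa_yes = -0.25)),
    "1-3" = list(log_baseline = log(0.025),
                 betas = c(sex_female = -0.40, vigorous_pa_yes = -0.30)),
    "2-3" = list(log_baseline = log(0.070),
                 betas = c(sex_female = -0.30, vigorous_pa_yes = -0.20))))
}

# A cohort with a deliberately strong harmful-smoking / inactive effect,
# for sign oracles in the pipeline tables.
harmful_smoking_truth <- function() {
  param_set(list(
    "1-2" = list(log_baseline = log(0.008), beta_age = 0.07,
                 betas = c(sex_female = -0.35, smoking_never = -0.9,
                           smoking_former = -0.7, vigorous_pa_yes = -0.5)),
    "1-3" = list(log_baseline = log(0.007), beta_age = 0.09,
                 betas = c(sex_female = -0.35, smoking_never = -0.9,
                           smoking_former = -0.7, vigorous_pa_yes = -0.5)),
    "2-3" = list(log_baseline = log(0.035), beta_age = 0.07,
                 betas = c(sex_female = -0.30, smoking_never = -0.3,
                           smoking_former = -0.2, vigorous_pa_yes = -0.3))))
}

# Two-subject toy dataset with one panel pair, one exact death and one
# exact transition, on the constant-intensity model.
toy_histories <- function() {
  data.frame(
    subject_id = c("A", "A", "B", "B", "B"),
    age = c(50, 60, 50, 60, 65),
    state = c(1L, 1L, 1L, 2L, 3L),
    obs_type = c("panel", "panel", "panel", "exact_transition",
                 "exact_death"),
    sex = "male",
    stringsAsFactors = FALSE)
}
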