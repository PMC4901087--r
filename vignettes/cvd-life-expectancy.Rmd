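---
title: "Modelling life expectancy with and without cardiovascular disease"
author: "cvdle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling life expectancy with and without cardiovascular disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdle)
```

## The model

`cvdle` implements a continuous-time, three-state, non-recoverable
illness-death Markov model for ageing cohorts.  A subject is in one of

* state 1 — alive and free of cardiovascular disease (CVD),
* state 2 — alive after a first nonfatal CVD event,
* state 3 — dead (any cause; absorbing),

with allowed moves 1→2 (first nonfatal event), 1→3 (death without a prior
event) and 2→3 (death after an event).  There is no recovery: 2→1 is
structurally impossible, and structural zeros are encoded by *omitting* a
transition from the model, never by degenerate parameters.

Age is the time scale.  Each transition intensity follows a
proportional-hazards form with log-linear (Gompertz-type) age dependence,

$$ q_{ij}(a, z) \;=\; \exp\!\big(\beta^{(ij)}_0 + \beta^{(ij)}_a (a - 50)
   + {\beta^{(ij)}}^{\!\top} z \big), $$

where $a$ is age in years, $z$ the covariate dummy vector, and the
baseline $\exp(\beta_0)$ is the intensity per year at age 50 for the
reference covariate pattern.  Reference levels follow the tabulation
convention of the output tables: current smoker, no vigorous physical
activity, normal BMI, light/moderate alcohol, male, no diabetes, no
hypertension, and a total/HDL cholesterol ratio of 4.5 (numeric covariates
enter centred).  The exact age form used in comparable published analyses
is not always reported; the log-linear choice is the standard one for this
model class, and `model_spec(age_model = "none")` swaps in a
time-homogeneous model when age effects are not wanted.

Transition probability matrices over an age interval come from
product-integration: the interval is cut into grid cells of width $h$
(default 0.25 years) and $Q$ is taken constant within each cell, evaluated
at the **cell midpoint**.  The midpoint choice makes the discretisation
error $O(h^2)$ rather than $O(h)$, which is why the coarser default
fitting step of 0.5 years is still bias-free at human hazard scales (the
relative cell error is about $(\beta_a h)^2/24 \approx 10^{-4}$ at
$\beta_a = 0.1$/yr).  For a constant generator the 3×3 exponential has an
analytic triangular solution — $P_{11} = e^{-(q_{12}+q_{13})t}$,
$P_{22} = e^{-q_{23}t}$, $P_{12} = q_{12}t\,e^{-(q_{12}+q_{13})t}\,
g\!\big((q_{23}-q_{12}-q_{13})t\big)$ with $g(u) = (1-e^{-u})/u$ — which
the package uses per cell instead of a generic matrix exponential; the
same formula evaluated in one shot (`closed_form_tpm()`) serves as an
independent oracle for the multi-cell product in the tests, together with
Chapman–Kolmogorov checks.

## The panel likelihood

Cohort data are *panel observed*: the state is known only at a baseline
contact and one or two re-contacts roughly 5–7 years apart, deaths are
exactly dated by a register, and nonfatal events are either registry dated
or only noticed at the next contact.  Covariates are piecewise constant
and carried forward from the most recent contact (the interval's left
endpoint), including over the interval that ends in an event.

Writing $P = P(a_0, a_1)$ for the interval matrix under the left-endpoint
covariates, the likelihood contribution of one interval is

| observation at $a_1$            | contribution |
|---------------------------------|--------------|
| panel, state $s$                | $P_{rs}$ |
| exactly dated onset (1→2)       | $P_{11}\, q_{12}(a_1)$ |
| exactly dated death, onsets panel-observed | $\sum_{k\in\{1,2\}} P_{rk}\, q_{k3}(a_1)$ |
| exactly dated death, onsets registry dated | $P_{11}\,q_{13}(a_1)$ from state 1 ($P_{22}\,q_{23}(a_1)$ from state 2) |
| known alive, state unobserved   | $P_{r1} + P_{r2}$ |

Two of these rows deserve comment, because both encode register
information that is easy to drop by accident:

* **End of follow-up.**  The death register observes vital status through
  the administrative censoring age, so a subject with no death record is
  *known alive* there — ignoring this truncates survivors' exposure at
  their last contact while still counting late deaths, and biases the age
  slopes upward severely.  The observation scheme therefore emits an
  end-of-follow-up record for every survivor: with registry-dated onsets
  the disease state at that age is known too (an ordinary panel record);
  with panel-observed onsets it is not, and the record type `"alive"`
  (state `NA`) contributes $P_{r1}+P_{r2}$.
* **Deaths without a prior onset record.**  When onsets are registry
  dated, the registry's *silence* before a death identifies the pre-death
  state as 1, and the unknown-state mixture must not be used — the mixture
  credits disease paths that would have produced an onset record, is not a
  proper likelihood for that design, and demonstrably flattens the age
  slope of the 1→3 intensity.  `fit_model()` infers the design from the
  data (`exact_onsets = TRUE` whenever `exact_transition` records are
  present) and the switch can be set explicitly.  The unknown-pre-death
  mixture remains the default of the low-level likelihood functions, which
  is the correct form for purely panel-observed onsets.

Estimation is quasi-Newton (BFGS) maximisation of the summed interval
contributions, initialised at crude event/person-time rates with all
coefficients at zero (deterministic and robust).  The covariance is the
inverse of the observed information, computed by `stats::optimHess`
central differences at the optimum; its default step (about
$10^{-4}|\theta|$) is used rather than something smaller because at
log-likelihood magnitudes of $10^3$–$10^4$ a much finer second-difference
step amplifies floating-point rounding into the information matrix.
Non-convergence is flagged on the returned object, never raised.
Transitions with zero observed events trigger a boundary-diagnostic
warning.

## Life expectancy

Starting disease free at age $a_0$ (default 50), the occupancy
probabilities at age $a$ are the first row of $P(a_0, a)$.  The expected
remaining years free of disease and with disease are

$$ e_{\text{free}} = \int_{a_0}^{a_{\max}} P_{11}(a_0, a)\,da,
   \qquad
   e_{\text{with}} = \int_{a_0}^{a_{\max}} P_{12}(a_0, a)\,da, $$

and total life expectancy is their sum — an exact decomposition that holds
for the point estimate and for every parameter draw, and is asserted for
every row the pipeline renders.  Integration uses the trapezoid rule on
the grid nodes.  A left-endpoint rectangle rule was considered (it matches
the product-integration nodes) but rejected: at $h = 0.25$ it
overestimates a constant-hazard sojourn time by about $h \cdot q/2 \approx
0.6\%$, while the trapezoid error is $O(h^2)$ and at the same step
reproduces the analytic sojourn times $1/(q_{12}+q_{13})$ and
$q_{12}/((q_{12}+q_{13})q_{23})$ to five digits.  The grid is truncated at
`max_age` (default 115); if more than $10^{-3}$ occupancy remains in the
transient states there the package warns rather than extrapolating.

Uncertainty is parametric bootstrap: parameter vectors are drawn from the
multivariate normal at the MLE and its covariance, life expectancy is
recomputed per draw (the occupancy recursion is vectorised across draws),
and percentile intervals are reported.  Percentile rather than Wald
intervals because life expectancy is a markedly nonlinear functional of
the parameters; 1000 draws by default.  Between-profile differences are
evaluated on the *same* draws and summarised per draw (paired), not by
interval subtraction; the point difference is the difference of point
estimates before any rounding.

Profiles at which life expectancy is evaluated may hold fractional dummy
values — the population-mean profile of a cohort ("other covariates at
cohort means") is the observed level frequencies of the baseline sample.
Whether such means should be taken over the baseline sample or over all
person-time is a genuinely open choice; the package uses the baseline
sample, which matches how baseline characteristics tables are built.

## The synthetic cohort generator

`simulate_cohort()` generates the study conditions the analysis assumes:

* baseline ages truncated normal (mean 62, sd 7, range 50–80), subjects
  disease free at entry;
* baseline lifestyle and clinical covariates drawn from a mix loosely
  matching ageing European cohorts (about a third current smokers, a third
  vigorously active, BMI mass in normal/overweight, light/moderate
  drinking dominant, hypertension common, total/HDL ratio ~4.5 ± 1.5);
* re-contacts at +6 and +12 years (bracketing the 5–7-year spacing of
  real designs), administrative censoring at age 85;
* smoking re-measured at re-contacts with a 10% per-contact cessation
  probability (current → former), other covariates constant;
* exactly dated deaths; onsets registry dated by default, panel observed
  on request.

True event times are sampled exactly by competing-risk inversion on a
piecewise-constant hazard grid of 0.05 years (hazard variation within a
cell is negligible at age slopes ≤ 0.15/yr): within a cell the exit
probability is $1-e^{-a w}$, the exit time is a truncated exponential, and
the cause is chosen with probability $q_{12}/(q_{12}+q_{13})$.  The
default generating parameters give total life expectancies at age 50 in
the 20–40-year range typical of published cohort tables, so scale errors
are immediately visible; they are documented defaults, not estimates from
any cohort.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: attrition and nonresponse correlated with
health, covariate measurement error and imputation, cohort-specific
harmonisation differences, competing non-CVD morbidity beyond the
all-cause death state, and calendar-period effects.

## Verification and numerical choices

* Constant-intensity transition probabilities agree with the analytic
  triangular solution to 1e-8, and the grid product satisfies
  Chapman–Kolmogorov; time-homogeneous results are step-independent.
* Panel, exact-onset and exact-death likelihood contributions match
  hand-derived closed forms to 1e-10, and the full cohort likelihood
  matches an independent closed-form Gompertz survival likelihood to
  1e-6 on a death-only design.
* The exact-death contribution equals the numerically differentiated
  death density to 1e-4 relative.
* A 200-replication study (n = 2000 per replication, the default
  observation design, a time-homogeneous truth with sex and activity
  effects) checks that 95% Wald intervals cover every log-intensity and
  log hazard ratio with frequency in [0.90, 0.99] and that the mean of
  each fitted life-expectancy component is within 2% of the truth.  The
  time-homogeneous truth keeps 200 maximum-likelihood fits tractable: its
  likelihood is evaluated by the exact single-cell formula, roughly ten
  times cheaper than the age-varying grid.  The Gompertz age model is
  validated separately by the closed-form likelihood oracle and a single
  n = 2000 recovery fit whose z-scores are all within noise.
* Empirical occupancy from simulated trajectories matches the computed
  transition probabilities within three Monte-Carlo standard errors at
  several horizons and configurations (100,000 trajectories in the
  acceptance suite).
* Problem sizes in the test suite (cohorts of 150–2000 subjects, 20,000 to
  100,000 oracle trajectories, 200 replications) were chosen as the
  smallest that leave the stochastic checks well inside their Monte-Carlo
  tolerances.

Degenerate inputs are handled explicitly: zero-length intervals give the
identity matrix; the $q_{23} \to q_{12}+q_{13}$ limit of $P_{12}$ uses the
stable $g(u)$ form with a series fallback at $u = 0$; runaway intensities
during optimisation excursions are capped at $10^8$/yr (which already
saturates every probability) only when the parameters could overflow;
and an all-zero generator (no transitions declared) is legal and yields
eternal disease-free occupancy.

## The reporting pipeline

`run_risk_factor_analysis()` mirrors the published table layout: one
fitted model per tabulated lifestyle factor — the exposure plus the other
three lifestyle factors, sex, age, diabetes, hypertension and the
cholesterol ratio as adjusters — with life expectancy per category level
at age 50, other covariates at the baseline cohort means, and paired
differences against the factor's reference level.  (A single-model mode
tabulating all factors from one fit is available but off by default.)
Category levels with no baseline subjects are omitted with a warning.
`run_joint_analysis()` contrasts the joint "favourable" profile
(overweight not obese, light/moderate drinker, non-smoker, vigorously
active) with the "unfavourable" profile (same, but a smoker and inactive)
— the two differ in exactly those two fields — and reports the count of
baseline subjects matching each profile.  Whether "non-smoker" pools never
and former smokers is not a settled convention; the default codes it as
never smoker, with `nonsmoker = "never_former"` pooling the two at equal
weight.  Rounding to one decimal happens only at render time; differences
are computed before rounding, which is why rendered components can
occasionally disagree with the rendered total in the last digit, exactly
as in published tables.

Everything is deterministic given the configuration seed: per-factor and
per-sex draw seeds are derived from it, and a run manifest (seed,
settings, subject counts at each exclusion step) is written next to the
tables.
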