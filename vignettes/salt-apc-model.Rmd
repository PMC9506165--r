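---
title: "Methods: the salt-APC cardiovascular mortality model"
author: "saltapc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the salt-APC cardiovascular mortality model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltapc)
```

## Scope and model structure

`saltapc` simulates cardiovascular (CVD) mortality in adults aged 20–69
over calendar years 1950–2017, one stock-flow model per sex replicated
across the 118 single-year birth cohorts 1880–1997. A row labelled year
*t* describes the state at the start of *t* and the flows during
[*t*, *t* + 1); age in year *t* is *t* − birth year (completed years).
Under this convention the 1880 cohort is already at the exit boundary in
1950: it is instantiated, keeping the 118-cohort count, but contributes no
person-time.

Total mortality is a deliberately strict multiplicative
age–period–cohort (APC) product,

$$\mu(a,t,s) = m_{1950}(a,s)\; p_s^{\,t-1950}\; c_s^{\,b-1880},
  \qquad b = t-a,$$

so the entire age profile is carried by the 1950 rate table, secular
change by a single geometric period factor, and between-cohort change by
a single geometric cohort factor. The classic APC identifiability problem
(only two of the three trends are free once the age table is fixed) is
resolved here by construction: the age table is data, the cohort reference
is pinned at 1880, and whatever scaling ambiguity remains between
$m_{1950}$ and $c$ is absorbed by calibration, which uses the same
convention as the synthetic generator.

The hazard is split by the year's CVD share $\pi(t)$ — taken as
age-universal within each year, because cause-of-death proportions are
typically published for all ages combined — and only the CVD component
responds to salt. Other-cause hazards are therefore identical across
scenarios (a property the test suite asserts), though other-cause *death
counts* differ slightly because scenario populations differ.

## The salt-effect multiplier

The exposure contrast is the difference between an assumed and the actual
salt intake, split 1:1 between two channels: the *period* channel (the
difference at the current year and age, capturing the blood-pressure
pathway) and the *cohort* channel (the difference at age 20 for the
cohort, capturing long-run vascular damage accrued by early adulthood).
With $\Delta_p$ and $\Delta_c$ in g/day, the CVD hazard is multiplied by

$$M = 1.01^{\,(\tfrac12\Delta_p + \tfrac12\Delta_c)/0.584}
  \quad (a \ge 20), \qquad M = 1 \; (a < 20),$$

anchored to the epidemiological finding that 10 mmol/day of sodium
(0.584 g salt) is associated with a 1% change in CVD mortality. Two
functional forms could implement that statement; we default to the power
law rather than the linear form $1 + 0.01\,\Delta/0.584$ because it
composes exactly across the two channels
($M(\Delta_p,\Delta_c) = M(\Delta_p,0)\,M(0,\Delta_c)$), remains positive
for arbitrarily large negative differences, and agrees with the linear
form to first order (and exactly at one unit). The linear form is kept as
`salt_effect_params(form = "linear")` for sensitivity analysis. Ages
below 20 are entirely unaffected, so how the salt surface is filled below
the youngest surveyed age group is inert for results.

## Reconstructing the salt-exposure surface

Survey data come in two regimes: overall annual means only (1973–1994,
household-level collection) and means by sex × 10-year age group
(1995–2017). The reconstruction is:

1. **Back-extrapolation.** An OLS line through the overall means of
   1973–1986 (the window over which the published series is close to
   linear) supplies overall values for earlier years. The line is
   extended to 1900 — not merely to 1950 — because each cohort needs an
   intake at age 20 and the 1880 cohort turns 20 in 1900. Extrapolated
   male values in 1942 and earlier are capped at 20 g/day, a plausibility
   bound from prewar intake studies; females are used as fitted (no
   published bound names them).
2. **Age-group ratios.** For each sex × 10-year group, the ratio of the
   group's mean over 1995–2017 to the overall mean over the same window.
   When the supplied overall series stops in 1994 (the historical
   design), per-year overall values inside the window are derived as the
   unweighted mean of that sex's adult group means; with the synthetic
   generator, whose group means are exactly consistent with its overall
   path, both routes give identical ratios.
3. **Surface assembly.** Years ≤ 1994: overall × ratio, constant across
   single ages within a group; years ≥ 1995: reported group means passed
   through unchanged. The male cap is re-applied to the assembled cells
   in 1942 and earlier, so age-specific male values also respect the
   20 g bound even where a group ratio exceeds 1. Per-cohort intake at
   age 20 is then read off the surface at (birth year + 20, age 20).

Counterfactual surfaces retain a fraction $f$ of the actual change after
the 1950 anchor, `assumed = actual + (1 − f)(actual(1950) − actual)`,
leaving pre-anchor years untouched; consequently cohorts who reached age
20 before 1950 keep their actual cohort-channel exposure in every
scenario.

## The stock-flow engine

The annual update uses the exact constant-hazard competing-risks solution
rather than a small-step Euler scheme: survivors are
$N e^{-(h_{cvd}+h_{oth})}$ and the year's deaths are allocated in
proportion $h_{cvd} : h_{oth}$. This removes the integration step size as
a tuning parameter, is unconditionally stable for the large
early-century hazards, and agrees with Euler to first order in the
hazards. Flows are computed from start-of-year stocks; a cohort's final
active year is the year it is aged 69, at the end of which survivors
leave through the aged-out flow. Per-cohort person conservation
(entry stock = deaths + aged-out + final stock) holds to 1e-9 relative
in the tests. Births enter at the start of their birth year and are
exposed to the age-0 hazard in that year.

## Calibration

The period and cohort coefficients are fitted per sex, independently, by
minimising the sum of squared differences of **log** rates over the full
70 × 68 age × year grid. The log scale is a deliberate choice: mortality
spans two to three orders of magnitude across age, and a linear-scale
objective would be dominated by old-age cells; a linear option is kept
(`calibration_spec(scale = "linear")`). On the log scale the objective is
exactly quadratic in $(\log p, \log c)$, so it has a unique minimum.

The optimiser is a Nelder–Mead simplex started at the neutral point
$(1, 1)$ with box bounds $[0.8, 1.2]$ enforced by a quadratic penalty,
relative tolerance 1e-14, an iteration cap of 2000, and one restart from
the best point (a fresh simplex polishes an optimum near which the first
simplex may have collapsed; a collapsed restart at the optimum is
reported as converged). On noiseless self-generated surfaces the
generating pair is recovered to machine precision — far inside the 1e-4
recovery tolerance the tests assert across a 3 × 3 grid of truths — and
with 1% lognormal cell noise recovery is still within 1e-3. Observed
rates must be strictly positive for the log loss; a zero observed cell is
an error, not silently dropped.

## Scenario analytics

Excess mortality is computed on death *counts* (persons), not rates,
matching the reporting units of the underlying study design; population
feedback is therefore included — a scenario with higher CVD mortality
carries a smaller surviving population forward. Counts are summed over
ages 20–69 (the study scope) even though the engine simulates ages 0–69;
the exit-year aged-70 flow is excluded. Relative excess uses the base
run's CVD deaths as denominator. Accumulated excess over 1950–2017 is
nearly linear in $1-f$ (within 10% on the synthetic bundle; mildly
sub-linear because the population-depletion feedback grows with the
effect), and annual CVD deaths are monotone in $f$ every year.

## The synthetic-data generator

`generate_bundle()` emulates the *statistical structure* the pipeline
assumes, not postwar Japan itself:

* a 1950 pyramid tapering exponentially with age (1.8 M at age 0, 3% per
  year of age) and total births of 1.5 M/year declining 1% per year with
  a 0.512 male fraction — round, demographically plausible magnitudes;
* a Gompertz 1950 mortality schedule $5\times10^{-5} e^{0.085a}$ with a
  0.02 infant offset decaying as $e^{-a}$, scaled ×1.1 (male) / ×0.9
  (female);
* a CVD proportion rising 0.20 → 0.40 by 1970 then easing to 0.30 by
  2017;
* overall salt paths flat before 1940 (20 g male, 14 g female) then
  declining linearly to 11 g and 9 g in 2017, with a normalised age
  gradient (trough ≈ 0.9 in the 20s, peak ≈ 1.1 in the 50s). The
  pre-1973 linearity means the back-extrapolation is exact over
  1940–1972, and the male 20 g cap binds exactly where the true path
  plateaus, so the imputed surface reproduces the true one to rounding
  over 1950–1994 (the tests require mean absolute error < 0.5 g/day);
* an observed mortality surface generated from the APC model itself at
  configurable true coefficients (defaulting to the published calibrated
  pairs, so recovery tests are meaningful), with optional lognormal cell
  noise; the default σ = 0 keeps the bundle fully deterministic, and all
  randomness flows from the single configured seed.

What the generator does **not** emulate: migration, sex-ratio drift, war
shocks to the 1950 pyramid, age-by-period interactions in the CVD share,
survey sampling error in the salt means, and any deviation of real
mortality from the strict multiplicative APC form. Passing tests
therefore validate the machinery — imputation, calibration, simulation,
accounting — not the historical accuracy of any particular application;
with real inputs the APC form itself is an approximation whose residuals
`residuals(fit)` should be inspected.

## Degenerate inputs, tie-breaks and problem sizes

Zero total hazard yields zero deaths (no 0/0 in cause allocation); a
zero-population cohort yields an empty mortality curve; `f = 1` returns
the identical salt-surface object, making the base-run comparison
bit-exact. Validation refuses gaps in any age/year axis, negative stocks
or rates, rates ≥ 1, and proportions outside [0, 1] rather than imputing.
All shipped analyses run at the full study frame — 118 cohorts × 2
sexes × 68 years, five scenarios, and a 70 × 68 calibration grid per
sex — which completes in a few seconds; the test suite, including the
3 × 3 calibration recovery grid and a noisy-recovery case, runs in well
under a minute.

## Known limitations

* The 1% per 10 mmol effect and the 1:1 period/cohort split are imported
  assumptions; results are proportionally sensitive to both, and no
  uncertainty is propagated from them.
* The CVD share of mortality is age-universal within each year.
* Salt affects only CVD mortality; effects on other causes (e.g. gastric
  cancer) are out of scope, as are ages 70+ and effect modification by
  age or blood pressure.
* Calibration minimises an unweighted log-rate loss; it is not a
  population-weighted fit, and no confidence intervals are produced for
  $(p, c)$.
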