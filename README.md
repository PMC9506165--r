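# saltapc

Stock-flow age–period–cohort (APC) simulation of the effect of long-run
population salt-intake change on cardiovascular (CVD) mortality.

## The problem

In Japan, mean dietary salt intake fell substantially after the 1950s while
CVD mortality declined dramatically. How much of that mortality decline is
attributable to the salt reduction? `saltapc` answers this with a
retrospective system-dynamics simulation of adults aged 20–69 over
1950–2017: it reconstructs a salt-exposure surface from survey tables,
calibrates an APC mortality model to an observed mortality surface
(the *base run*), then replays history under counterfactual salt
trajectories and counts the excess CVD deaths.

It is written for epidemiologists and health-policy modellers who want a
scriptable, fully tested replacement for a visual system-dynamics tool, and
it ships a synthetic-data generator so the whole pipeline can be exercised
and validated without access to the original government statistics.

## The model

Total mortality for sex *s* at age *a* in year *t* (birth year *b = t − a*)
is a multiplicative APC product

```
μ(a, t, s) = m1950(a, s) · p_s^(t − 1950) · c_s^(b − 1880)
```

where `m1950` is the observed 1950 single-age rate table (the age effect),
`p_s` the period coefficient and `c_s` the cohort coefficient, fitted per
sex by Nelder–Mead least squares on log rates against the observed
mortality surface. The hazard is split into causes by the year's CVD share
`π(t)`; only the CVD part responds to salt:

```
μ_cvd = μ · π(t) · M,          μ_other = μ · (1 − π(t))
M     = 1.01^[ (½·Δ_period + ½·Δ_cohort) / 0.584 ]   for a ≥ 20, else 1
```

`Δ_period` is the assumed-minus-actual salt difference (g/day) at the
current year and age, `Δ_cohort` the same difference at age 20 for the
cohort, so a sustained 10 mmol (0.584 g/day) difference through both
channels raises CVD mortality by exactly 1%. A stock-flow engine advances
118 single-year birth cohorts (1880–1997) per sex annually under the
competing hazards (`exp` survival, proportional cause allocation), with
entry at birth or at the 1950 initial stock and exit at the 70th birthday.

Counterfactual scenarios retain a fraction *f* of the actual post-1950
salt change: `assumed(t) = actual(t) + (1 − f)(actual(1950) − actual(t))`;
`f = 1` is the base run and `f = 0` freezes intake at its 1950 level.
Excess CVD mortality is the scenario-minus-base death count at ages 20–69,
reported annually (absolute and relative) and accumulated.

## Worked example

```r
library(saltapc)

bundle <- generate_bundle(synth_config(seed = 1))  # synthetic inputs
fit <- salt_apc(bundle)                            # impute salt + calibrate
fit
#> Salt-APC cardiovascular mortality model
#>   years: 1950 - 2017 | cohorts: 1880 - 1997
#>   salt effect: 1 % per 0.584 g/day, period:cohort 0.5 : 0.5 , from age 20
#>   calibrated coefficients:
#>               p        c
#> male   0.977770 0.999826
#> female 0.962632 0.998483
```

The synthetic observed surface was generated with exactly those
coefficients as ground truth, so the calibration has recovered them. Now
run the scenarios:

```r
scen <- simulate(fit)   # fractions 1, 0.75, 0.5, 0.25, 0
scen
#> Salt counterfactual scenarios
#>   effect fractions: 1, 0.75, 0.5, 0.25, 0
#>   accumulated excess CVD deaths (ages 20-69):
#>     sex   scenario excess_deaths
#>  female 75% effect          2178
#>    male 75% effect         10350
#>  female 50% effect          4371
#>    male 50% effect         20848
#>  female 25% effect          6581
#>    male 25% effect         31496
#>  female  0% effect          8806
#>    male  0% effect         42298
```

Had salt stayed at its 1950 level (`0% effect`), the synthetic male
population would have suffered ≈42,300 additional CVD deaths over
1950–2017; the totals scale almost linearly in `1 − f`. Annual detail and
cohort curves:

```r
e0 <- scen$excess[["0% effect"]]
subset(e0, year %in% c(1960, 1990, 2017) & sex == "male")
#>   sex year  scenario base_deaths scenario_deaths absolute_excess relative_excess_pct
#>  male 1960 0% effect     12062.2         12188.5           126.3                 1.0
#>  male 1990 0% effect     16836.1         17633.5           797.4                 4.7
#>  male 2017 0% effect     10482.1         11498.4          1016.3                 9.7

tail(cohort_curve(scen$runs[["base"]], 1940, "male"), 2)
#>  year age rate_per_1000
#>  2008  68         1.523
#>  2009  69         1.610
```

The relative excess grows over time (the salt gap accumulates through the
cohort channel), and each cohort's curve ends in the year it reaches age
69 — 2009 for the 1940 cohort. `plot(scen)`, `plot(scen, "relative")` and
`plot(fit)` draw the standard figures. Real data can be supplied as seven
CSV tables via `read_inputs()` (see `?read_inputs` for the schemas), and a
thin command-line wrapper is installed at `inst/cli/saltapc.R`
(`synth`, `impute-salt`, `calibrate`, `simulate`, `report`).

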