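# stratalife

Life expectancy (LE) and years of life lost (YLL) for disease cohorts
with selection effects, built on the Chiang II abridged life table.

Estimating LE for a cohort such as adults in care for HIV runs into two
problems that the standard abridged table ignores. Mortality is a
function of *time since entering the cohort* as well as age — rates in
the first year of care are a multiple of those of same-age longer-term
survivors — and rates for the oldest age groups are unavailable because
a young cohort has no person-time there. `stratalife` modifies the
Chiang II calculation to accept rates stratified by time since entry
(the first 5-year age group is split into a 1-year *select* interval
and a 4-year remainder), to complete the schedule at old ages by
Gompertz projection, a constant rate ratio, or a constant rate
difference against a general-population reference — with every
extrapolated rate floored at the reference rate — and to report the
Chiang sampling variance of LE from the ages with observed rates.

The core conversion is Chiang's

    q_x = n M_x / (1 + n (1 - a) M_x),      a = 0.5 by default

per age interval of width `n` and central rate `M_x`, with `q = 1` and
`e = 1/M` in the open-ended terminal group; LE at the table's first age
is `e = T/l` as usual, with `var(q_x) = q_x^2 (1 - q_x) / D_x` feeding
the LE error bar.

The package also tabulates stratified rates from person-level records
(three-visits-in-three-years entry rule, censoring at the minimum of
eligibility end and one year after last contact, exact person-time
splitting), computes exact Poisson rate CIs, fits quasi-Poisson annual
trends (AAPC), and ships a person-level cohort simulator for end-to-end
parameter-recovery validation.

## Worked example

The package bundles the published mortality inputs of a province-wide
HIV care cohort (Ontario, 2005–2012): stratified cohort rates by
5-year age group and the matching general-population schedule.

```r
library(stratalife)

rates     <- hiv_rates_ontario()   # first_year + survivor strata, 20-24 ... 90+
reference <- ontario_reference()   # Ontario general-population schedule

res <- run_scenario("gompertz_start90", rates, reference, entry_age = 20)
print(res)
#> scenario 'gompertz_start90' at entry age 20
#> LE at age 20: 47.5 years (95% CI +/- 0.00)
#> YLL vs reference: 14.7 years
#> reference LE at same age: 62.2 years
```

A 20-year-old entering HIV care is expected to live 47.5 more years
under 2005–2012 rates, versus 62.2 for the general population — 14.7
years of life lost. (The error bar is zero here because the published
rates carry no deaths/person-years counts; supply counts to get the
Chiang variance.) The schedule behind this number: a 1-year interval at
the first-year-of-care rate, survivor rates through 85–89, and a 90+
rate from a Gompertz fit to the survivor rates at ages 30–59, floored
at the reference:

```r
fit <- fit_gompertz(rates[rates$stratum == "survivor", ], fit_ages = c(30, 59))
print(fit)
#> Gompertz fit over ages 30-59 (6 groups): log(rate) = -6.4088 + 0.04324 * age; residual SD 0.038
predict(fit, 92.5)   # 0.0899 -- below the reference 0.20184, so the floor binds
```

The cohort's fitted mortality trend crosses the general population's
around age 80: extrapolating it naively would claim HIV-positive
90-year-olds outlive their peers, which is why the reference floor
exists.

Other presets in `scenario_presets()` reproduce the conventional
sensitivity grid (rate ratios 2–3, rate differences 0.013–0.03,
extrapolation from 60 vs 90); `open_55_variant()` computes the biased
55+ open-group shortcut for comparison. Annual trend summary:

```r
ann <- hiv_annual_ontario()
d <- ann[ann$year >= 2000, ]
aapc(d$deaths, d$in_care, d$year)
#> AAPC: -4.1%/yr (95% CI -5.2, -3.0); dispersion 1.30
```

Simulated-cohort validation of the whole pipeline:

```r
cfg <- sim_config(seed = 314, n_entrants_per_year = 5000,
                  year_range = c(1993L, 2012L))
recovery_suite(cfg, entry_age = 20)
#> recovery over 100000 records: 19 cells compared, max |z| 1.42
#> LE pipeline 49.08 vs analytic 49.08 (gap +0.01 years)
```

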