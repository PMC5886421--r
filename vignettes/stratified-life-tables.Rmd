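---
title: "Stratified abridged life tables with old-age extrapolation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified abridged life tables with old-age extrapolation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratalife)
```

## The problem

Period life expectancy (LE) for a disease cohort — say, adults in care
for HIV — cannot be read off a standard abridged life table for two
reasons. First, mortality depends on time since entering the cohort as
well as on age: people entering care are often diagnosed late, so their
mortality in the first year of care is a multiple of that of
same-age patients who have already stabilised on treatment (a *select*
effect, in the actuarial sense of select-and-ultimate tables). Pooling
the two regimes contaminates every age-specific rate with first-year
deaths. Second, a young cohort has little or no person-time at the
oldest ages, so the age-specific rates needed to close the table do not
exist and must be extrapolated. The historically common shortcut —
collapsing everything above 55 into the open-ended age group — badly
overstates LE once expected age at death exceeds 55, because the
cohort's age mix *within* 55+ is far younger than the stationary mix the
life table implicitly assumes.

`stratalife` addresses both issues inside the Chiang II abridged
life-table framework: the entry-age group is split into a 1-year select
interval and its 4-year remainder, old-age rates are completed by one of
three explicit extrapolation rules floored at a general-population
reference schedule, and the sampling variance of LE is propagated from
the ages where cohort rates were actually observed.

## The life-table model

For an age interval of width $n$ with central mortality rate $M$
(deaths per person-year), the conditional probability of death is
Chiang's conversion

$$q = \frac{nM}{1 + n(1-a)M},$$

where $a$ is the average fraction of the interval lived by those dying
in it; `a = 0.5` throughout by default, the standard convention for
adult ages, exposed as a parameter of every entry point. Columns follow
the usual recursion: survivors $l$ (radix $100\,000$), deaths
$d = l q$, person-years $L = n\,(l - (1-a)d)$, cumulative person-years
$T$, and $e = T/l$. The open-ended terminal interval has $q = 1$ and
$L = l/M$, hence $e = 1/M$ there; a table whose open group starts at 90
therefore needs a defensible 90+ rate, which is exactly what the
extrapolation supplies.

Sampling variance uses Chiang's form
$\operatorname{var}(q) = q^2(1-q)/D$ for closed intervals with $D$
observed deaths, a Poisson contribution $l^2/(M^2 D)$ from the open
interval, and zero from intervals whose deaths counts are absent or
zero. Extrapolated and reference-substituted intervals are treated as
known constants, so the reported error bar reflects only the ages with
observed cohort rates. This is one defensible convention among several
(variants differ in the final-age term); we implement this single
convention rather than a menu, because it is the one whose terms are
auditable from the table's own columns.

Two identities are worth knowing when reasoning about this machinery:

* $M_i L_i = d_i$ holds exactly in every interval, so a
  person-time-weighted pooled rate over any upper tail of a *stationary*
  table equals $l/T$ at the tail's start — collapsing 55+ into the open
  group with stationary weights is exactly unbiased. The 55+ bias
  in real cohorts is therefore entirely an age-mix effect, which
  `open_55_variant()` demonstrates.
* Chiang's conversion is not multiplicative over interval splits:
  $(1-q_5) \ne (1-q_1)(1-q_4)$ at equal rates, with a third-order
  discrepancy in $nM$. Consequently "stratified equals pooled when the
  strata rates are equal" holds to about $10^{-6}$ years at realistic
  rates, not to machine precision; tests assert it at that tolerance.

## Stratification by time since entry

`stratified_schedule(entry_age, ...)` emits `[entry, entry+1)` at the
first-year rate of the entry age's 5-year group, the remainder
`[entry+1, next boundary)` at the survivor rate (dropped when empty,
e.g. entry at 24), then survivor rates for all older groups. LE
"conditional on surviving the first year of care" (`survivor_only =
TRUE`) skips the split, and a rate table carrying only a `pooled`
stratum reproduces the plain unstratified table. When the entry age
falls at or above the extrapolation start and no observed first-year
rate exists, the first-year rate is taken as the survivor
(extrapolated) rate scaled by the oldest observed first-year/survivor
ratio — an assumption, flagged as such, needed only for entry ages
beyond the observed range.

## Completing the schedule at old ages

Three rules complete the schedule from `start_age` upward, all floored
at the reference schedule so that cohort mortality is never assumed
*lower* than the general population's:

* **Gompertz**: ordinary least squares of $\log M$ on age-group
  midpoints (default fit ages 30–59, where cohort rates are typically
  well estimated and visibly log-linear), projected at the midpoints of
  the missing groups and at `age_start + 2.5` for the open group
  (92.5 for a 90+ group — the midpoint convention continued; both the
  offset and a deaths-weighted fit are available but off by default,
  since the unweighted fit at 92.5 reproduces the published sensitivity
  grid).
* **Rate ratio**: reference rate times a constant (2–3 are
  conventional sensitivity values).
* **Rate difference**: reference rate plus a constant excess
  (0.013–0.03 deaths/person-year).

`start_age = 90` keeps observed rates through 85–89 and adjusts only
the open group; `start_age = 60` is the situation forced when rates
above 60 are unavailable. The floor interacts with fitting noise: since
$\mathrm{E}[\max(\hat{M}, M_{ref})] \ge \max(\mathrm{E}\hat{M},
M_{ref})$, very noisy fits are pulled slightly upward, which is
conservative (never optimistic) for LE.

## Rates from person-level records

Cohort entry is the first of three disease-related visits within three
years; follow-up ends at death or at the minimum of eligibility end,
one year after last health-care contact, and administrative closure.
Ages are continuous (365.25 days per year, the leap-year-free
convention; the first-year boundary is entry + 365.25 days) and
person-time is split *exactly* at age-group boundaries, the
first-anniversary boundary and the analysis-window limits using
`survival::survSplit`, so cell totals are invariant to arbitrary
further splitting — a property the tests exercise. Records entering
before the window contribute whatever part of their select year
overlaps the window, and survivor time thereafter. Records known only
by 5-year birth cohort use the cohort's mid year as representative
birth year. Rate confidence intervals are Garwood exact Poisson
(chi-square form), with a zero lower bound at zero deaths.

For annual series the crude rate is deaths over the end-of-year
in-care count — matching how such surveillance tables print their
arithmetic — while `tabulate_person_time()` remains exact; the
quasi-Poisson AAPC regresses annual deaths on calendar year with a log
in-care offset, years centred (the estimate is invariant to centring),
dispersion by Pearson $\chi^2/\mathrm{df}$ inflating the slope SE only.

## The synthetic cohort

`simulate_cohort()` generates person records with exactly the
structure the analysis assumes: a Gompertz baseline hazard in age
(defaults $\log M = -6.5 + 0.044\,\mathrm{age}$, cohort-survivor
scale), a first-year hazard multiplier (default 2.6), exponential loss
to follow-up (default 1%/year), 850 entrants per year with entry ages
20–64 averaging about 40 — each default chosen to mirror a
province-wide HIV care cohort. Death times are sampled by inversion on
a 0.1-year piecewise-constant grid; because the hazard factorises into
a person-level scale and a shared shape, one cumulative grid serves
every person and the sampler is exact at grid resolution. The
simulation is deterministic under its seed and restores the global RNG
state.

What the generator does *not* emulate — and hence what passing
recovery tests cannot certify about real data: secular improvement in
mortality over calendar time, covariate heterogeneity (sex, income,
disease stage), competing risks and cause-of-death structure, reporting
delay, or dependence between loss to follow-up and health status. It
validates the *pipeline*, not the epidemiology.

`recovery_suite()` runs simulate → tabulate → rates → extrapolate →
life table and compares estimated cell hazards to the generating ones
(z-scores, cells with ≥ 50 deaths) and the pipeline LE to
`analytic_le()`, a fine 1-year life table built directly from the
generating hazards. Two conventions matter here. An age group is
treated as *observed* only with at least 1000 survivor person-years
(the conventional reliability threshold; thinner groups go to
extrapolation). And the flooring reference is `generating_reference()`,
the *stationary* schedule the hazards imply — group rates as deaths
over person-years of a fine life table, the open group at $l/T = 1/e$
— because that, not the hazard evaluated at 92.5, is what a published
reference schedule contains; using the raw hazard at the open group's
nominal midpoint understates open-group mortality under a rising
hazard and would bias recovered LE upward by over a year.

The recovery check in the acceptance suite uses 100,000 records as
5,000 entrants/year over a 20-year window: the long window gives the
cohort enough old-age follow-up that observed coverage reaches the 70s
and the LE comparison is sharp (about ±0.35 years of sampling noise at
this size). Smaller unit tests use 3,000–50,000 records.

## Numerical choices and degenerate inputs

* Open-ended interval encoded as `width = NA` in memory, `-1` in
  files; exactly one, always last — validated on construction.
* A zero-width remainder after the 1-year split is dropped, not
  emitted; schedules are validated for contiguity to $10^{-9}$ years.
* A zero rate in the open group is an error (its $e = 1/M$ is
  undefined); zero rates in closed intervals are legal ($q = 0$) but
  are excluded from Gompertz fits with a warning.
* Rates given alongside deaths and person-years must agree with
  deaths/person-years to within the printing precision of the rate.
* Quasi-Poisson fitting uses `glm` with convergence tolerance
  $10^{-10}$; the Gompertz fit is a plain `lm` on logs.
* All LE values are carried at full precision and rounded to one
  decimal only for display.

## Limitations

The package computes *period* LE: it assumes current rates persist, so
its numbers are summary measures, not forecasts. Extrapolated old-age
rates inherit the structural assumption of the chosen rule; the
sensitivity grid (`scenario_presets()`) exists precisely because no
single rule is right, and the spread across rules — a few years — is
itself the honest statement of that uncertainty. The variance reflects
sampling error in observed rates only, not extrapolation uncertainty.
Average LE over an entry-age distribution is only as good as that
distribution.
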