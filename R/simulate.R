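# Person-level cohort simulator with the structure the life-table
# analysis assumes: Gompertz baseline mortality in age, an excess-hazard
# multiplier during the first year after entry (the select effect), and
# exponential loss to follow-up. Used for end-to-end parameter-recovery
# checks of the tabulation -> rates -> extrapolation -> LE pipeline.

#' Configure the cohort simulator
#'
#' Death times follow the hazard
#' `h(t) = exp(g0 + g1 * (age_at_entry + t)) * m(t)` with `m(t) =
#' first_year_multiplier` for `t < 1` year since entry and 1 after, i.e. a
#' Gompertz baseline with a select-period excess. Loss to follow-up is an
#' independent exponential. Entry dates are uniform within each calendar
#' year; entry ages are drawn from `entry_age_distribution` plus a
#' uniform fraction of a year.
#'
#' @param seed integer seed; the simulation is deterministic given it.
#' @param n_entrants_per_year entrants per calendar year (default 850, the
#'   scale of a province-wide HIV care cohort).
#' @param year_range `c(first, last)` calendar years of entry.
#' @param entry_age_distribution data.frame with `age` (integer years) and
#'   `weight` columns; the default spans ages 20-64 with mean near 40
#'   years, as observed for ages at entry to HIV care.
#' @param gompertz_intercept,gompertz_slope baseline log-hazard at age 0
#'   and its per-year increase. The defaults (-6.5, 0.044) give
#'   survivor-stratum rates of cohort scale: about 0.004 deaths per
#'   person-year at age 20 rising to 0.02 at age 60.
#' @param first_year_multiplier hazard ratio during the first year after
#'   entry (`>= 1`); the default 2.6 matches the select effect typical of
#'   HIV care cohorts.
#' @param ltf_rate per-year hazard of loss to follow-up (default 0.01, as
#'   in a linked administrative cohort).
#' @param admin_end administrative end of follow-up; default December 31
#'   of `year_range[2]`.
#' @param max_age age above which the simulated hazard is truncated
#'   (everyone still alive is censored administratively anyway).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_entrants_per_year = 850L,
                       year_range = c(2005L, 2012L),
                       entry_age_distribution =
                         data.frame(age = 20:64,
                                    weight = stats::dnorm(20:64, 40, 10)),
                       gompertz_intercept = -6.5, gompertz_slope = 0.044,
                       first_year_multiplier = 2.6, ltf_rate = 0.01,
                       admin_end = NULL, max_age = 110) {
  if (first_year_multiplier < 0 || ltf_rate < 0)
    stop("hazards must be >= 0")
  if (is.null(admin_end))
    admin_end <- as.Date(sprintf("%d-12-31", year_range[2]))
  structure(list(seed = as.integer(seed),
                 n_entrants_per_year = n_entrants_per_year,
                 year_range = year_range,
                 entry_age_distribution = entry_age_distribution,
                 gompertz_intercept = gompertz_intercept,
                 gompertz_slope = gompertz_slope,
                 first_year_multiplier = first_year_multiplier,
                 ltf_rate = ltf_rate, admin_end = as.Date(admin_end),
                 max_age = max_age),
            class = "sim_config")
}

# evaluate the generating hazard at age `age` for time-since-entry `tse`
sim_hazard <- function(config, age, tse) {
  exp(config$gompertz_intercept + config$gompertz_slope * age) *
    ifelse(tse < 1, config$first_year_multiplier, 1)
}

#' Simulate person-level cohort records
#'
#' Death times are sampled by inversion of the cumulative hazard on a
#' piecewise-constant grid (0.1-year steps). Because the hazard factorises
#' into a person level `exp(g0 + g1 * age_at_entry)` and a shared shape
#' `exp(g1 * t) * m(t)`, a single cumulative grid serves every person.
#' Lost-to-follow-up records get an `eligibility_end` date; everyone else
#' is administratively censored at `admin_end` unless dead before it.
#'
#' @param config a [sim_config()].
#' @return A data.frame of person records (`id`, `birth_date`,
#'   `entry_date`, `death_date`, `eligibility_end`, `last_contact`)
#'   consumable by [resolve_records()].
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  yrs <- seq(config$year_range[1], config$year_range[2])
  n <- config$n_entrants_per_year * length(yrs)
  entry_year <- rep(yrs, each = config$n_entrants_per_year)
  entry_date <- as.Date(sprintf("%d-01-01", entry_year)) +
    floor(stats::runif(n) * 365)
  dist <- config$entry_age_distribution
  age0 <- dist$age[sample.int(nrow(dist), n, replace = TRUE,
                              prob = dist$weight)] + stats::runif(n)
  birth_date <- entry_date - round(age0 * DAYS_PER_YEAR)
  age0 <- as.numeric(entry_date - birth_date) / DAYS_PER_YEAR

  t_death <- sample_death_times(config, age0)
  t_ltf <- if (config$ltf_rate > 0) stats::rexp(n, config$ltf_rate) else
    rep(Inf, n)
  t_admin <- as.numeric(config$admin_end - entry_date) / DAYS_PER_YEAR

  died <- t_death <= pmin(t_ltf, t_admin)
  lost <- !died & t_ltf <= t_admin
  death_date <- as.Date(rep(NA, n))
  death_date[died] <- entry_date[died] +
    round(t_death[died] * DAYS_PER_YEAR)
  elig_end <- as.Date(rep(NA, n))
  elig_end[lost] <- entry_date[lost] + round(t_ltf[lost] * DAYS_PER_YEAR)

  data.frame(id = sprintf("p%06d", seq_len(n)),
             birth_date = birth_date, entry_date = entry_date,
             death_date = death_date, eligibility_end = elig_end,
             last_contact = as.Date(rep(NA, n)),
             stringsAsFactors = FALSE)
}

# inverse-CDF sampling of death times since entry on a 0.1-year grid.
# H_i(t) = A_i * C(t) with A_i = exp(g0 + g1*age0_i) and C the shared
# cumulative of exp(g1*t)*m(t); solve A_i*C(T) = E_i, E ~ Exp(1).
sample_death_times <- function(config, age0, dt = 0.1) {
  g1 <- config$gompertz_slope
  horizon <- config$max_age - min(age0)
  tg <- seq(0, horizon, by = dt)
  B <- exp(g1 * tg) * ifelse(tg < 1, config$first_year_multiplier, 1)
  C <- cumsum(B * dt)
  A <- exp(config$gompertz_intercept + g1 * age0)
  target <- stats::rexp(length(age0)) / A
  j <- findInterval(target, c(0, C)) # step index whose interior holds T
  over <- j > length(tg)
  j[over] <- length(tg)
  C0 <- c(0, C)[j]
  t_death <- tg[j] + (target - C0) / B[j]
  t_death[over] <- Inf
  t_death
}

#' Life expectancy implied by the generating hazards
#'
#' The simulator's analytic benchmark: a fine-grained (1-year) life table
#' built directly from the generating hazard, with the first-year
#' multiplier applied to the first interval after entry and an open-ended
#' interval at `max_age`.
#'
#' @param config a [sim_config()].
#' @param entry_age age at cohort entry.
#' @param select apply the first-year multiplier to the first year
#'   (default `TRUE`).
#' @return Life expectancy in years at `entry_age`.
#' @export
analytic_le <- function(config, entry_age, select = TRUE) {
  ages <- seq(entry_age, config$max_age - 1)
  tse <- ages - entry_age + 0.5
  if (!select) tse <- tse + 1  # never inside the select window
  rate <- sim_hazard(config, ages + 0.5, tse)
  open_rate <- sim_hazard(config, config$max_age + 0.5, Inf)
  sched <- age_schedule(c(ages, config$max_age),
                        c(rep(1, length(ages)), NA), c(rate, open_rate))
  build_life_table(sched)$e[1L]
}

#' Reference schedule implied by the generating hazards
#'
#' Emulates a published general-population schedule for the simulated
#' world: age-group rates are the stationary person-time-weighted rates
#' of the generating (no-select) hazard, computed from a fine (1-year)
#' life table as deaths over person-years lived within each group; the
#' open-ended group's rate is `l/T` at its starting age, i.e. the
#' reciprocal of remaining life expectancy there — exactly what observed
#' deaths over person-years converge to in a stationary population.
#'
#' @param config a [sim_config()].
#' @param age_breaks lower bounds of the 5-year groups plus the open
#'   group's start (default `seq(20, 90, 5)`).
#' @return A [reference_schedule()].
#' @export
generating_reference <- function(config, age_breaks = seq(20, 90, 5)) {
  a0 <- age_breaks[1]
  ages <- seq(a0, config$max_age - 1)
  fine <- build_life_table(age_schedule(
    c(ages, config$max_age), c(rep(1, length(ages)), NA),
    sim_hazard(config, c(ages + 0.5, config$max_age + 0.5), Inf)))
  open_start <- age_breaks[length(age_breaks)]
  gi <- findInterval(fine$age_start, age_breaks)
  closed <- fine$age_start < open_start
  d_grp <- tapply(fine$d[closed], gi[closed], sum)
  L_grp <- tapply(fine$L[closed], gi[closed], sum)
  i_open <- match(open_start, fine$age_start)
  open_rate <- fine$l[i_open] / fine$T[i_open]  # 1 / e at the open age
  reference_schedule(age_breaks, c(diff(age_breaks), NA),
                     c(as.numeric(d_grp / L_grp), open_rate))
}

#' End-to-end parameter recovery report
#'
#' Runs the full pipeline on one simulated cohort — simulate, resolve,
#' tabulate person-time, estimate rates, extrapolate, life table — and
#' compares (a) estimated age-group hazards against the generating
#' hazards (z-scores on the log scale, restricted to cells with enough
#' deaths) and (b) the pipeline life expectancy against [analytic_le()].
#'
#' @param config a [sim_config()].
#' @param entry_age entry age at which LE is compared.
#' @param age_breaks age-group layout for tabulation.
#' @param min_deaths cells with fewer deaths are excluded from the hazard
#'   comparison (default 50).
#' @param min_py an age group is treated as observed (rather than handed
#'   to extrapolation) only with at least this much survivor person-time
#'   (default 1000, the conventional reliability threshold for 5-year
#'   groups).
#' @return A list of class `"recovery_report"`: `cells` (per-cell rates,
#'   generating hazards and z-scores), `le_pipeline`, `le_analytic`,
#'   `le_gap`, `n_records`, `config`.
#' @export
recovery_suite <- function(config, entry_age = 20,
                           age_breaks = seq(20, 90, 5), min_deaths = 50,
                           min_py = 1000) {
  persons <- simulate_cohort(config)
  rec <- resolve_records(persons, admin_end = config$admin_end)
  period <- c(as.Date(sprintf("%d-01-01", config$year_range[1])),
              config$admin_end)
  cells <- tabulate_person_time(rec, period, age_breaks)
  rt <- suppressWarnings(rates_with_ci(cells))

  mids <- interval_midpoints(rt)
  gen <- sim_hazard(config, mids, ifelse(rt$stratum == "first_year", 0.5, 2))
  z <- (log(rt$rate) - log(gen)) / (1 / sqrt(pmax(rt$deaths, 1)))
  keep <- rt$deaths >= min_deaths
  comp <- data.frame(age_start = rt$age_start, stratum = rt$stratum,
                     deaths = rt$deaths, person_years = rt$person_years,
                     rate = rt$rate, generating = gen, z = z,
                     compared = keep)

  # reference for flooring: the stationary schedule the generating
  # hazards imply (what a published reference table would show)
  ref <- generating_reference(config, age_breaks)
  # extrapolate from the end of well-populated survivor coverage
  sv <- rt[rt$stratum == "survivor", ]
  ok <- age_breaks %in% sv$age_start[sv$person_years >= min_py &
                                       sv$deaths >= 1]
  n_run <- which(!ok)[1] - 1L  # leading run of well-populated groups
  if (is.na(n_run)) n_run <- length(age_breaks)
  if (n_run < 1L) stop("no well-populated survivor age groups to fit")
  start_age <- if (n_run == length(age_breaks)) max(age_breaks) else
    age_breaks[n_run + 1L]
  cfg <- extrapolation_config("gompertz", start_age = start_age,
                              fit_ages = c(min(age_breaks) + 10,
                                           min(start_age, 60) - 1))
  sched <- stratified_schedule(entry_age, rt, ref, cfg)
  le_pipe <- build_life_table(sched)$e[1L]
  le_true <- analytic_le(config, entry_age)

  structure(list(cells = comp, le_pipeline = le_pipe,
                 le_analytic = le_true, le_gap = le_pipe - le_true,
                 n_records = nrow(persons), config = config),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  k <- x$cells[x$cells$compared, ]
  cat(sprintf("recovery over %d records: %d cells compared, max |z| %.2f\n",
              x$n_records, nrow(k), max(abs(k$z))))
  cat(sprintf("LE pipeline %.2f vs analytic %.2f (gap %+.2f years)\n",
              x$le_pipeline, x$le_analytic, x$le_gap))
  invisible(x)
}
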