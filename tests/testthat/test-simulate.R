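# Synthetic cohort generator: determinism, distributional correctness,
# and recovery of the generating select effect.

test_that("simulation is deterministic under a seed and leaves the RNG alone", {
  cfg <- sim_config(seed = 42, n_entrants_per_year = 150)
  a <- simulate_cohort(cfg)
  set.seed(1); before <- runif(1)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  # global RNG stream untouched by the simulator
  set.seed(1); expect_identical(runif(1), before)
})

test_that("zero hazards mean administrative censoring for everyone", {
  cfg <- sim_config(seed = 3, n_entrants_per_year = 100,
                    gompertz_intercept = -Inf, ltf_rate = 0)
  p <- simulate_cohort(cfg)
  expect_true(all(is.na(p$death_date)))
  expect_true(all(is.na(p$eligibility_end)))
  rec <- resolve_records(p, admin_end = cfg$admin_end)
  expect_true(all(rec$exit_date == cfg$admin_end))
})

test_that("simulated death times follow the generating survival function (KS)", {
  # fixed entry age so the generating survival curve is in closed form
  cfg <- sim_config(seed = 8, n_entrants_per_year = 1250,
                    year_range = c(2005L, 2012L),
                    entry_age_distribution = data.frame(age = 40, weight = 1),
                    gompertz_intercept = -4.5,
                    first_year_multiplier = 3, ltf_rate = 0)
  p <- simulate_cohort(cfg)
  rec <- resolve_records(p, admin_end = cfg$admin_end)
  t_death <- as.numeric(rec$death_date - rec$entry_date) / 365.25
  age0 <- as.numeric(rec$entry_date - rec$birth_date) / 365.25
  # restrict to deaths within 1 year of entry among a fixed-age slice:
  # conditional distribution is that of min(T, 1) truncated; instead use
  # all deaths and compare against the exact piecewise-Gompertz CDF by
  # probability integral transform (censoring-free up to admin end)
  dead <- rec$died
  g0 <- cfg$gompertz_intercept; g1 <- cfg$gompertz_slope; m <- 3
  cumhaz <- function(t, a0) {
    base <- exp(g0 + g1 * a0) / g1
    ifelse(t < 1, m * base * (exp(g1 * t) - 1),
           base * (m * (exp(g1) - 1) + exp(g1 * t) - exp(g1)))
  }
  # Kolmogorov-Smirnov on U = 1 - exp(-H(T)) conditional on death before
  # the (per-person) admin horizon: U/U_max is Uniform(0,1)
  h_admin <- cumhaz(as.numeric(cfg$admin_end - rec$entry_date) / 365.25, age0)
  u <- (1 - exp(-cumhaz(t_death[dead], age0[dead]))) /
    (1 - exp(-h_admin[dead]))
  expect_gt(length(u), 1000)
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("a unit multiplier gives equal strata; multiplier 3 is recovered", {
  breaks <- seq(20, 90, 5)
  run_rates <- function(mult, n) {
    cfg <- sim_config(seed = 21, n_entrants_per_year = n,
                      first_year_multiplier = mult)
    rec <- resolve_records(simulate_cohort(cfg), admin_end = cfg$admin_end)
    cells <- tabulate_person_time(rec, c(as.Date("2005-01-01"),
                                         cfg$admin_end), breaks)
    suppressWarnings(rates_with_ci(cells))
  }
  ratio_z <- function(rt, target) {
    fy <- rt[rt$stratum == "first_year", ]
    sv <- rt[rt$stratum == "survivor", ]
    i <- match(fy$age_start, sv$age_start)
    ok <- fy$deaths >= 50 & sv$deaths[i] >= 50
    lr <- log(fy$rate[ok] / sv$rate[i][ok])
    se <- sqrt(1 / fy$deaths[ok] + 1 / sv$deaths[i][ok])
    z <- (lr - log(target)) / se
    # inverse-variance pooled estimate across age groups
    w <- 1 / se^2
    list(z = z, n = sum(ok),
         z_pooled = (sum(w * lr) / sum(w) - log(target)) / sqrt(1 / sum(w)))
  }
  r1 <- ratio_z(run_rates(1, 6000), 1)
  expect_gt(r1$n, 0)
  expect_lt(abs(r1$z_pooled), 3)   # combined ratio recovers the target
  expect_true(all(abs(r1$z) <= 4)) # no wild single-group departure
  r3 <- ratio_z(run_rates(3, 2500), 3)
  expect_gt(r3$n, 0)
  expect_lt(abs(r3$z_pooled), 3)
  expect_true(all(abs(r3$z) <= 4))
})

test_that("loss to follow-up approximates its configured rate", {
  cfg <- sim_config(seed = 14, n_entrants_per_year = 2000,
                    gompertz_intercept = -Inf, ltf_rate = 0.01)
  rec <- resolve_records(simulate_cohort(cfg), admin_end = cfg$admin_end)
  py <- as.numeric(rec$exit_date - rec$entry_date) / 365.25
  ltf <- sum(!is.na(rec$eligibility_end))
  rate <- ltf / sum(py)
  expect_equal(rate, 0.01, tolerance = 3 / sqrt(ltf))
})

test_that("recovery report is reproducible and internally consistent", {
  cfg <- sim_config(seed = 6, n_entrants_per_year = 400)
  r1 <- recovery_suite(cfg, entry_age = 30, min_py = 100)
  r2 <- recovery_suite(cfg, entry_age = 30, min_py = 100)
  expect_identical(r1, r2)
  expect_equal(r1$n_records, 400 * 8)
  expect_true(is.finite(r1$le_gap))
  # null select effect: generating hazards equal the reference, so the
  # pipeline LE should track the no-select analytic LE closely
  cfg0 <- sim_config(seed = 61, n_entrants_per_year = 1500,
                     year_range = c(1993L, 2012L),
                     first_year_multiplier = 1)
  r0 <- recovery_suite(cfg0, entry_age = 30)
  expect_lt(abs(r0$le_gap), 1.5)
})

test_that("a select effect shows up as pooled-below-stratified LE ordering", {
  # pooled rates mix first-year deaths into every age group, so ignoring
  # stratification must lower the calculated LE when the multiplier > 1
  cfg <- sim_config(seed = 17, n_entrants_per_year = 2500,
                    first_year_multiplier = 3)
  rec <- resolve_records(simulate_cohort(cfg), admin_end = cfg$admin_end)
  breaks <- seq(20, 90, 5)
  cells <- tabulate_person_time(rec, c(as.Date("2005-01-01"), cfg$admin_end),
                                breaks)
  rt <- suppressWarnings(rates_with_ci(cells))
  agg <- stats::aggregate(cbind(deaths, person_years) ~ age_start + width,
                          data = as.data.frame(rt), FUN = sum)
  pooled <- rate_table(agg$age_start, agg$width, "pooled",
                       agg$deaths / agg$person_years,
                       agg$deaths, agg$person_years)
  layout <- data.frame(age_start = breaks, width = c(diff(breaks), NA))
  ref <- reference_schedule(breaks, layout$width,
                            sim_hazard_for_test(cfg, layout))
  keep_to <- max(rt$age_start[rt$stratum == "survivor" & rt$deaths > 0])
  cfg_x <- extrapolation_config("gompertz", start_age = min(keep_to + 5, 90),
                                fit_ages = c(30, 59))
  e_strat <- build_life_table(
    stratified_schedule(25, rt, ref, cfg_x))$e[1]
  e_pool <- build_life_table(
    stratified_schedule(25, pooled, ref, cfg_x))$e[1]
  expect_lt(e_pool, e_strat)
})
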