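# Shared fixtures and independent oracles for the test suite.

# cohort and reference tables bundled with the package (published
# Ontario HIV cohort rates, 2005-2012)
fx_rates <- hiv_rates_ontario()
fx_ref <- ontario_reference()
fx_annual <- hiv_annual_ontario()

# independently derived closed form for LE of a constant-rate schedule:
# k closed intervals of width n at rate m (Chiang conversion), then an
# open interval at rate m. Derived from the geometric survival series:
#   e0 = n (1 - (1-a) q) (1 - (1-q)^k) / q + (1-q)^k / m
constant_rate_le <- function(m, n, k, a = 0.5) {
  q <- n * m / (1 + n * (1 - a) * m)
  n * (1 - (1 - a) * q) * (1 - (1 - q)^k) / q + (1 - q)^k / m
}

# constant-rate schedule as an age_schedule
constant_schedule <- function(m, n, k, age0 = 20) {
  age_schedule(age0 + n * (0:k), c(rep(n, k), NA), rep(m, k + 1))
}

# brute-force oracle for the entry-date rule: check every consecutive
# visit triple
entry_date_bruteforce <- function(v, window_years = 3) {
  n <- length(v)
  if (n < 3L) return(as.Date(NA))
  for (i in seq_len(n - 2L)) {
    if (as.numeric(v[i + 2L] - v[i]) / 365.25 <= window_years) return(v[i])
  }
  as.Date(NA)
}

# discrete per-day survival under constant hazard h over `years` years:
# returns the implied central mortality rate and the death probability
discrete_survival_oracle <- function(h_per_year, years) {
  dt <- 1 / 2000  # per-interval resolution of the discrete grid
  steps <- years / dt
  p_step <- h_per_year * dt
  S <- (1 - p_step)^(0:steps)
  deaths <- 1 - S[steps + 1]
  py <- sum((S[-1] + S[-length(S)]) / 2) * dt
  list(M = deaths / py, q = deaths)
}

# the simulator's generating (no-select) hazard at group midpoints
sim_hazard_for_test <- function(cfg, layout) {
  mid <- ifelse(is.na(layout$width), layout$age_start + 2.5,
                layout$age_start + layout$width / 2)
  exp(cfg$gompertz_intercept + cfg$gompertz_slope * mid)
}

# synthetic counted schedule: reference-shaped rates with person-years,
# deaths consistent with the rates (for variance tests)
counted_schedule <- function(py = 2e4) {
  r <- fx_ref
  deaths <- round(r$rate * py)
  age_schedule(r$age_start, r$width, deaths / py, deaths, py,
               source = "observed")
}
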