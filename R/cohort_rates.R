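# Tabulation of stratified mortality rates from person-level cohort
# records: the visit-based entry rule, the censoring rule combining
# eligibility end and last contact, exact person-time splitting on the
# age / time-since-entry / calendar axes, and annual cohort bookkeeping.

DAYS_PER_YEAR <- 365.25

#' Cohort entry date from disease-related visit dates
#'
#' A person enters the cohort at the first of three disease-related visits
#' falling within a three-year window: the entry date is the earliest
#' visit `v[i]` such that `v[i+2] - v[i] <= 3` years. Fewer than three
#' qualifying visits mean the person never enters.
#'
#' @param visit_dates `Date` vector, sorted ascending.
#' @param window_years width of the qualifying window (default 3).
#' @return The entry `Date`, or `NA` if no triple qualifies.
#' @export
#' @examples
#' find_entry_date(as.Date(c("2000-01-01", "2001-01-01", "2002-07-01")))
find_entry_date <- function(visit_dates, window_years = 3) {
  v <- visit_dates[!is.na(visit_dates)]
  if (is.unsorted(v)) stop("visit_dates must be sorted ascending")
  n <- length(v)
  if (n < 3L) return(as.Date(NA))
  span <- as.numeric(v[3:n] - v[1:(n - 2L)]) / DAYS_PER_YEAR
  hit <- which(span <= window_years)
  if (length(hit) == 0L) return(as.Date(NA))
  v[hit[1L]]
}

#' End of follow-up for a cohort record
#'
#' Deaths end follow-up at the death date. Otherwise follow-up ends at the
#' earliest of: end of health-insurance eligibility, one year after the
#' last health-care contact (a proxy for the unrecorded date of leaving
#' the covered population), and the administrative end of the study
#' window. Absent fields are simply skipped in the minimum.
#'
#' @param death_date,eligibility_end,last_contact `Date` or `NA`.
#' @param admin_end administrative censoring `Date`.
#' @return The censoring (or death) `Date`.
#' @export
censor_date <- function(death_date = as.Date(NA),
                        eligibility_end = as.Date(NA),
                        last_contact = as.Date(NA),
                        admin_end) {
  n <- max(length(death_date), length(eligibility_end),
           length(last_contact), length(admin_end))
  death_date <- rep_len(as.Date(death_date), n)
  eligibility_end <- rep_len(as.Date(eligibility_end), n)
  contact_plus <- rep_len(as.Date(last_contact), n) + floor(DAYS_PER_YEAR)
  admin_end <- rep_len(as.Date(admin_end), n)
  cand <- cbind(as.numeric(eligibility_end), as.numeric(contact_plus),
                as.numeric(admin_end))
  end <- as.Date(apply(cand, 1L, min, na.rm = TRUE),
                 origin = "1970-01-01")
  dead <- !is.na(death_date)
  end[dead] <- death_date[dead]
  end
}

#' Read or normalise person-level cohort records
#'
#' @param persons a data.frame with columns `id`, `birth_date` (or
#'   `birth_cohort`, a 5-year label like `"1960-1964"` whose mid year is
#'   used as the representative birth year), `entry_date`, and optional
#'   `death_date`, `eligibility_end`, `last_contact` (ISO-8601 strings or
#'   `Date`s).
#' @param admin_end administrative end of follow-up (`Date`); used by
#'   [censor_date()] for records without a death date.
#' @return The records with `Date` columns, a resolved `birth_date`, and
#'   an `exit_date` column.
#' @export
resolve_records <- function(persons, admin_end) {
  p <- as.data.frame(persons)
  for (col in c("birth_date", "entry_date", "death_date",
                "eligibility_end", "last_contact")) {
    p[[col]] <- if (is.null(persons[[col]])) as.Date(NA) else
      as.Date(persons[[col]])
  }
  if (any(is.na(p$birth_date))) {
    if (is.null(persons$birth_cohort))
      stop("records need birth_date or birth_cohort")
    mid <- birth_cohort_midyear(persons$birth_cohort)
    use <- is.na(p$birth_date)
    p$birth_date[use] <- as.Date(sprintf("%d-07-01", mid[use]))
  }
  if (any(is.na(p$entry_date))) stop("records need entry_date")
  bad <- !is.na(p$death_date) & p$death_date < p$entry_date
  if (any(bad)) stop("death before entry in record(s): ",
                     paste(p$id[bad], collapse = ", "))
  p$exit_date <- as.Date(censor_date(p$death_date, p$eligibility_end,
                                     p$last_contact, admin_end),
                         origin = "1970-01-01")
  p$died <- !is.na(p$death_date) & p$death_date <= p$exit_date
  p
}

# mid year of a 5-year birth-cohort label "1960-1964" (or "1960_1964")
birth_cohort_midyear <- function(label) {
  parts <- regmatches(label, gregexpr("[0-9]{4}", label))
  vapply(parts, function(x) {
    x <- as.numeric(x)
    if (length(x) == 0L) return(NA_real_)
    floor(mean(range(x)))
  }, numeric(1))
}

#' Tabulate deaths and person-years by age group and time since entry
#'
#' Splits each record's follow-up exactly at age-group boundaries, at the
#' first-anniversary-of-entry boundary separating the `first_year` and
#' `survivor` strata, and at the analysis-period limits, then sums
#' person-years and deaths per cell. Splitting is done with
#' [survival::survSplit()] on the age and time-since-entry scales. Age is
#' continuous (365.25 days/year); the death is assigned to the cell
#' containing the death date. Records entering before the period
#' contribute survivor time only once their first anniversary has passed.
#'
#' @importFrom survival Surv
#' @param records resolved records from [resolve_records()].
#' @param period `c(start, end)` calendar `Date`s of the analysis window.
#' @param age_breaks lower bounds of the age groups (e.g. `seq(20, 90, 5)`);
#'   the last is the open-ended group's start. Follow-up below the first
#'   break is excluded.
#' @param strata_cut years since entry separating the select interval from
#'   the ultimate rates (default 1).
#' @return A data.frame of class `"cell_counts"` with `age_start`, `width`
#'   (`NA` for the open group), `stratum`, `deaths`, `person_years`.
#' @export
tabulate_person_time <- function(records, period, age_breaks,
                                 strata_cut = 1) {
  if (is.unsorted(age_breaks, strictly = TRUE))
    stop("age_breaks must be strictly increasing")
  p <- records
  t0 <- as.Date(period[1]); t1 <- as.Date(period[2])
  # clip follow-up to the analysis window (time in years since birth)
  start <- pmax(as.numeric(p$entry_date - p$birth_date),
                as.numeric(t0 - p$birth_date)) / DAYS_PER_YEAR
  stop_ <- pmin(as.numeric(p$exit_date - p$birth_date),
                as.numeric(t1 - p$birth_date)) / DAYS_PER_YEAR
  died_in <- p$died & p$exit_date >= t0 & p$exit_date <= t1
  keep <- stop_ > start
  df <- data.frame(age_in = start[keep], age_out = stop_[keep],
                   event = as.integer(died_in[keep]),
                   entry_age = as.numeric(p$entry_date - p$birth_date)[keep] /
                     DAYS_PER_YEAR)
  if (nrow(df) == 0L)
    return(empty_cells(age_breaks))
  # split on the age scale, then on the time-since-entry scale
  sp <- survival::survSplit(Surv(age_in, age_out, event) ~ .,
                            data = df, cut = age_breaks)
  sp$tse_in <- sp$age_in - sp$entry_age
  sp$tse_out <- sp$age_out - sp$entry_age
  sp2 <- survival::survSplit(Surv(tse_in, tse_out, event) ~ .,
                             data = sp, cut = strata_cut)
  sp2 <- sp2[sp2$tse_in + sp2$entry_age >= age_breaks[1] - 1e-9, ]
  age_lo <- sp2$entry_age + sp2$tse_in
  gi <- findInterval(age_lo + 1e-9, age_breaks)
  stratum <- ifelse(sp2$tse_out <= strata_cut + 1e-9, "first_year",
                    "survivor")
  py <- sp2$tse_out - sp2$tse_in
  key <- interaction(factor(gi, levels = seq_along(age_breaks)),
                     factor(stratum, levels = c("first_year", "survivor")),
                     drop = FALSE)
  cells <- empty_cells(age_breaks)
  cells$person_years <- as.numeric(tapply(py, key, sum, default = 0))
  cells$deaths <- as.numeric(tapply(sp2$event, key, sum, default = 0))
  cells
}

empty_cells <- function(age_breaks) {
  k <- length(age_breaks)
  out <- expand.grid(age_start = age_breaks,
                     stratum = c("first_year", "survivor"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$width <- rep(c(diff(age_breaks), NA_real_), 2L)
  out$deaths <- 0
  out$person_years <- 0
  out <- out[, c("age_start", "width", "stratum", "deaths", "person_years")]
  class(out) <- c("cell_counts", "data.frame")
  out
}

#' Mortality rates with exact Poisson confidence intervals
#'
#' Converts tabulated deaths and person-years to rates with Garwood exact
#' Poisson 95% confidence limits (chi-square form); with zero deaths the
#' lower limit is 0. Cells with zero person-years cannot yield a rate and
#' are dropped with a warning.
#'
#' @param cells output of [tabulate_person_time()].
#' @param conf confidence level (default 0.95).
#' @return A [rate_table()] with extra columns `rate_lo`, `rate_hi`.
#' @export
rates_with_ci <- function(cells, conf = 0.95) {
  c0 <- as.data.frame(cells)
  drop <- c0$person_years <= 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " cell(s) with zero person-years")
    c0 <- c0[!drop, ]
  }
  a <- (1 - conf) / 2
  D <- c0$deaths; PY <- c0$person_years
  lo <- ifelse(D == 0, 0, stats::qchisq(a, 2 * D) / 2) / PY
  hi <- stats::qchisq(1 - a, 2 * (D + 1)) / 2 / PY
  rt <- rate_table(c0$age_start, c0$width, c0$stratum, D / PY, D, PY)
  rt$rate_lo <- lo
  rt$rate_hi <- hi
  rt
}

#' Annual incidence, prevalence and mortality series for a cohort
#'
#' Per calendar year: new entries, deaths, losses to follow-up, the number
#' in care at year end (cumulative entries minus deaths and losses), the
#' percentage lost, the percentage newly entered, and the crude mortality
#' rate `deaths / in_care` with an exact Poisson 95% CI. The bookkeeping
#' identity `new - deaths - ltf = diff(in_care)` holds by construction.
#'
#' @param records resolved records from [resolve_records()].
#' @param years integer years to report.
#' @return A data.frame with columns `year`, `new_cases`, `deaths`, `ltf`,
#'   `in_care`, `pct_ltf`, `pct_new`, `crude_rate`, `rate_lo`, `rate_hi`.
#' @export
annual_series <- function(records, years) {
  p <- records
  yr_entry <- as.integer(format(p$entry_date, "%Y"))
  yr_exit <- as.integer(format(p$exit_date, "%Y"))
  all_yrs <- seq(min(c(yr_entry, years)), max(years))
  new_all <- tabulate(factor(yr_entry, levels = all_yrs), length(all_yrs))
  death_all <- tabulate(factor(yr_exit[p$died], levels = all_yrs),
                        length(all_yrs))
  ltf_all <- tabulate(factor(yr_exit[!p$died], levels = all_yrs),
                      length(all_yrs))
  in_care <- cumsum(new_all - death_all - ltf_all)
  i <- match(years, all_yrs)
  deaths <- death_all[i]; care <- in_care[i]
  lo <- ifelse(deaths == 0, 0, stats::qchisq(0.025, 2 * deaths) / 2) / care
  hi <- stats::qchisq(0.975, 2 * (deaths + 1)) / 2 / care
  data.frame(year = years, new_cases = new_all[i], deaths = deaths,
             ltf = ltf_all[i], in_care = care,
             pct_ltf = ltf_all[i] / care,
             pct_new = new_all[i] / care,
             crude_rate = deaths / care, rate_lo = lo, rate_hi = hi)
}
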