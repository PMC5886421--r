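# Containers for mortality schedules: a sequence of age intervals with
# rates (an "age_schedule"), a stratified cohort rate table ("rate_table"),
# and a general-population reference schedule ("reference_schedule").
# All are plain data.frames with a class attribute and validated columns;
# the open-ended terminal interval carries width = NA internally (encoded
# as -1 in delimited files).

#' Construct a mortality schedule over a sequence of age intervals
#'
#' An `age_schedule` is the input to [build_life_table()]: contiguous age
#' intervals, each with an all-cause mortality rate (deaths per person-year),
#' optional deaths and person-years counts, and a provenance flag. The last
#' interval must be open-ended (`width = NA`), as in the conventional
#' abridged life table whose terminal group (e.g. 90+) has no upper bound.
#'
#' @param age_start integer vector of interval starting ages (years),
#'   strictly increasing; each interval must begin where the previous ends.
#' @param width interval widths in years; `NA` marks the open-ended terminal
#'   interval, which must be last and unique.
#' @param rate mortality rates, deaths per person-year, all `>= 0`.
#' @param deaths optional death counts per interval (used for the sampling
#'   variance of life expectancy; `NA` where unknown).
#' @param person_years optional person-years at risk per interval; where
#'   both counts are present, `deaths / person_years` must agree with
#'   `rate` to within rounding of the printed rate.
#' @param source provenance of each rate: `"observed"`, `"extrapolated"`
#'   or `"reference"`. Extrapolated and reference-substituted rates are
#'   treated as known constants in variance propagation.
#'
#' @return A data.frame of class `"age_schedule"` with the above columns.
#' @seealso [build_life_table()], [stratified_schedule()]
#' @export
#' @examples
#' age_schedule(c(20, 25, 30), c(5, 5, NA), c(0.001, 0.002, 0.05))
age_schedule <- function(age_start, width, rate, deaths = NA_real_,
                         person_years = NA_real_,
                         source = "observed") {
  s <- data.frame(age_start = as.numeric(age_start),
                  width = as.numeric(width),
                  rate = as.numeric(rate),
                  deaths = as.numeric(deaths),
                  person_years = as.numeric(person_years),
                  source = as.character(source),
                  stringsAsFactors = FALSE)
  class(s) <- c("age_schedule", "data.frame")
  validate_schedule(s)
  s
}

validate_schedule <- function(s) {
  if (nrow(s) < 1L) stop("schedule has no intervals")
  if (any(s$rate < 0, na.rm = TRUE)) stop("mortality rates must be >= 0")
  open <- is.na(s$width)
  if (sum(open) != 1L || !open[nrow(s)])
    stop("schedule must have exactly one open-ended interval, and it must be last")
  if (any(s$width[!open] <= 0)) stop("interval widths must be positive")
  if (nrow(s) > 1L) {
    ends <- s$age_start[-nrow(s)] + s$width[-nrow(s)]
    if (any(abs(ends - s$age_start[-1L]) > 1e-9))
      stop("age intervals must be contiguous (each must begin where the previous ends)")
  }
  bad <- !is.na(s$deaths) & !is.na(s$person_years) & s$person_years > 0 &
    abs(s$rate - s$deaths / s$person_years) >
      pmax(5e-5, 5 * 10^(-rate_decimals(s$rate) - 1))
  if (any(bad))
    stop("rate disagrees with deaths/person_years beyond printing tolerance in row(s): ",
         paste(which(bad), collapse = ", "))
  if (!all(s$source %in% c("observed", "extrapolated", "reference")))
    stop("source must be one of 'observed', 'extrapolated', 'reference'")
  invisible(s)
}

# number of decimals a printed rate appears to carry (for the
# rate-vs-counts consistency check only)
rate_decimals <- function(x) {
  ch <- sub("0+$", "", sub(".*\\.", "", formatC(x, format = "f", digits = 10)))
  nchar(ch)
}

#' Construct a stratified cohort mortality rate table
#'
#' Rows of age-group mortality rates for a disease cohort, stratified by
#' time since cohort entry: `"first_year"` (the select interval, deaths
#' during the first year after entering care), `"survivor"` (the ultimate
#' rates, among those who survived the first year) and/or `"pooled"`
#' (unstratified). Per stratum the age coverage must be contiguous.
#'
#' @param age_start,width as in [age_schedule()]; `width = NA` for the
#'   open-ended group.
#' @param stratum one of `"first_year"`, `"survivor"`, `"pooled"` per row.
#' @param rate mortality rates (deaths per person-year).
#' @param deaths,person_years optional counts.
#' @return A data.frame of class `"rate_table"`.
#' @export
rate_table <- function(age_start, width, stratum, rate,
                       deaths = NA_real_, person_years = NA_real_) {
  rt <- data.frame(age_start = as.numeric(age_start),
                   width = as.numeric(width),
                   stratum = as.character(stratum),
                   rate = as.numeric(rate),
                   deaths = as.numeric(deaths),
                   person_years = as.numeric(person_years),
                   stringsAsFactors = FALSE)
  class(rt) <- c("rate_table", "data.frame")
  validate_rate_table(rt)
  rt
}

validate_rate_table <- function(rt) {
  if (!all(rt$stratum %in% c("first_year", "survivor", "pooled")))
    stop("stratum must be 'first_year', 'survivor' or 'pooled'")
  if (any(rt$rate < 0, na.rm = TRUE)) stop("rates must be >= 0")
  for (st in unique(rt$stratum)) {
    r <- rt[rt$stratum == st, ]
    r <- r[order(r$age_start), ]
    if (nrow(r) > 1L) {
      closed <- !is.na(r$width)
      if (any(!closed[-nrow(r)]))
        stop("open-ended group must be the oldest within stratum '", st, "'")
      ends <- r$age_start[-nrow(r)] + r$width[-nrow(r)]
      if (any(abs(ends - r$age_start[-1L]) > 1e-9))
        stop("age coverage not contiguous within stratum '", st, "'")
    }
  }
  invisible(rt)
}

#' Construct a general-population reference mortality schedule
#'
#' Reference rates serve two purposes: they are the comparator for years of
#' life lost, and they floor extrapolated cohort rates, encoding the
#' assumption that cohort mortality in old age is no lower than in the
#' general population.
#'
#' @param age_start,width,rate as in [age_schedule()]; all rates must be
#'   strictly positive and the last interval open-ended.
#' @param deaths,person_years optional counts.
#' @return A data.frame of class `"reference_schedule"`.
#' @export
reference_schedule <- function(age_start, width, rate,
                               deaths = NA_real_, person_years = NA_real_) {
  if (any(rate <= 0)) stop("reference rates must be > 0")
  s <- age_schedule(age_start, width, rate, deaths, person_years,
                    source = "reference")
  class(s) <- c("reference_schedule", class(s))
  s
}

# pick the reference rate for the group starting at a given age
ref_rate_at <- function(reference, age_start) {
  i <- match(age_start, reference$age_start)
  if (is.na(i)) stop("reference schedule has no group starting at age ", age_start)
  reference$rate[i]
}

# midpoint of each interval; open interval gets a representative age
interval_midpoints <- function(s, open_midpoint_offset = 2.5) {
  ifelse(is.na(s$width), s$age_start + open_midpoint_offset,
         s$age_start + s$width / 2)
}
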