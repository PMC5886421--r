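# Chiang II abridged life table: rate -> probability conversion, the
# standard columns (q, l, d, L, T, e), and the sampling variance of life
# expectancy from deaths counts. The terminal open-ended interval closes
# the table with q = 1 and e = 1/M.

#' Convert an age-interval mortality rate to a probability of death
#'
#' Chiang's conversion for the abridged life table,
#' \deqn{q = \frac{n M}{1 + n (1 - a) M},}
#' where \eqn{n} is the interval width, \eqn{M} the central mortality rate
#' and \eqn{a} the average fraction of the interval lived by those dying in
#' it. In the open-ended terminal interval everyone dies, so `q = 1`.
#'
#' @param rate central mortality rate, deaths per person-year (`>= 0`).
#' @param width interval width in years; `NA` for the open-ended interval.
#' @param a fraction of the interval lived by those who die in it,
#'   in `[0, 1]`; 0.5 is the standard convention.
#' @return Probability of dying within the interval conditional on being
#'   alive at its start, in `[0, 1]`. Vectorised over all arguments.
#' @export
#' @examples
#' chiang_q(0.01, 5)            # 0.05 / 1.025
#' chiang_q(0.2, NA)            # open-ended: 1
chiang_q <- function(rate, width, a = 0.5) {
  if (any(rate < 0, na.rm = TRUE)) stop("rate must be >= 0")
  if (any(a < 0 | a > 1)) stop("a must be in [0, 1]")
  ifelse(is.na(width), 1, width * rate / (1 + width * (1 - a) * rate))
}

#' Build a Chiang II abridged life table
#'
#' Computes the standard life-table columns from an [age_schedule()]:
#' conditional death probabilities `q` (via [chiang_q()]), survivors `l`
#' (starting at `radix`), deaths `d`, person-years lived `L`, cumulative
#' person-years `T`, and remaining life expectancy `e = T / l`. For the
#' open-ended interval `L = l / M`, hence `e = 1 / M` there.
#'
#' Sampling variances follow Chiang: `var(q) = q^2 (1 - q) / D` in closed
#' intervals with `D > 0` deaths, zero where deaths are zero or counts are
#' absent; the open interval contributes `l^2 / (M^2 D)` to the variance of
#' `e`. Intervals whose rate is extrapolated or substituted from a
#' reference schedule are treated as known constants and contribute no
#' variance, so the reported precision reflects only the ages with observed
#' cohort rates.
#'
#' @param schedule an [age_schedule()] (or data.frame with its columns).
#' @param a fraction of interval lived by those dying; default 0.5.
#' @param radix survivors at the first age; default 100000.
#' @return A data.frame of class `"life_table"` with columns `age_start`,
#'   `width`, `M`, `q`, `l`, `d`, `L`, `T`, `e`, `var_q`, `var_e`, `source`,
#'   and attributes `a` and `radix`. `var_e` is the variance of `e` at each
#'   age (zero when no counts are supplied).
#' @references Chiang C.L. (1984) *The Life Table and its Applications*.
#' @export
build_life_table <- function(schedule, a = 0.5, radix = 1e5) {
  s <- as.data.frame(schedule)
  class(s) <- c("age_schedule", "data.frame")
  validate_schedule(s)
  if (length(a) != 1 || a < 0 || a > 1) stop("a must be a single value in [0, 1]")
  k <- nrow(s)
  open <- is.na(s$width)
  if (s$rate[k] <= 0)
    stop("open-ended interval must have rate > 0 (e = 1/M is undefined)")

  q <- chiang_q(s$rate, s$width, a)
  l <- radix * cumprod(c(1, 1 - q[-k]))
  d <- l * q
  L <- ifelse(open, l / s$rate, s$width * (l - (1 - a) * d))
  Tx <- rev(cumsum(rev(L)))
  e <- Tx / l

  # Chiang sampling variance; only intervals with observed counts contribute
  observed <- s$source == "observed" & !is.na(s$deaths) & s$deaths > 0
  var_q <- ifelse(observed & !open, q^2 * (1 - q) / s$deaths, 0)
  term <- numeric(k)
  term[!open] <- l[!open]^2 *
    ((1 - a) * s$width[!open] + c(e[-1], 0)[!open])^2 * var_q[!open]
  term[k] <- if (observed[k]) l[k]^2 / (s$rate[k]^2 * s$deaths[k]) else 0
  var_e <- rev(cumsum(rev(term))) / l^2

  lt <- data.frame(age_start = s$age_start, width = s$width, M = s$rate,
                   q = q, l = l, d = d, L = L, T = Tx, e = e,
                   var_q = var_q, var_e = var_e, source = s$source,
                   stringsAsFactors = FALSE)
  attr(lt, "a") <- a
  attr(lt, "radix") <- radix
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' Life expectancy with its 95% confidence interval
#'
#' Builds the life table and reports remaining life expectancy at the
#' schedule's first age, its standard error from the Chiang variance, and
#' the half-width of the 95% confidence interval (the "error bar"). Rates
#' without deaths counts carry no sampling information, so `se = 0` then.
#'
#' @inheritParams build_life_table
#' @param le_reference optional reference-population life expectancy at the
#'   same age; when given, years of life lost is included in the result.
#' @return A list of class `"le_result"`: `le`, `se`, `ci95_halfwidth`
#'   (`= 1.96 * se`), `age`, and `yll` (when `le_reference` is supplied).
#' @export
le_with_ci <- function(schedule, a = 0.5, radix = 1e5, le_reference = NULL) {
  lt <- build_life_table(schedule, a = a, radix = radix)
  le <- lt$e[1L]
  se <- sqrt(lt$var_e[1L])
  res <- list(le = le, se = se, ci95_halfwidth = 1.96 * se,
              age = lt$age_start[1L],
              yll = if (!is.null(le_reference)) yll(le, le_reference) else NULL)
  class(res) <- "le_result"
  res
}

#' @export
print.le_result <- function(x, ...) {
  cat(sprintf("LE at age %g: %.1f years (95%% CI +/- %.2f)\n",
              x$age, x$le, x$ci95_halfwidth))
  if (!is.null(x$yll)) cat(sprintf("YLL vs reference: %.1f years\n", x$yll))
  invisible(x)
}

#' Years of life lost
#'
#' The gap between the reference population's life expectancy and the
#' cohort's at the same age. Negative when the cohort estimate exceeds the
#' reference (as happens with a biased open-ended group at too young an
#' age).
#'
#' @param le_cohort cohort life expectancy in years (`>= 0`).
#' @param le_reference reference-population life expectancy in years.
#' @return `le_reference - le_cohort`, in years.
#' @export
#' @examples
#' yll(47.5, 62.2)  # 14.7
yll <- function(le_cohort, le_reference) {
  if (any(le_cohort < 0) || any(le_reference < 0))
    stop("life expectancies must be >= 0")
  le_reference - le_cohort
}

#' Assemble the stratified mortality schedule for a given entry age
#'
#' Encodes the select-and-ultimate structure of cohort mortality: the first
#' year after entering care is its own interval at the entry age group's
#' first-year rate, followed by the remainder of that 5-year group and all
#' older groups at survivor rates, with rates beyond the observed ages
#' completed by [extrapolate_schedule()] and floored at the reference.
#'
#' For `entry_age = 20` with 5-year groups this yields intervals
#' `[20,21)` (first-year), `[21,25)` (survivor), `[25,30)` (survivor), ...;
#' a zero-width remainder (e.g. `entry_age = 24`) is dropped. With
#' `survivor_only = TRUE` the one-year split is skipped and the schedule
#' starts at `entry_age` on survivor rates (life expectancy conditional on
#' having survived the first year of care). A `rates` table carrying only
#' the `"pooled"` stratum yields the unstratified schedule.
#'
#' @param entry_age age (integer years) at cohort entry; must fall within
#'   the rate table's age coverage.
#' @param rates a [rate_table()] with `first_year` and `survivor` strata
#'   (or `pooled` for the unstratified calculation).
#' @param reference a [reference_schedule()] covering all ages through the
#'   open-ended group.
#' @param extrapolation an [extrapolation_config()]; use
#'   `extrapolation_config("none")` when the rate table itself covers all
#'   ages.
#' @param survivor_only skip the first-year interval (condition on
#'   surviving the first year of care).
#' @return An [age_schedule()] ready for [build_life_table()].
#' @export
stratified_schedule <- function(entry_age, rates, reference,
                                extrapolation = extrapolation_config("none"),
                                survivor_only = FALSE) {
  validate_rate_table(rates)
  strata <- unique(rates$stratum)
  pooled <- identical(strata, "pooled")
  ult_stratum <- if (pooled) "pooled" else "survivor"
  if (!pooled && !all(c("first_year", "survivor") %in% strata) && !survivor_only)
    stop("rate table must carry both 'first_year' and 'survivor' strata ",
         "(or 'pooled' alone for the unstratified schedule)")

  ult <- rates[rates$stratum == ult_stratum, ]
  ult <- ult[order(ult$age_start), ]
  if (entry_age < min(ult$age_start))
    stop("entry_age ", entry_age, " is below the youngest covered age group")
  if (entry_age >= max(ult$age_start) + ifelse(is.na(ult$width[nrow(ult)]), 1,
                                               ult$width[nrow(ult)]) &&
      !is.na(ult$width[nrow(ult)]))
    stop("entry_age beyond rate-table coverage")

  completed <- extrapolate_schedule(ult, reference, extrapolation)

  # group containing the entry age
  gi <- findInterval(entry_age, completed$age_start)
  g <- completed[gi, ]

  ult_rows <- function(rows) {
    age_schedule(rows$age_start, rows$width, rows$rate,
                 rows$deaths, rows$person_years, rows$source)
  }

  if (pooled || survivor_only) {
    later <- completed[completed$age_start > entry_age, ]
    if (g$age_start < entry_age) {
      # split the entry group so the table starts exactly at entry_age
      head_int <- data.frame(age_start = entry_age,
                             width = g$age_start + g$width - entry_age,
                             rate = g$rate, deaths = NA_real_,
                             person_years = NA_real_, source = g$source)
      return(ult_rows(rbind(head_int, later[, names(head_int)])))
    }
    return(ult_rows(completed[completed$age_start >= entry_age,
                              c("age_start", "width", "rate", "deaths",
                                "person_years", "source")]))
  }

  fy_rate <- first_year_rate(entry_age, rates, completed, extrapolation)
  first <- data.frame(age_start = entry_age, width = 1,
                      rate = fy_rate$rate, deaths = fy_rate$deaths,
                      person_years = fy_rate$person_years,
                      source = fy_rate$source)
  rows <- first
  rem_width <- g$age_start + ifelse(is.na(g$width), Inf, g$width) -
    (entry_age + 1)
  if (is.finite(rem_width) && rem_width > 1e-9) {
    rows <- rbind(rows, data.frame(age_start = entry_age + 1,
                                   width = rem_width, rate = g$rate,
                                   deaths = g$deaths,
                                   person_years = g$person_years,
                                   source = g$source))
  }
  later <- completed[completed$age_start > g$age_start,
                     c("age_start", "width", "rate", "deaths",
                       "person_years", "source")]
  ult_rows(rbind(rows, later))
}

# first-year rate for the entry group: observed when the table has it;
# beyond the observed first-year ages, survivor (possibly extrapolated)
# rate scaled by the oldest observed first-year/survivor rate ratio
first_year_rate <- function(entry_age, rates, completed, extrapolation) {
  fy <- rates[rates$stratum == "first_year", ]
  fy <- fy[order(fy$age_start), ]
  if (nrow(fy) == 0L) stop("rate table has no 'first_year' stratum")
  gi <- findInterval(entry_age, fy$age_start)
  in_cov <- gi >= 1L &&
    (is.na(fy$width[gi]) || entry_age < fy$age_start[gi] + fy$width[gi])
  use_observed <- in_cov &&
    (extrapolation$method == "none" || fy$age_start[gi] < extrapolation$start_age)
  if (use_observed) {
    return(list(rate = fy$rate[gi], deaths = fy$deaths[gi],
                person_years = fy$person_years[gi], source = "observed"))
  }
  sv <- rates[rates$stratum == "survivor", ]
  last <- fy[nrow(fy), ]
  sv_match <- sv$rate[match(last$age_start, sv$age_start)]
  if (is.na(sv_match) || sv_match <= 0)
    stop("cannot form a first-year/survivor rate ratio for extrapolation")
  ci <- findInterval(entry_age, completed$age_start)
  list(rate = completed$rate[ci] * last$rate / sv_match,
       deaths = NA_real_, person_years = NA_real_, source = "extrapolated")
}

#' Average life expectancy over an entry-age distribution
#'
#' Few members of a disease cohort enter care at the youngest tabulated
#' age, so a single-entry-age LE can misrepresent the cohort burden. This
#' weights the stratified LE at each entry age by the distribution of ages
#' at cohort entry.
#'
#' @inheritParams stratified_schedule
#' @param entry_age_distribution a data.frame with columns `age` and
#'   `weight` (counts or probabilities; non-negative, not all zero).
#' @param a,radix passed to [build_life_table()].
#' @return Weighted mean life expectancy in years.
#' @export
average_le <- function(rates, reference, extrapolation,
                       entry_age_distribution, a = 0.5, radix = 1e5,
                       survivor_only = FALSE) {
  d <- entry_age_distribution
  if (is.null(d) || nrow(d) == 0L) stop("entry-age distribution is empty")
  if (any(d$weight < 0) || sum(d$weight) <= 0)
    stop("weights must be >= 0 and not all zero")
  les <- vapply(d$age, function(age) {
    sched <- stratified_schedule(age, rates, reference, extrapolation,
                                 survivor_only = survivor_only)
    build_life_table(sched, a = a, radix = radix)$e[1L]
  }, numeric(1))
  sum(les * d$weight) / sum(d$weight)
}
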