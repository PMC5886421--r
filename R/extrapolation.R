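# Completion of a cohort mortality schedule beyond the oldest reliable
# age group: Gompertz log-linear projection, constant rate ratio, or
# constant rate difference relative to a reference schedule, always
# floored at the reference rates.

#' Configure old-age mortality extrapolation
#'
#' @param method `"gompertz"` (project the log-linear age trend of the
#'   observed rates), `"rate_ratio"` (`param` times the reference rate),
#'   `"rate_difference"` (reference rate plus `param` deaths/person-year),
#'   or `"none"` (the rate table must already cover all ages). Whatever the
#'   method, extrapolated rates are never allowed below the reference
#'   rates.
#' @param start_age first age (a group boundary) whose rate is replaced by
#'   extrapolation. `start_age = 90` adjusts only the open-ended group
#'   while keeping observed rates through 85-89; `start_age = 60` is the
#'   choice forced when rates above 60 are unavailable.
#' @param param rate ratio (dimensionless, `> 0`) or rate difference
#'   (deaths per person-year, `>= 0`); ignored for `"gompertz"`.
#' @param fit_ages ages `[min, max]` whose groups feed the Gompertz fit
#'   (default 30-59, where cohort rates are typically well estimated).
#' @param open_midpoint_offset representative age of the open-ended group
#'   for Gompertz projection, as an offset from its starting age
#'   (default 2.5, continuing the midpoint convention: 90+ projects
#'   at 92.5).
#' @param weighted use deaths-weighted least squares in the Gompertz fit
#'   (default unweighted).
#' @return A list of class `"extrapolation_config"`.
#' @export
extrapolation_config <- function(method = c("gompertz", "rate_ratio",
                                            "rate_difference", "none"),
                                 start_age = 90, param = NULL,
                                 fit_ages = c(30, 59),
                                 open_midpoint_offset = 2.5,
                                 weighted = FALSE) {
  method <- match.arg(method)
  if (method == "rate_ratio" && (is.null(param) || param <= 0))
    stop("rate_ratio extrapolation needs param > 0")
  if (method == "rate_difference" && (is.null(param) || param < 0))
    stop("rate_difference extrapolation needs param >= 0")
  structure(list(method = method, start_age = start_age,
                 param = param, fit_ages = fit_ages,
                 open_midpoint_offset = open_midpoint_offset,
                 weighted = weighted),
            class = "extrapolation_config")
}

#' Fit Gompertz's law to age-group mortality rates
#'
#' Gompertz's law holds that the force of mortality grows exponentially
#' with age, i.e. log rate is linear in age. The fit is ordinary least
#' squares of `log(rate)` on the age-group midpoint (`age_start +
#' width/2`), optionally weighted by deaths counts. Zero rates cannot be
#' log-transformed and are dropped with a warning.
#'
#' @param rates rows of a [rate_table()] or [age_schedule()] for a single
#'   stratum.
#' @param fit_ages ages `[min, max]`; groups lying entirely within
#'   `[min, max + 1)` enter the fit.
#' @param weighted if `TRUE`, weight by `deaths` (rows lacking counts then
#'   get weight 0).
#' @return A list of class `"gompertz_fit"`: `intercept` (log rate at age
#'   0), `slope` (per-year increase in log rate), `fit_ages`, `n_points`,
#'   `residual_sd`, and `predict(age)` via [predict.gompertz_fit()].
#' @export
fit_gompertz <- function(rates, fit_ages = c(30, 59), weighted = FALSE) {
  r <- as.data.frame(rates)
  closed <- !is.na(r$width)
  keep <- closed & r$age_start >= fit_ages[1] &
    (r$age_start + r$width) <= fit_ages[2] + 1
  r <- r[keep, ]
  if (any(r$rate == 0)) {
    warning("dropping ", sum(r$rate == 0), " zero-rate group(s) from Gompertz fit")
    r <- r[r$rate > 0, ]
  }
  if (nrow(r) < 2L)
    stop("need at least 2 positive-rate age groups within fit_ages")
  mid <- r$age_start + r$width / 2
  w <- if (weighted) ifelse(is.na(r$deaths), 0, r$deaths) else NULL
  fit <- stats::lm(log(r$rate) ~ mid, weights = w)
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 fit_ages = fit_ages, n_points = nrow(r),
                 residual_sd = suppressWarnings(summary(fit)$sigma)),
            class = "gompertz_fit")
}

#' Predicted mortality rate from a Gompertz fit
#'
#' @param object a [fit_gompertz()] result.
#' @param age age(s) in years at which to evaluate the fitted rate.
#' @param ... unused.
#' @return Predicted rate(s), deaths per person-year.
#' @export
predict.gompertz_fit <- function(object, age, ...) {
  exp(object$intercept + object$slope * age)
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat(sprintf(
    "Gompertz fit over ages %g-%g (%d groups): log(rate) = %.4f + %.5f * age; residual SD %.3f\n",
    x$fit_ages[1], x$fit_ages[2], x$n_points, x$intercept, x$slope,
    x$residual_sd))
  invisible(x)
}

#' Complete a cohort mortality schedule to the oldest ages
#'
#' Replaces every rate at or above `config$start_age` with the configured
#' extrapolation, then floors each extrapolated rate at the reference
#' rate for the same group — encoding the assumption that cohort mortality
#' at old ages is at least that of the general population. Replaced rows
#' are flagged `source = "extrapolated"`; their deaths/person-years are
#' cleared so they carry no weight in variance calculations.
#'
#' The output age layout above `start_age` is taken from the reference
#' schedule, so an observed table truncated below the open-ended group is
#' extended to the reference's full coverage.
#'
#' @param observed one stratum's rows of a [rate_table()] (columns
#'   `age_start`, `width`, `rate`, optionally `deaths`, `person_years`).
#' @param reference a [reference_schedule()] covering all groups through
#'   the open-ended one.
#' @param config an [extrapolation_config()].
#' @return A data.frame shaped like an [age_schedule()] (contiguous,
#'   open-ended last) with a `source` column.
#' @export
extrapolate_schedule <- function(observed, reference, config) {
  obs <- as.data.frame(observed)
  obs <- obs[order(obs$age_start), ]
  for (col in c("deaths", "person_years"))
    if (is.null(obs[[col]])) obs[[col]] <- NA_real_
  if (is.null(obs$source)) obs$source <- "observed"
  if (is.na(reference$width[nrow(reference)]))
    open_ref <- reference[nrow(reference), ]
  else stop("reference schedule must end with an open-ended group")

  if (config$method == "none") {
    keep <- obs[, c("age_start", "width", "rate", "deaths", "person_years",
                    "source")]
    if (!any(is.na(keep$width)))
      stop("method 'none' requires the observed table to include the open-ended group")
    return(keep)
  }

  start <- config$start_age
  keep <- obs[obs$age_start < start & !is.na(obs$width) &
                obs$age_start + obs$width <= start, ]
  if (nrow(keep) == 0L) stop("no observed groups below start_age ", start)
  if (max(keep$age_start + keep$width) < start)
    stop("observed rates do not reach start_age ", start)
  tail_ref <- reference[reference$age_start >= start, ]
  if (nrow(tail_ref) == 0L)
    stop("reference schedule has no groups at or above start_age ", start)
  if (!is.na(tail_ref$width[nrow(tail_ref)]))
    stop("reference schedule does not cover the open-ended group above start_age")

  raw <- switch(config$method,
    gompertz = {
      fit <- fit_gompertz(obs, fit_ages = config$fit_ages,
                          weighted = config$weighted)
      mids <- ifelse(is.na(tail_ref$width),
                     tail_ref$age_start + config$open_midpoint_offset,
                     tail_ref$age_start + tail_ref$width / 2)
      predict(fit, mids)
    },
    rate_ratio = config$param * tail_ref$rate,
    rate_difference = tail_ref$rate + config$param)
  extrap <- data.frame(age_start = tail_ref$age_start,
                       width = tail_ref$width,
                       rate = pmax(raw, tail_ref$rate),
                       deaths = NA_real_, person_years = NA_real_,
                       source = "extrapolated",
                       stringsAsFactors = FALSE)
  out <- rbind(keep[, names(extrap)], extrap)
  rownames(out) <- NULL
  out
}
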