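# Annual-trend summaries: average annual percent change from a
# quasi-Poisson log-linear model, and simple between-period change.

#' Average annual percent change (AAPC) by quasi-Poisson regression
#'
#' Fits a log-link count regression of annual events on calendar year with
#' a log exposure offset, `log E[deaths] = a + b * year + log(exposure)`,
#' with quasi-Poisson dispersion (Pearson chi-square / df) inflating the
#' slope's standard error. The AAPC is `100 * (exp(b) - 1)` and its CI is
#' the slope CI transformed the same way; overdispersion widens the CI but
#' leaves the point estimate at the Poisson value. Years are centred
#' before fitting (the result is invariant to centring).
#'
#' @param counts annual event counts (`>= 0`, not all zero).
#' @param offsets annual exposures (`> 0`), e.g. the number in care.
#' @param years calendar years (length `>= 3`).
#' @return A list of class `"trend_result"`: `aapc` (percent/year), `ci95`
#'   (length-2), `slope` (log scale), `se_slope`, `dispersion`.
#' @export
#' @examples
#' aapc(c(100, 90, 81, 73), c(1000, 1000, 1000, 1000), 2000:2003)
aapc <- function(counts, offsets, years) {
  if (length(years) < 3L) stop("need at least 3 years")
  if (length(counts) != length(years) || length(offsets) != length(years))
    stop("counts, offsets and years must have equal length")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (all(counts == 0)) stop("all counts are zero; no trend to estimate")
  if (any(offsets <= 0)) stop("offsets must be > 0")
  yr <- years - mean(years)
  fit <- stats::glm(counts ~ yr + offset(log(offsets)),
                    family = stats::quasipoisson(link = "log"),
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)["yr"])
  se <- sm$coefficients["yr", "Std. Error"]
  structure(list(aapc = 100 * (exp(slope) - 1),
                 ci95 = 100 * (exp(slope + c(-1.96, 1.96) * se) - 1),
                 slope = slope, se_slope = se,
                 dispersion = sm$dispersion),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("AAPC: %.1f%%/yr (95%% CI %.1f, %.1f); dispersion %.2f\n",
              x$aapc, x$ci95[1], x$ci95[2], x$dispersion))
  invisible(x)
}

#' Percent change between two period counts
#'
#' @param count_a baseline-period count (`> 0`).
#' @param count_b comparison-period count.
#' @param digits decimals for display rounding (default 0, as such tables
#'   are conventionally printed in whole percent).
#' @return `100 * (count_b - count_a) / count_a`, rounded to `digits`.
#' @export
#' @examples
#' period_change(3214, 2825)  # -12
period_change <- function(count_a, count_b, digits = 0) {
  if (any(count_a <= 0)) stop("baseline count must be > 0")
  round(100 * (count_b - count_a) / count_a, digits)
}
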