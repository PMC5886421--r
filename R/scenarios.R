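# End-to-end scenario runner: named extrapolation presets (the standard
# sensitivity grid for old-age completion of a cohort schedule), the
# reference-population benchmark, and the biased 55+ open-ended variant
# kept as a cautionary comparison.

#' Named extrapolation presets for the sensitivity grid
#'
#' The conventional sensitivity analysis for completing a cohort
#' mortality schedule: Gompertz projection, rate ratios of 2 and 3, and
#' rate differences of 0.013, 0.02 and 0.03 deaths/person-year, each
#' starting either at age 60 (when observed rates end at 59) or at age 90
#' (adjusting only the open-ended group while keeping observed rates
#' through 85-89), plus `"reference"` (the general-population benchmark).
#'
#' @return A named list of [extrapolation_config()] objects (with
#'   `"reference"` as a marker entry).
#' @export
scenario_presets <- function() {
  p <- list(
    reference = "reference",
    gompertz_start60 = extrapolation_config("gompertz", 60),
    gompertz_start90 = extrapolation_config("gompertz", 90),
    rate_ratio_2.0_start60 = extrapolation_config("rate_ratio", 60, 2),
    rate_ratio_2.0_start90 = extrapolation_config("rate_ratio", 90, 2),
    rate_ratio_3.0_start60 = extrapolation_config("rate_ratio", 60, 3),
    rate_difference_0.013_start60 =
      extrapolation_config("rate_difference", 60, 0.013),
    rate_difference_0.02_start60 =
      extrapolation_config("rate_difference", 60, 0.02),
    rate_difference_0.03_start60 =
      extrapolation_config("rate_difference", 60, 0.03))
  p
}

#' Run one life-expectancy scenario end to end
#'
#' Loads nothing itself: takes a rate table and reference schedule already
#' in memory (see [read_rate_table()] / [read_reference_schedule()] or the
#' bundled accessors), completes the schedule per the preset, builds the
#' Chiang II life table, and reports LE with its confidence interval and
#' years of life lost against the reference population at the same age.
#'
#' @param preset a preset name from [scenario_presets()], an
#'   [extrapolation_config()], or `"reference"` for the
#'   general-population benchmark.
#' @param rates a [rate_table()]; ignored for `"reference"`.
#' @param reference a [reference_schedule()].
#' @param entry_age age at cohort entry (default 20).
#' @param survivor_only condition on surviving the first year of care
#'   (skips the one-year select interval).
#' @param pooled use the `"pooled"` stratum of `rates` (unstratified
#'   calculation).
#' @param a,radix life-table conventions, see [build_life_table()].
#' @return A list of class `"scenario_result"`: `le` (an `le_result` with
#'   `yll`), `life_table`, `schedule`, `le_reference`, `preset_name`.
#' @export
run_scenario <- function(preset, rates = NULL, reference,
                         entry_age = 20, survivor_only = FALSE,
                         pooled = FALSE, a = 0.5, radix = 1e5) {
  name <- if (is.character(preset)) preset else "custom"
  if (is.character(preset) && preset != "reference") {
    all <- scenario_presets()
    if (!preset %in% names(all)) stop("unknown preset '", preset, "'")
    preset <- all[[preset]]
  }

  ref_sched <- trim_reference(reference, entry_age)
  le_ref <- build_life_table(ref_sched, a = a, radix = radix)$e[1L]

  if (identical(preset, "reference")) {
    le <- le_with_ci(ref_sched, a = a, radix = radix, le_reference = le_ref)
    lt <- build_life_table(ref_sched, a = a, radix = radix)
    out <- list(le = le, life_table = lt, schedule = ref_sched,
                le_reference = le_ref, preset_name = "reference")
    class(out) <- "scenario_result"
    return(out)
  }

  if (is.null(rates)) stop("cohort scenarios need a rate table")
  use <- if (pooled) {
    pr <- rates[rates$stratum == "pooled", ]
    if (nrow(pr) == 0L) stop("rate table has no 'pooled' stratum")
    pr
  } else rates
  sched <- stratified_schedule(entry_age, use, reference, preset,
                               survivor_only = survivor_only)
  le <- le_with_ci(sched, a = a, radix = radix, le_reference = le_ref)
  lt <- build_life_table(sched, a = a, radix = radix)
  out <- list(le = le, life_table = lt, schedule = sched,
              le_reference = le_ref, preset_name = name)
  class(out) <- "scenario_result"
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("scenario '%s' at entry age %g\n", x$preset_name, x$le$age))
  print(x$le)
  cat(sprintf("reference LE at same age: %.1f years\n", x$le_reference))
  invisible(x)
}

# reference schedule starting exactly at entry_age (splitting the
# containing group if entry_age is interior to it)
trim_reference <- function(reference, entry_age) {
  r <- as.data.frame(reference)
  gi <- findInterval(entry_age, r$age_start)
  if (gi < 1L) stop("entry_age below reference coverage")
  later <- r[r$age_start > entry_age, ]
  g <- r[gi, ]
  if (g$age_start == entry_age) {
    rows <- r[r$age_start >= entry_age, ]
  } else {
    head_int <- g
    head_int$age_start <- entry_age
    head_int$width <- if (is.na(g$width)) NA_real_ else
      g$age_start + g$width - entry_age
    head_int$deaths <- NA_real_
    head_int$person_years <- NA_real_
    rows <- rbind(head_int, later)
  }
  age_schedule(rows$age_start, rows$width, rows$rate, rows$deaths,
               rows$person_years, source = "reference")
}

#' Life expectancy with a 55+ open-ended age group (biased variant)
#'
#' The shortcut of collapsing all ages 55 and over into the open-ended
#' group — common when cohort rates above 55 are unavailable — overstates
#' LE whenever the cohort's age distribution within 55+ is younger than
#' the general population's, because the single pooled 55+ rate then
#' understates mortality at the ages the table attributes to it. This
#' function computes that biased estimate so the bias can be demonstrated
#' against the properly extrapolated table.
#'
#' @param rates a [rate_table()] whose `pooled` stratum includes a single
#'   open-ended row starting at 55 (`width = NA`); younger groups may be
#'   stratified as usual.
#' @param reference a [reference_schedule()].
#' @param entry_age,survivor_only,a,radix as in [run_scenario()].
#' @return A `scenario_result` (see [run_scenario()]).
#' @export
open_55_variant <- function(rates, reference, entry_age = 20,
                            survivor_only = FALSE, a = 0.5, radix = 1e5) {
  open_row <- rates[rates$stratum == "pooled" & rates$age_start == 55 &
                      is.na(rates$width), ]
  if (nrow(open_row) != 1L)
    stop("rate table must supply exactly one pooled open-ended 55+ row")
  stratified <- any(rates$stratum == "survivor")
  ult_stratum <- if (stratified) "survivor" else "pooled"
  out_stratum <- if (stratified || survivor_only) "survivor" else "pooled"
  below <- rates[rates$stratum == ult_stratum & !is.na(rates$width) &
                   rates$age_start + rates$width <= 55, ]
  crafted <- rbind(
    rates[rates$stratum == "first_year" & rates$age_start < 55, ],
    transform(below, stratum = out_stratum),
    transform(open_row, stratum = out_stratum))
  crafted <- rate_table(crafted$age_start, crafted$width, crafted$stratum,
                        crafted$rate, crafted$deaths, crafted$person_years)
  sched <- stratified_schedule(entry_age, crafted, reference,
                               extrapolation_config("none"),
                               survivor_only = survivor_only)
  ref_sched <- trim_reference(reference, entry_age)
  le_ref <- build_life_table(ref_sched, a = a, radix = radix)$e[1L]
  le <- le_with_ci(sched, a = a, radix = radix, le_reference = le_ref)
  out <- list(le = le, life_table = build_life_table(sched, a, radix),
              schedule = sched, le_reference = le_ref,
              preset_name = "open_55")
  class(out) <- "scenario_result"
  out
}
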