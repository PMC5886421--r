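# Delimited-text readers and writers for rate tables, reference
# schedules, life tables and person records, plus accessors for the
# bundled Ontario HIV cohort example data. Open-ended intervals are
# encoded as width = -1 in files and width = NA in memory.

width_to_file <- function(w) ifelse(is.na(w), -1, w)
width_from_file <- function(w) ifelse(w < 0, NA_real_, w)

#' Read a stratified cohort rate table from delimited text
#'
#' Expected header: `age_start,width,stratum,rate` with optional `deaths`
#' and `person_years` columns; `width = -1` encodes the open-ended group.
#'
#' @param path file path.
#' @return A [rate_table()].
#' @export
read_rate_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_start", "width", "stratum", "rate")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("rate table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  rate_table(d$age_start, width_from_file(d$width), d$stratum, d$rate,
             if (is.null(d$deaths)) NA_real_ else d$deaths,
             if (is.null(d$person_years)) NA_real_ else d$person_years)
}

#' Write a rate table (or completed schedule) to delimited text
#'
#' @param x a [rate_table()], [age_schedule()] or compatible data.frame.
#' @param path file path.
#' @export
write_rate_table <- function(x, path) {
  d <- as.data.frame(x)
  d$width <- width_to_file(d$width)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference-population mortality schedule
#'
#' Expected header: `age_start,width,rate` (optional `deaths`,
#' `person_years`); `width = -1` encodes the open-ended group, which must
#' be present.
#'
#' @param path file path.
#' @return A [reference_schedule()].
#' @export
read_reference_schedule <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_start", "width", "rate")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("reference schedule ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  reference_schedule(d$age_start, width_from_file(d$width), d$rate,
                     if (is.null(d$deaths)) NA_real_ else d$deaths,
                     if (is.null(d$person_years)) NA_real_ else d$person_years)
}

#' Write a life table with the full Chiang column set
#'
#' @param lt a [build_life_table()] result.
#' @param path file path.
#' @export
write_life_table <- function(lt, path) {
  d <- as.data.frame(lt)
  d$width <- width_to_file(d$width)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read person-level cohort records
#'
#' Expected header: `id,birth_date,birth_cohort,entry_date,death_date,
#' eligibility_end,last_contact` (ISO-8601 dates; empty fields for
#' missing); any of `birth_date`/`birth_cohort` may be omitted if the
#' other is present. An optional long-format visits file with header
#' `id,visit_date` supplies visit dates from which the entry date is
#' derived by [find_entry_date()] for records lacking `entry_date`.
#'
#' @param path person records file.
#' @param visits_path optional visits file.
#' @return A data.frame of person records (dates as `Date`), ready for
#'   [resolve_records()].
#' @export
read_person_records <- function(path, visits_path = NULL) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  if (is.null(p$id)) stop("person records need an 'id' column")
  for (col in c("birth_date", "entry_date", "death_date",
                "eligibility_end", "last_contact"))
    if (!is.null(p[[col]])) p[[col]] <- as.Date(ifelse(p[[col]] == "",
                                                       NA, p[[col]]))
  if (!is.null(visits_path)) {
    v <- utils::read.csv(visits_path, stringsAsFactors = FALSE)
    v$visit_date <- as.Date(v$visit_date)
    v <- v[order(v$id, v$visit_date), ]
    entries <- vapply(split(v$visit_date, v$id),
                      function(d) as.numeric(find_entry_date(d)), numeric(1))
    if (is.null(p$entry_date)) p$entry_date <- as.Date(NA)
    hit <- match(p$id, names(entries))
    fill <- is.na(p$entry_date) & !is.na(hit)
    p$entry_date[fill] <- as.Date(entries[hit[fill]], origin = "1970-01-01")
  }
  p
}

#' Write person-level cohort records
#'
#' @param persons data.frame as produced by [simulate_cohort()].
#' @param path file path.
#' @export
write_person_records <- function(persons, path) {
  utils::write.csv(persons, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "stratalife",
                      mustWork = FALSE)
  if (!nzchar(path)) stop("bundled data file not found: ", file)
  path
}

#' Bundled example data: Ontario HIV cohort mortality rates, 2005-2012
#'
#' All-cause mortality rates for adults in care for HIV in Ontario over
#' 2005-2012, by 5-year age group (20-24 through 85-89 plus open-ended
#' 90+) and time since entering care (`first_year` vs `survivor`
#' strata).
#'
#' @return A [rate_table()].
#' @export
hiv_rates_ontario <- function() read_rate_table(extdata("hiv_rates_ontario_2005_2012.csv"))

#' Bundled example data: Ontario general-population mortality schedule
#'
#' Ontario all-cause mortality rates by 5-year age group (20-24 through
#' 85-89 plus open-ended 90+), the reference schedule paired with
#' [hiv_rates_ontario()].
#'
#' @return A [reference_schedule()].
#' @export
ontario_reference <- function() read_reference_schedule(extdata("ontario_reference_rates.csv"))

#' Bundled example data: Ontario HIV cohort annual series, 1994-2012
#'
#' Annual counts of new entries to HIV care, all-cause deaths, losses to
#' follow-up, and persons in care at year end, for the Ontario HIV
#' cohort.
#'
#' @return A data.frame with columns `year`, `new_cases`, `deaths`,
#'   `ltf`, `in_care`.
#' @export
hiv_annual_ontario <- function() utils::read.csv(extdata("hiv_annual_ontario_1994_2012.csv"))
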