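# Calendar arithmetic helpers. Age computations use calendar-year addition;
# a Feb-29 birth maps to Mar-1 in non-leap target years so that "the nth
# birthday" is always a well-defined date.

is_leap_year <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

#' Add whole calendar years to a date
#'
#' Feb-29 anniversaries fall on Mar-1 in non-leap target years.
#'
#' @param date a `Date` vector.
#' @param n integer number of years (scalar).
#' @return a `Date` vector.
#' @export
add_years <- function(date, n) {
  date <- as.Date(date)
  lt <- as.POSIXlt(date)
  y <- lt$year + 1900L + as.integer(n)
  m <- lt$mon + 1L
  d <- lt$mday
  leapless <- m == 2L & d == 29L & !is_leap_year(y)
  out <- ifelse(leapless,
                sprintf("%04d-03-01", y),
                sprintf("%04d-%02d-%02d", y, m, d))
  out[is.na(date)] <- NA
  as.Date(out)
}

#' End of a child's follow-up window
#'
#' Follow-up runs from birth to the earliest of the sixth birthday, death,
#' disenrollment, and the administrative end of the study. Optional dates
#' that are absent (`NA`) simply drop out of the minimum. Encounter inclusion
#' treats the sixth-birthday bound as exclusive ("the first six years of
#' life") and the other bounds as inclusive; see [assemble_histories()].
#'
#' @param birth_date `Date` vector.
#' @param death_date,disenrollment_date `Date` vectors (or `NULL`); `NA`
#'   where not applicable. Must be on/after `birth_date` where present.
#' @param study_end `Date` scalar or vector, the administrative censoring
#'   date; must be on/after `birth_date`.
#' @return `Date` vector of follow-up end dates, never after the sixth
#'   birthday.
#' @examples
#' follow_up_end(as.Date("2010-02-10"), study_end = as.Date("2020-12-31"))
#' @export
follow_up_end <- function(birth_date, death_date = NULL,
                          disenrollment_date = NULL, study_end) {
  birth_date <- as.Date(birth_date)
  n <- length(birth_date)
  coerce_opt <- function(x) {
    if (is.null(x)) return(as.Date(rep(NA_character_, n)))
    x <- as.Date(x)
    if (length(x) == 1L) x <- rep(x, n)
    x
  }
  death_date <- coerce_opt(death_date)
  disenrollment_date <- coerce_opt(disenrollment_date)
  study_end <- as.Date(study_end)
  if (length(study_end) == 1L) study_end <- rep(study_end, n)
  stopifnot(length(death_date) == n, length(disenrollment_date) == n,
            length(study_end) == n)
  bad <- (!is.na(death_date) & death_date < birth_date) |
    (!is.na(disenrollment_date) & disenrollment_date < birth_date)
  if (any(bad, na.rm = TRUE)) {
    stop("death/disenrollment date before birth date at position(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  if (any(study_end < birth_date, na.rm = TRUE)) {
    stop("study_end precedes birth_date", call. = FALSE)
  }
  sixth <- add_years(birth_date, 6L)
  pmin(sixth, death_date, disenrollment_date, study_end, na.rm = TRUE)
}

# Parse a character column of ISO dates, reporting offending rows by line
# number (header is line 1, so data row i is line i + 1).
parse_date_column <- function(x, column, allow_na = FALSE) {
  x <- trimws(as.character(x))
  x[!nzchar(x)] <- NA_character_
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- is.na(out) & !is.na(x)
  if (!allow_na) bad <- bad | is.na(x)
  if (any(bad)) {
    stop(sprintf("unparseable %s at line(s) %s (expected YYYY-MM-DD)",
                 column, paste(which(bad) + 1L, collapse = ", ")),
         call. = FALSE)
  }
  out
}
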