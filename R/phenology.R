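#' Crop phenology calendar
#'
#' A calendar maps calendar dates to phenological stages via days after
#' transplant (DAT). The default reproduces the tomato cycle used throughout
#' the package: vegetative 0--50 DAT, reproductive 51--109 DAT, harvest
#' 110--190 DAT, transplanted 2024-03-14. Stage durations are taken as the
#' difference between consecutive stage end-DATs (50, 59 and 81 calendar
#' days), which sums to the 190-day cycle.
#'
#' @param transplant_date `Date` (or string coercible) of transplanting.
#' @param stage_ends named integer vector of stage end-DATs in cycle order;
#'   names are the stage labels.
#' @return object of class `phenology_calendar`: list with `transplant_date`,
#'   `stages` (data frame `stage`, `start_dat`, `end_dat`, `duration_days`)
#'   and `cycle_days`.
#' @examples
#' cal <- phenology_calendar()
#' cal$stages
#' stage_of(as.Date("2024-03-14"), cal)  # "vegetative"
#' @export
phenology_calendar <- function(transplant_date = as.Date("2024-03-14"),
                               stage_ends = c(vegetative = 50L,
                                              reproductive = 109L,
                                              harvest = 190L)) {
  transplant_date <- tryCatch(as.Date(transplant_date), error = function(e) NA)
  if (is.na(transplant_date)) stop("phenology_calendar(): invalid transplant date", call. = FALSE)
  stage_ends <- stats::setNames(as.integer(stage_ends), names(stage_ends))
  if (length(stage_ends) < 1L || is.null(names(stage_ends)) || any(!nzchar(names(stage_ends))))
    stop("phenology_calendar(): stage_ends must be a named vector", call. = FALSE)
  if (any(diff(stage_ends) <= 0L) || stage_ends[1L] <= 0L)
    stop("phenology_calendar(): stage end-DATs must be positive and strictly increasing", call. = FALSE)
  starts <- c(0L, head(stage_ends, -1L) + 1L)
  durations <- diff(c(0L, stage_ends))
  structure(
    list(transplant_date = transplant_date,
         stages = data.frame(stage = names(stage_ends),
                             start_dat = starts,
                             end_dat = unname(stage_ends),
                             duration_days = unname(durations),
                             stringsAsFactors = FALSE),
         cycle_days = unname(stage_ends[length(stage_ends)])),
    class = "phenology_calendar")
}

#' @export
print.phenology_calendar <- function(x, ...) {
  cat(sprintf("Phenology calendar: transplant %s, %d-day cycle\n",
              format(x$transplant_date), x$cycle_days))
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Days after transplant for a date
#'
#' @param date `Date` vector (or coercible).
#' @param calendar a [phenology_calendar()].
#' @return integer vector of whole days since transplant.
#' @export
days_after_transplant <- function(date, calendar) {
  stopifnot(inherits(calendar, "phenology_calendar"))
  as.integer(as.Date(date) - calendar$transplant_date)
}

#' Phenological stage of a date
#'
#' @param date `Date` vector (or coercible).
#' @param calendar a [phenology_calendar()].
#' @return character vector of stage names. Dates outside the cycle are an
#'   error.
#' @export
stage_of <- function(date, calendar) {
  dat <- days_after_transplant(date, calendar)
  stage_of_dat(dat, calendar)
}

#' Phenological stage by days after transplant
#'
#' @param dat integer vector of days after transplant.
#' @param calendar a [phenology_calendar()].
#' @return character vector of stage names.
#' @export
stage_of_dat <- function(dat, calendar) {
  stopifnot(inherits(calendar, "phenology_calendar"))
  st <- calendar$stages
  if (any(!is.na(dat) & (dat < 0L | dat > calendar$cycle_days))) {
    bad <- dat[!is.na(dat) & (dat < 0L | dat > calendar$cycle_days)][1L]
    stop(sprintf("stage_of(): DAT %d outside the 0--%d cycle", bad, calendar$cycle_days),
         call. = FALSE)
  }
  idx <- findInterval(dat, c(st$start_dat, calendar$cycle_days + 1L))
  st$stage[idx]
}

#' Day/night period of a timestamp
#'
#' Half-open daytime convention: a record is "day" iff its clock time lies in
#' `[day_start, day_end)`; everything else is "night". The default 06:00--18:00
#' split reflects an equatorial site with a near-constant 12-hour photoperiod.
#'
#' @param timestamp `POSIXct` vector (naive local time).
#' @param day_start,day_end day boundaries as fractional hours (defaults 6, 18).
#' @return character vector, `"day"` or `"night"`.
#' @examples
#' period_of(as.POSIXct("2024-03-14 18:00:00", tz = "UTC"))  # "night"
#' @export
period_of <- function(timestamp, day_start = 6, day_end = 18) {
  if (day_start >= day_end)
    stop("period_of(): day_start must be earlier than day_end", call. = FALSE)
  lt <- as.POSIXlt(timestamp)
  h <- lt$hour + lt$min / 60 + lt$sec / 3600
  ifelse(h >= day_start & h < day_end, "day", "night")
}
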