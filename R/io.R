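#' Read a sensor record CSV
#'
#' Expects the header `timestamp,sensor_id,temp_c,rh_pct` with ISO-8601
#' local timestamps and empty fields for missing values. Records are
#' validated (parseable timestamps, RH within \[0, 100\], no duplicate
#' (sensor, timestamp) pairs) and returned sorted by sensor and time.
#'
#' @param path CSV file path.
#' @return long data frame `timestamp` (`POSIXct`), `sensor_id`, `temp_c`,
#'   `rh_pct`.
#' @export
read_sensor_csv <- function(path) {
  if (!file.exists(path)) stop("read_sensor_csv(): file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "numeric", "numeric"))
  if (!identical(names(df), c("timestamp", "sensor_id", "temp_c", "rh_pct")))
    stop("read_sensor_csv(): header must be timestamp,sensor_id,temp_c,rh_pct",
         call. = FALSE)
  if (nrow(df) == 0L) stop("read_sensor_csv(): file has no records", call. = FALSE)
  ts <- tryCatch(
    as.POSIXct(df$timestamp, tz = "UTC",
               tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S")),
    error = function(e) rep(as.POSIXct(NA), nrow(df)))
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1L]
    stop(sprintf("read_sensor_csv(): unparseable timestamp at data row %d: '%s'",
                 bad, df$timestamp[bad]), call. = FALSE)
  }
  df$timestamp <- ts
  bad_rh <- which(!is.na(df$rh_pct) & (df$rh_pct < 0 | df$rh_pct > 100))
  if (length(bad_rh))
    stop(sprintf("read_sensor_csv(): RH out of [0, 100] at data row %d (sensor %s, value %.1f)",
                 bad_rh[1L], df$sensor_id[bad_rh[1L]], df$rh_pct[bad_rh[1L]]), call. = FALSE)
  key <- paste(df$sensor_id, format(df$timestamp, "%Y-%m-%d %H:%M:%S"))
  if (anyDuplicated(key))
    stop("read_sensor_csv(): duplicate (sensor, timestamp): ",
         key[anyDuplicated(key)], call. = FALSE)
  df[order(df$sensor_id, df$timestamp), , drop = FALSE]
}

#' Write a sensor record CSV
#'
#' Inverse of [read_sensor_csv()]: ISO-8601 timestamps, empty fields for
#' missing values.
#'
#' @param records long record table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(records, path) {
  out <- records[c("timestamp", "sensor_id", "temp_c", "rh_pct")]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a thresholds + calendar configuration file
#'
#' The YAML layout mirrors a stage-by-period range table cell for cell:
#' each (stage, period, variable) entry has an `optimal: [lo, hi]` interval
#' and `critical_below`/`critical_above` cuts; the suboptimal band is
#' implied (see [threshold_table()]). The packaged default
#' (`system.file("extdata", "thresholds_tomato.yaml", package = "microclim")`)
#' reproduces [default_thresholds()] and the 190-day tomato calendar.
#'
#' @param path YAML file path.
#' @return list with `thresholds` (a [threshold_table()]) and `calendar`
#'   (a [phenology_calendar()]).
#' @export
read_thresholds_config <- function(path) {
  if (!file.exists(path)) stop("read_thresholds_config(): file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$calendar) || is.null(cfg$thresholds))
    stop("read_thresholds_config(): config needs 'calendar' and 'thresholds' sections",
         call. = FALSE)
  ends <- vapply(cfg$calendar$stages, function(s) as.integer(s$end_dat), integer(1))
  calendar <- phenology_calendar(cfg$calendar$transplant_date, stage_ends = ends)
  rows <- list()
  for (stage in names(cfg$thresholds)) {
    for (period in names(cfg$thresholds[[stage]])) {
      for (variable in names(cfg$thresholds[[stage]][[period]])) {
        e <- cfg$thresholds[[stage]][[period]][[variable]]
        if (length(e$optimal) != 2L || is.null(e$critical_below) || is.null(e$critical_above))
          stop(sprintf("read_thresholds_config(): malformed entry %s/%s/%s",
                       stage, period, variable), call. = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          stage = stage, period = period, variable = variable,
          opt_lo = e$optimal[1], opt_hi = e$optimal[2],
          crit_lo = e$critical_below, crit_hi = e$critical_above,
          stringsAsFactors = FALSE)
      }
    }
  }
  thresholds <- threshold_table(do.call(rbind, rows), stages = names(ends))
  list(thresholds = thresholds, calendar = calendar)
}

#' Write a thresholds + calendar configuration file
#'
#' @param thresholds a [threshold_table()].
#' @param calendar a [phenology_calendar()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_thresholds_config <- function(thresholds, calendar, path) {
  stopifnot(inherits(thresholds, "threshold_table"),
            inherits(calendar, "phenology_calendar"))
  stages <- stats::setNames(
    lapply(seq_len(nrow(calendar$stages)),
           function(i) list(end_dat = calendar$stages$end_dat[i])),
    calendar$stages$stage)
  th <- list()
  for (i in seq_len(nrow(thresholds))) {
    r <- thresholds[i, ]
    th[[r$stage]][[r$period]][[r$variable]] <-
      list(optimal = c(r$opt_lo, r$opt_hi),
           critical_below = r$crit_lo, critical_above = r$crit_hi)
  }
  yaml::write_yaml(list(calendar = list(transplant_date = format(calendar$transplant_date),
                                        stages = stages),
                        thresholds = th), path)
  invisible(path)
}
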