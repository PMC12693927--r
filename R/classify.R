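#' Classify sensor records against stage/period thresholds
#'
#' Derives VPD, assigns each record its phenological stage (from the date)
#' and day/night period (from the clock time), classifies T, RH and VPD
#' independently against the threshold table, and adds a composite
#' microclimate category defined as the worst category across the three
#' variables (critical > suboptimal > optimal). Records missing any
#' variable carry `NA` in the affected categories.
#'
#' @param records long data frame `timestamp`, `sensor_id`, `temp_c`,
#'   `rh_pct` (e.g. `simulate_greenhouse()$records` or [read_sensor_csv()]).
#' @param calendar a [phenology_calendar()].
#' @param thresholds a [threshold_table()]; defaults to
#'   [default_thresholds()].
#' @param day_start,day_end day-period boundaries passed to [period_of()].
#' @return the input with added columns `vpd_kpa`, `date`, `stage`,
#'   `period`, per-variable `cat_*`/`side_*` and `cat_composite`.
#' @export
classify_records <- function(records, calendar,
                             thresholds = default_thresholds(),
                             day_start = 6, day_end = 18) {
  stopifnot(is.data.frame(records),
            all(c("timestamp", "sensor_id", "temp_c", "rh_pct") %in% names(records)),
            inherits(calendar, "phenology_calendar"))
  out <- add_vpd(records)
  out$date <- as.Date(out$timestamp)
  out$stage <- stage_of(out$date, calendar)
  out$period <- period_of(out$timestamp, day_start, day_end)
  for (v in c("T", "RH", "VPD")) {
    col <- switch(v, T = "temp_c", RH = "rh_pct", VPD = "vpd_kpa")
    cl <- classify_value(v, out[[col]], out$stage, out$period, thresholds)
    out[[paste0("cat_", v)]] <- cl$category
    out[[paste0("side_", v)]] <- cl$side
  }
  sev <- pmax(as.integer(out$cat_T), as.integer(out$cat_RH), as.integer(out$cat_VPD))
  out$cat_composite <- factor(category_levels()[sev], levels = category_levels())
  out
}

share_row <- function(categories) {
  categories <- categories[!is.na(categories)]
  n <- length(categories)
  if (n == 0L) {
    return(data.frame(pct_optimal = NA_real_, pct_suboptimal = NA_real_,
                      pct_critical = NA_real_, n_records = 0L))
  }
  p <- as.numeric(table(factor(categories, levels = category_levels()))) / n * 100
  data.frame(pct_optimal = p[1], pct_suboptimal = p[2], pct_critical = p[3],
             n_records = n)
}

#' Time-in-category shares by sensor, stage and period
#'
#' Converts classified records into the share of (non-missing) time each
#' sensor spent in the optimal, suboptimal and critical category, per
#' phenological stage and day/night period. The default `"composite"` mode
#' uses the integrated microclimate category (worst of T, RH, VPD per
#' record); `"per_variable"` reports each variable separately. When
#' `include_average = TRUE`, per-sensor/period `"average"` rows are appended
#' holding the unweighted mean of the stage values.
#'
#' @param classified output of [classify_records()].
#' @param mode `"composite"` or `"per_variable"`.
#' @param include_average append unweighted stage-average rows?
#' @return data frame `sensor_id`, `stage`, `period` (plus `variable` in
#'   per-variable mode), `pct_optimal`, `pct_suboptimal`, `pct_critical`,
#'   `n_records`. Empty cells have `n_records = 0` and `NA` percentages.
#' @export
aggregate_shares <- function(classified, mode = c("composite", "per_variable"),
                             include_average = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(classified), "cat_composite" %in% names(classified))
  stage_order <- unique(classified$stage)
  cells <- expand.grid(sensor_id = unique(classified$sensor_id),
                       stage = stage_order, period = c("day", "night"),
                       stringsAsFactors = FALSE)
  vars <- if (mode == "composite") "composite" else c("T", "RH", "VPD")
  res <- list()
  for (v in vars) {
    col <- paste0("cat_", v)
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      sel <- classified$sensor_id == cells$sensor_id[i] &
        classified$stage == cells$stage[i] & classified$period == cells$period[i]
      cbind(cells[i, , drop = FALSE], share_row(classified[[col]][sel]))
    })
    block <- do.call(rbind, rows)
    if (mode == "per_variable") block$variable <- v
    res[[v]] <- block
  }
  out <- do.call(rbind, res)
  row.names(out) <- NULL
  if (include_average) out <- rbind(out, share_stage_averages(out))
  out
}

#' Unweighted stage-average rows for a share table
#'
#' For each sensor and period (and variable, if present), the mean of the
#' per-stage percentages — the "Average" rows of a stage-by-period share
#' table. Stages with empty cells are skipped in the mean.
#'
#' @param shares data frame as produced by [aggregate_shares()] (stage rows
#'   only; existing `"average"` rows are ignored).
#' @return data frame of the same shape with `stage = "average"`.
#' @export
share_stage_averages <- function(shares) {
  stopifnot(is.data.frame(shares),
            all(c("sensor_id", "stage", "period", "pct_optimal") %in% names(shares)))
  shares <- shares[shares$stage != "average", , drop = FALSE]
  keys <- c("sensor_id", "period", intersect("variable", names(shares)))
  grp <- interaction(shares[keys], drop = TRUE)
  rows <- lapply(levels(grp), function(g) {
    block <- shares[grp == g, , drop = FALSE]
    block <- block[block$n_records > 0L, , drop = FALSE]
    if (nrow(block) == 0L) return(NULL)
    out <- block[1L, , drop = FALSE]
    out$stage <- "average"
    for (col in c("pct_optimal", "pct_suboptimal", "pct_critical"))
      out[[col]] <- mean(block[[col]])
    out$n_records <- sum(block$n_records)
    out
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Decompose critical time into low and high drivers
#'
#' For each stage, period and variable: the percentage of non-missing time
#' the variable was critically low and critically high. The two shares sum
#' to that variable's total critical share.
#'
#' @param classified output of [classify_records()].
#' @param by_sensor if `TRUE`, decompose per sensor; default pools all
#'   internal sensors.
#' @return data frame `stage`, `period`, `variable` (plus `sensor_id` when
#'   `by_sensor`), `pct_critical_low`, `pct_critical_high`, `n_records`.
#' @export
critical_driver_decomposition <- function(classified, by_sensor = FALSE) {
  stopifnot(is.data.frame(classified), "cat_T" %in% names(classified))
  keys <- c(if (by_sensor) "sensor_id", "stage", "period")
  cells <- unique(classified[keys])
  res <- list()
  for (v in c("T", "RH", "VPD")) {
    cat_col <- paste0("cat_", v); side_col <- paste0("side_", v)
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      sel <- rep(TRUE, nrow(classified))
      for (k in keys) sel <- sel & classified[[k]] == cells[[k]][i]
      cats <- classified[[cat_col]][sel]; sides <- classified[[side_col]][sel]
      ok <- !is.na(cats)
      n <- sum(ok)
      lo <- if (n) 100 * sum(cats[ok] == "critical" & sides[ok] == "low") / n else NA_real_
      hi <- if (n) 100 * sum(cats[ok] == "critical" & sides[ok] == "high") / n else NA_real_
      cbind(cells[i, , drop = FALSE],
            data.frame(variable = v, pct_critical_low = lo,
                       pct_critical_high = hi, n_records = n))
    })
    res[[v]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res)
  row.names(out) <- NULL
  out
}

#' Majority-rule daily microclimate status
#'
#' For one calendar date: computes, per variable, the percentage of the
#' (non-missing) day spent in each category, then assigns the daily status
#' by majority rule — if at least two of the three variables spent more
#' than 50% of the day in the same category, that category is the status
#' (`rule_satisfied = TRUE`). Otherwise the category with the largest mean
#' share across variables is assigned, ties broken by severity
#' (critical > suboptimal > optimal), and `rule_satisfied = FALSE`.
#'
#' @param classified_day classified records (one date; see
#'   [classify_records()]).
#' @return one-row data frame: `date`, the nine `pct_<category>_<variable>`
#'   columns, `status`, `rule_satisfied`. `NULL` (with a message) if any
#'   variable is entirely missing that day.
#' @export
daily_status <- function(classified_day) {
  stopifnot(is.data.frame(classified_day), "cat_T" %in% names(classified_day))
  date <- unique(classified_day$date)
  if (length(date) != 1L)
    stop("daily_status(): records must belong to a single date", call. = FALSE)
  pct <- matrix(NA_real_, nrow = 3, ncol = 3,
                dimnames = list(category_levels(), c("T", "RH", "VPD")))
  for (v in colnames(pct)) {
    cats <- classified_day[[paste0("cat_", v)]]
    cats <- cats[!is.na(cats)]
    if (length(cats) == 0L) {
      message(sprintf("daily_status(): %s entirely missing on %s; day excluded",
                      v, format(date)))
      return(NULL)
    }
    pct[, v] <- as.numeric(table(factor(cats, levels = category_levels()))) /
      length(cats) * 100
  }
  votes <- rowSums(pct > 50)
  if (any(votes >= 2)) {
    status <- category_levels()[which(votes >= 2)[1L]]
    rule <- TRUE
  } else {
    m <- rowMeans(pct)
    best <- which(m == max(m))
    status <- category_levels()[max(best)]  # ties resolved toward severity
    rule <- FALSE
  }
  out <- data.frame(date = date)
  for (v in colnames(pct)) for (cc in rownames(pct))
    out[[paste0("pct_", cc, "_", v)]] <- pct[cc, v]
  out$status <- factor(status, levels = category_levels())
  out$rule_satisfied <- rule
  out
}

#' Daily microclimate status table
#'
#' Applies [daily_status()] to every date in a classified record table,
#' optionally restricted to one sensor (default pools all internal
#' sensors). Days with a fully missing variable are dropped with a message.
#'
#' @param classified output of [classify_records()].
#' @param sensor optional sensor id filter.
#' @return data frame, one row per retained date, time-ordered.
#' @export
daily_status_table <- function(classified, sensor = NULL) {
  if (!is.null(sensor)) classified <- classified[classified$sensor_id %in% sensor, ]
  classified <- classified[classified$sensor_id != "EXTERNAL", ]
  if (nrow(classified) == 0L) stop("daily_status_table(): no records", call. = FALSE)
  days <- split(classified, classified$date)
  rows <- lapply(days, daily_status)
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- out[order(out$date), , drop = FALSE]
  row.names(out) <- NULL
  out
}
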