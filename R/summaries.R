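#' Descriptive statistics by stage, variable and sensor
#'
#' For each (stage, variable, sensor) cell: overall mean, absolute minimum
#' and maximum, and the means of the per-day minima and maxima. Days with
#' less than `min_coverage` of their expected records present are excluded
#' from the daily-extrema means (and noted via a message).
#'
#' @param records long record table (`timestamp`, `sensor_id`, `temp_c`,
#'   `rh_pct`; a `vpd_kpa` column is added if absent).
#' @param calendar a [phenology_calendar()].
#' @param min_coverage minimum share of a day's records required for that
#'   day to enter the daily-extrema means (default 0.5).
#' @return data frame `stage`, `variable`, `sensor_id`, `mean`,
#'   `min_absolute`, `max_absolute`, `mean_of_min`, `mean_of_max`,
#'   `n_records`.
#' @export
descriptive_table <- function(records, calendar, min_coverage = 0.5) {
  stopifnot(is.data.frame(records), inherits(calendar, "phenology_calendar"))
  if (!"vpd_kpa" %in% names(records)) records <- add_vpd(records)
  records$date <- as.Date(records$timestamp)
  records$stage <- stage_of(records$date, calendar)
  cols <- c(T = "temp_c", RH = "rh_pct", VPD = "vpd_kpa")
  expected_per_day <- max(table(records$date, records$sensor_id))
  out <- list()
  for (sid in unique(records$sensor_id)) {
    for (st in unique(records$stage)) {
      block <- records[records$sensor_id == sid & records$stage == st, ]
      for (v in names(cols)) {
        vals <- block[[cols[v]]]
        ok <- !is.na(vals)
        if (!any(ok)) {
          warning(sprintf("descriptive_table(): empty cell %s/%s/%s omitted", st, v, sid))
          next
        }
        counts <- tapply(ok, block$date, sum)
        full_days <- names(counts)[counts / expected_per_day >= min_coverage]
        dmin <- tapply(vals[ok], block$date[ok], min)
        dmax <- tapply(vals[ok], block$date[ok], max)
        keep <- names(dmin) %in% full_days
        out[[length(out) + 1L]] <- data.frame(
          stage = st, variable = v, sensor_id = sid,
          mean = mean(vals[ok]),
          min_absolute = min(vals[ok]), max_absolute = max(vals[ok]),
          mean_of_min = mean(dmin[keep]), mean_of_max = mean(dmax[keep]),
          n_records = sum(ok), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

#' One-way analysis of variance
#'
#' Classical between/within sum-of-squares decomposition with the F test.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2), or a
#'   data frame with columns `value` and `group`.
#' @return object of class `anova_result`: list with `df_between`,
#'   `df_within`, `ss_between`, `ss_within`, `ms_between`, `ms_within`,
#'   `f_value`, `p_value`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
one_way_anova <- function(groups) {
  if (is.data.frame(groups)) groups <- split(groups$value, groups$group)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L || any(lengths(groups) < 2L))
    stop("one_way_anova(): need >= 2 groups with >= 2 observations each", call. = FALSE)
  all_vals <- unlist(groups, use.names = FALSE)
  grand <- mean(all_vals)
  ni <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(ni * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_between <- length(groups) - 1L
  df_within <- length(all_vals) - length(groups)
  if (ss_within == 0)
    stop("one_way_anova(): zero within-group variance; F undefined", call. = FALSE)
  ms_between <- ss_between / df_between
  ms_within <- ss_within / df_within
  f_value <- ms_between / ms_within
  structure(list(df_between = df_between, df_within = df_within,
                 ss_between = ss_between, ss_within = ss_within,
                 ms_between = ms_between, ms_within = ms_within,
                 f_value = f_value,
                 p_value = stats::pf(f_value, df_between, df_within,
                                     lower.tail = FALSE)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_value, x$p_value))
  cat(sprintf("  SS between = %.4g, SS within = %.4g\n", x$ss_between, x$ss_within))
  invisible(x)
}

#' Sensor-wise ANOVA for the three climate variables
#'
#' Convenience wrapper applying [one_way_anova()] to T, RH and VPD across
#' the internal sensors.
#'
#' @param records long record table with `vpd_kpa` (added if absent).
#' @return named list of `anova_result` objects (`T`, `RH`, `VPD`).
#' @export
sensor_anova <- function(records) {
  if (!"vpd_kpa" %in% names(records)) records <- add_vpd(records)
  records <- records[records$sensor_id != "EXTERNAL", ]
  cols <- c(T = "temp_c", RH = "rh_pct", VPD = "vpd_kpa")
  lapply(cols, function(col)
    one_way_anova(split(records[[col]], records$sensor_id)))
}

#' Internal versus external climate comparison
#'
#' Internal-minus-external mean temperature differences overall, by
#' day/night period and by phenological stage, plus the proportion of time
#' internal RH exceeds the external value in the same strata. When
#' `external` carries 5-minute records (a `timestamp` column), internal
#' and external records are compared period-resolved on the shared grid.
#' When it is a daily table (a `date` column), the external daily mean is
#' used overall and by stage, with daytime/nighttime external temperature
#' proxied by the daily maximum/minimum — a documented approximation for
#' stations that only log daily summaries.
#'
#' @param internal internal sensor records (any number of sensors).
#' @param external external records: 5-min table or daily weather table.
#' @param calendar a [phenology_calendar()].
#' @param day_start,day_end day-period boundaries.
#' @return list with `overall`, `by_period` and `by_stage` data frames
#'   (columns `t_diff_c`, `rh_exceedance_pct`).
#' @export
internal_external_comparison <- function(internal, external, calendar,
                                         day_start = 6, day_end = 18) {
  stopifnot(is.data.frame(internal), is.data.frame(external))
  internal <- internal[internal$sensor_id != "EXTERNAL", ]
  internal$date <- as.Date(internal$timestamp)
  internal$stage <- stage_of(internal$date, calendar)
  internal$period <- period_of(internal$timestamp, day_start, day_end)

  if ("timestamp" %in% names(external)) {
    key <- match(internal$timestamp, external$timestamp)
    if (all(is.na(key))) stop("internal_external_comparison(): no overlap", call. = FALSE)
    ext_t <- external$temp_c[key]
    ext_rh <- external$rh_pct[key]
  } else if ("date" %in% names(external)) {
    key <- match(internal$date, external$date)
    if (all(is.na(key))) stop("internal_external_comparison(): no overlap", call. = FALSE)
    ext_t <- ifelse(internal$period == "day",
                    external$tmax_c[key], external$tmin_c[key])
    ext_rh <- external$rhmean_pct[key]
  } else stop("internal_external_comparison(): external needs a timestamp or date column",
              call. = FALSE)

  dt <- internal$temp_c - ext_t
  exceed <- internal$rh_pct > ext_rh
  strat <- function(sel) {
    data.frame(t_diff_c = mean(dt[sel], na.rm = TRUE),
               rh_exceedance_pct = 100 * mean(exceed[sel], na.rm = TRUE))
  }
  by_period <- do.call(rbind, lapply(c("day", "night"), function(p)
    cbind(period = p, strat(internal$period == p))))
  stages <- unique(internal$stage)
  by_stage <- do.call(rbind, lapply(stages, function(s)
    cbind(stage = s, strat(internal$stage == s))))
  list(overall = strat(rep(TRUE, nrow(internal))),
       by_period = by_period, by_stage = by_stage)
}

#' PAR transmission coefficient of a greenhouse cover
#'
#' Mean of the pairwise inside/outside photosynthetically active radiation
#' ratios. Pairs with a nonpositive outside reading are dropped with a
#' warning.
#'
#' @param par_inside,par_outside paired radiation readings (same units).
#' @return scalar ratio, in `(0, 1]` for physically sensible inputs.
#' @examples
#' transmission_coefficient(120, 200)  # 0.6
#' @export
transmission_coefficient <- function(par_inside, par_outside) {
  stopifnot(length(par_inside) == length(par_outside))
  keep <- !is.na(par_inside) & !is.na(par_outside) & par_outside > 0
  if (!all(keep, na.rm = TRUE))
    warning("transmission_coefficient(): dropped pairs with nonpositive or missing outside readings")
  if (!any(keep)) stop("transmission_coefficient(): no valid pairs", call. = FALSE)
  mean(par_inside[keep] / par_outside[keep])
}

#' Yield and economic indicators
#'
#' From per-category yields, planting density and the cycle's cost/income
#' totals: category shares, marketable share (first two categories), yield
#' per plant (exact area conversion, 1 ha = 10,000 m^2), gross profit and
#' the benefit--cost ratio.
#'
#' @param category_weights named numeric vector of yields per quality
#'   category, kg/ha (category order = market order, best first).
#' @param plant_density plants per m^2.
#' @param total_cost,gross_income USD/ha.
#' @return object of class `economic_summary`: list with `categories`
#'   (data frame `category`, `weight_kg_ha`, `share_pct`),
#'   `total_yield_kg_ha`, `marketable_share_pct`, `yield_per_plant_kg`,
#'   `total_cost`, `gross_income`, `gross_profit`, `benefit_cost_ratio`.
#' @examples
#' economics(c(first = 37507.7, second = 29591.8,
#'             third = 16295.6, fourth = 4607.3),
#'           plant_density = 1.14,
#'           total_cost = 30800.9, gross_income = 44001.3)
#' @export
economics <- function(category_weights, plant_density, total_cost, gross_income) {
  stopifnot(is.numeric(category_weights), all(category_weights >= 0),
            plant_density > 0, total_cost > 0, gross_income >= 0)
  total <- sum(category_weights)
  if (total == 0) stop("economics(): total yield is zero", call. = FALSE)
  shares <- category_weights / total * 100
  marketable <- sum(shares[seq_len(min(2L, length(shares)))])
  structure(list(
    categories = data.frame(category = names(category_weights),
                            weight_kg_ha = unname(category_weights),
                            share_pct = unname(shares),
                            stringsAsFactors = FALSE),
    total_yield_kg_ha = total,
    marketable_share_pct = marketable,
    yield_per_plant_kg = total / (plant_density * 10000),
    total_cost = total_cost,
    gross_income = gross_income,
    gross_profit = gross_income - total_cost,
    benefit_cost_ratio = gross_income / total_cost),
    class = "economic_summary")
}

#' @export
print.economic_summary <- function(x, ...) {
  print(transform(x$categories, share_pct = round(share_pct, 1)), row.names = FALSE)
  cat(sprintf("total yield %.1f kg/ha (%.2f kg/plant), marketable %.1f%%\n",
              x$total_yield_kg_ha, x$yield_per_plant_kg, x$marketable_share_pct))
  cat(sprintf("gross profit %.1f USD/ha, benefit-cost ratio %.2f\n",
              x$gross_profit, x$benefit_cost_ratio))
  invisible(x)
}
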