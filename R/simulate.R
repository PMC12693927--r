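#' Configuration for the synthetic greenhouse simulator
#'
#' Builds a validated configuration describing a quadrant sensor network in
#' a passively ventilated greenhouse over one crop cycle. Defaults emulate a
#' 190-day tomato cycle logged at 5-minute intervals by four interior
#' sensors (eastern, northern, southern, western quadrants) plus one
#' external reference: stage-specific daytime/nighttime mean temperature
#' and relative humidity, additive quadrant offsets producing
#' ANOVA-detectable spatial heterogeneity, an asymmetric diurnal cycle
#' (minimum 06:00, maximum 14:00, equatorial photoperiod), anti-phase RH
#' with nocturnal excess, Gaussian record noise plus AR(1) day-to-day
#' drift, and per-sensor missingness near the 0.7--2.9% range typical of
#' field deployments.
#'
#' @param transplant_date start of the cycle (`Date` or string).
#' @param cycle_days number of simulated days (> 0).
#' @param interval_minutes sampling interval; must divide 1440.
#' @param stage_means data frame `stage`, `t_day`, `t_night`, `rh_day`,
#'   `rh_night`: target period means per phenological stage (degrees C, %).
#' @param external_means named list/vector `t_day`, `t_night`, `rh_day`,
#'   `rh_night` for the external sensor.
#' @param diurnal_amplitude_t,diurnal_amplitude_rh extra within-period
#'   diurnal swing (degrees C, % RH) beyond what the day/night means imply.
#' @param external_amplitude_t,external_amplitude_rh same for the external
#'   sensor (smaller by default: outside air varies less than the covered
#'   volume).
#' @param quadrant_offsets data frame `sensor_id`, `t_offset`, `rh_offset`.
#' @param noise_sd_t,noise_sd_rh per-record Gaussian noise SDs (internal).
#' @param external_noise_sd_t,external_noise_sd_rh same for external.
#' @param drift_sd_t,drift_sd_rh stationary SD of the AR(1) day-level drift.
#' @param drift_phi AR(1) coefficient of the day-level drift, in (-1, 1).
#' @param missing_fraction named numeric vector, per internal sensor, each
#'   in `[0, 0.5)`.
#' @param gap_length_mean mean length (records) of contiguous missing gaps.
#' @param day_start,day_end day-period boundaries (fractional hours).
#' @param par_transmission cover PAR transmission ratio used when pairing
#'   inside/outside radiation demos.
#' @param seed integer RNG seed giving fully reproducible output.
#' @return object of class `simulation_config` (a validated list).
#' @seealso [simulate_greenhouse()]
#' @export
simulation_config <- function(
    transplant_date = as.Date("2024-03-14"),
    cycle_days = 190L,
    interval_minutes = 5L,
    stage_means = data.frame(
      stage = c("vegetative", "reproductive", "harvest"),
      t_day = c(23.2, 22.0, 22.0),
      t_night = c(17.2, 15.8, 15.0),
      rh_day = c(65, 76, 59),
      rh_night = c(85.6, 90, 83.4)),
    external_means = c(t_day = 19.0, t_night = 14.3, rh_day = 58, rh_night = 88),
    diurnal_amplitude_t = 4, diurnal_amplitude_rh = 8,
    external_amplitude_t = 1.5, external_amplitude_rh = 3,
    quadrant_offsets = data.frame(
      sensor_id = c("S1-EQ", "S2-NQ", "S3-SQ", "S4-WQ"),
      t_offset = c(0.1, 0.5, -1.0, 0.0),
      rh_offset = c(-0.3, -0.6, 2.8, 0.1)),
    noise_sd_t = 1.0, noise_sd_rh = 3.0,
    external_noise_sd_t = 0.4, external_noise_sd_rh = 1.5,
    drift_sd_t = 0.8, drift_sd_rh = 2.0, drift_phi = 0.7,
    missing_fraction = c("S1-EQ" = 0.009, "S2-NQ" = 0.007,
                         "S3-SQ" = 0.029, "S4-WQ" = 0.023),
    gap_length_mean = 6,
    day_start = 6, day_end = 18,
    par_transmission = 0.60,
    seed = 1L) {
  transplant_date <- as.Date(transplant_date)
  if (is.na(transplant_date)) stop("simulation_config(): invalid transplant date", call. = FALSE)
  cycle_days <- as.integer(cycle_days)
  interval_minutes <- as.integer(interval_minutes)
  if (is.na(cycle_days) || cycle_days <= 0L)
    stop("simulation_config(): cycle_days must be positive", call. = FALSE)
  if (is.na(interval_minutes) || interval_minutes <= 0L || 1440L %% interval_minutes != 0L)
    stop("simulation_config(): interval_minutes must divide 1440", call. = FALSE)
  if (any(missing_fraction < 0 | missing_fraction >= 0.5))
    stop("simulation_config(): missing_fraction must lie in [0, 0.5)", call. = FALSE)
  stopifnot(is.data.frame(stage_means),
            all(c("stage", "t_day", "t_night", "rh_day", "rh_night") %in% names(stage_means)),
            is.data.frame(quadrant_offsets),
            all(c("sensor_id", "t_offset", "rh_offset") %in% names(quadrant_offsets)),
            abs(drift_phi) < 1, gap_length_mean >= 1,
            day_start < day_end)
  cfg <- list(transplant_date = transplant_date, cycle_days = cycle_days,
              interval_minutes = interval_minutes, stage_means = stage_means,
              external_means = external_means,
              diurnal_amplitude_t = diurnal_amplitude_t,
              diurnal_amplitude_rh = diurnal_amplitude_rh,
              external_amplitude_t = external_amplitude_t,
              external_amplitude_rh = external_amplitude_rh,
              quadrant_offsets = quadrant_offsets,
              noise_sd_t = noise_sd_t, noise_sd_rh = noise_sd_rh,
              external_noise_sd_t = external_noise_sd_t,
              external_noise_sd_rh = external_noise_sd_rh,
              drift_sd_t = drift_sd_t, drift_sd_rh = drift_sd_rh,
              drift_phi = drift_phi,
              missing_fraction = missing_fraction,
              gap_length_mean = gap_length_mean,
              day_start = day_start, day_end = day_end,
              par_transmission = par_transmission,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Asymmetric diurnal shape
#'
#' Unit-amplitude daily curve with minimum -1 at 06:00 and maximum +1 at
#' 14:00 (8 h rise, 16 h fall), built from two half-sinusoids. Used as the
#' deterministic backbone of the simulated temperature cycle; RH uses it in
#' anti-phase.
#'
#' @param hour fractional hour of day (vector, values taken mod 24).
#' @return numeric vector in `[-1, 1]`.
#' @export
diurnal_shape <- function(hour) {
  h <- hour %% 24
  ifelse(h >= 6 & h < 14,
         -cos(pi * (h - 6) / 8),
         cos(pi * ((h - 14) %% 24) / 16))
}

# deterministic per-sensor mean curves. Temperature rides the continuous
# diurnal sinusoid (c0 + c1*s solved against the grid means of s so the
# day/night period means hit their targets exactly); RH follows its period
# targets with anti-phase diurnal modulation (peak pre-dawn), which keeps the
# large day/night RH gap from overshooting the 100% ceiling. In both cases
# the amplitude term is centred within each period so it cannot shift the
# period means.
sensor_curve <- function(s, is_day, stage, stage_tab, amp, anti_phase = FALSE) {
  ms_day <- mean(s[is_day]); ms_night <- mean(s[!is_day])
  day_target <- stage_tab$day[match(stage, stage_tab$stage)]
  night_target <- stage_tab$night[match(stage, stage_tab$stage)]
  centred <- s - ifelse(is_day, ms_day, ms_night)
  if (anti_phase) {
    ifelse(is_day, day_target, night_target) - amp * centred
  } else {
    c1 <- (day_target - night_target) / (ms_day - ms_night)
    c0 <- day_target - c1 * ms_day
    c0 + c1 * s + amp * centred
  }
}

ar1_daily_drift <- function(n_days, phi, sd_stationary) {
  if (sd_stationary <= 0) return(numeric(n_days))
  innov_sd <- sd_stationary * sqrt(1 - phi^2)
  x <- numeric(n_days)
  x[1] <- stats::rnorm(1, 0, sd_stationary)
  for (j in seq_len(n_days)[-1]) x[j] <- phi * x[j - 1] + stats::rnorm(1, 0, innov_sd)
  x
}

#' Simulate a greenhouse sensor network over a crop cycle
#'
#' Generates the complete (gap-free) 5-minute series for four quadrant
#' sensors and one external sensor, injects per-sensor missingness into the
#' internal series, and aggregates the external series into a daily weather
#' table with simulated precipitation, wind and radiation. Output is fully
#' determined by `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return object of class `greenhouse_sim`: list with
#'   \describe{
#'     \item{records}{long data frame `timestamp`, `sensor_id`, `temp_c`,
#'       `rh_pct` for all five sensors, internal sensors carrying injected
#'       `NA` gaps}
#'     \item{truth}{the same table before missingness injection}
#'     \item{weather}{daily external weather: `date`, `tmean_c`, `tmin_c`,
#'       `tmax_c`, `rhmean_pct`, `precip_lm2`, `wind_kmh`, `rad_wm2`}
#'     \item{calendar}{the [phenology_calendar()] used}
#'     \item{config}{the input configuration}
#'   }
#' @examples
#' sim <- simulate_greenhouse(simulation_config(cycle_days = 2, seed = 42))
#' head(sim$records)
#' @export
simulate_greenhouse <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  calendar <- phenology_calendar(config$transplant_date)
  if (config$cycle_days > calendar$cycle_days + 1L)
    calendar <- phenology_calendar(config$transplant_date,
                                   stage_ends = c(vegetative = 50L, reproductive = 109L,
                                                  harvest = as.integer(config$cycle_days)))
  with_seed(config$seed, {
    per_day <- 1440L %/% config$interval_minutes
    n <- config$cycle_days * per_day
    t0 <- as.POSIXct(paste(config$transplant_date, "00:00:00"), tz = "UTC")
    ts <- t0 + seq(0L, n - 1L) * config$interval_minutes * 60
    hour <- (seq(0L, n - 1L) %% per_day) * config$interval_minutes / 60
    day_idx <- seq(0L, n - 1L) %/% per_day + 1L
    dat <- day_idx - 1L
    stage <- stage_of_dat(pmin(dat, calendar$cycle_days), calendar)
    s <- diurnal_shape(hour)
    is_day <- hour >= config$day_start & hour < config$day_end

    t_tab <- data.frame(stage = config$stage_means$stage,
                        day = config$stage_means$t_day,
                        night = config$stage_means$t_night)
    rh_tab <- data.frame(stage = config$stage_means$stage,
                         day = config$stage_means$rh_day,
                         night = config$stage_means$rh_night)
    ext_t_tab <- data.frame(stage = t_tab$stage,
                            day = unname(config$external_means["t_day"]),
                            night = unname(config$external_means["t_night"]))
    ext_rh_tab <- data.frame(stage = t_tab$stage,
                             day = unname(config$external_means["rh_day"]),
                             night = unname(config$external_means["rh_night"]))

    base_t <- sensor_curve(s, is_day, stage, t_tab, config$diurnal_amplitude_t)
    base_rh <- sensor_curve(s, is_day, stage, rh_tab, config$diurnal_amplitude_rh,
                            anti_phase = TRUE)
    ext_t <- sensor_curve(s, is_day, stage, ext_t_tab, config$external_amplitude_t)
    ext_rh <- sensor_curve(s, is_day, stage, ext_rh_tab, config$external_amplitude_rh,
                           anti_phase = TRUE)

    qs <- config$quadrant_offsets
    out <- vector("list", nrow(qs) + 1L)
    for (i in seq_len(nrow(qs))) {
      drift_t <- ar1_daily_drift(config$cycle_days, config$drift_phi, config$drift_sd_t)[day_idx]
      drift_rh <- ar1_daily_drift(config$cycle_days, config$drift_phi, config$drift_sd_rh)[day_idx]
      temp <- base_t + qs$t_offset[i] + drift_t +
        stats::rnorm(n, 0, config$noise_sd_t)
      rh <- base_rh + qs$rh_offset[i] + drift_rh +
        stats::rnorm(n, 0, config$noise_sd_rh)
      out[[i]] <- data.frame(timestamp = ts, sensor_id = qs$sensor_id[i],
                             temp_c = temp, rh_pct = pmin(pmax(rh, 0), 100),
                             stringsAsFactors = FALSE)
    }
    drift_t <- ar1_daily_drift(config$cycle_days, config$drift_phi, config$drift_sd_t / 2)[day_idx]
    drift_rh <- ar1_daily_drift(config$cycle_days, config$drift_phi, config$drift_sd_rh / 2)[day_idx]
    ext <- data.frame(
      timestamp = ts, sensor_id = "EXTERNAL",
      temp_c = ext_t + drift_t + stats::rnorm(n, 0, config$external_noise_sd_t),
      rh_pct = pmin(pmax(ext_rh + drift_rh +
                           stats::rnorm(n, 0, config$external_noise_sd_rh), 0), 100),
      stringsAsFactors = FALSE)
    out[[nrow(qs) + 1L]] <- ext
    truth <- do.call(rbind, out)
    row.names(truth) <- NULL

    records <- truth
    for (i in seq_len(nrow(qs))) {
      sid <- qs$sensor_id[i]
      frac <- config$missing_fraction[[sid]]
      if (!is.null(frac) && frac > 0) {
        sel <- records$sensor_id == sid
        records[sel, ] <- inject_missingness(
          records[sel, ], fraction = frac,
          gap_length_mean = config$gap_length_mean,
          seed = config$seed + i)
      }
    }

    weather <- simulate_daily_weather(ext, stage, day_idx, config)
    structure(list(records = records, truth = truth, weather = weather,
                   calendar = calendar, config = config),
              class = "greenhouse_sim")
  })
}

#' @export
print.greenhouse_sim <- function(x, ...) {
  cat(sprintf("Simulated greenhouse cycle: %d days x %d sensors, %d records (%.2f%% missing)\n",
              x$config$cycle_days, length(unique(x$records$sensor_id)),
              nrow(x$records),
              100 * mean(is.na(x$records$temp_c[x$records$sensor_id != "EXTERNAL"]))))
  invisible(x)
}

# daily weather table from the simulated external 5-min series; precipitation,
# wind and radiation are stage-dependent draws shaped like an equatorial dry
# season advancing through the cycle (wet early, dry and windy late).
simulate_daily_weather <- function(ext, stage, day_idx, config) {
  dates <- as.Date(ext$timestamp[!duplicated(day_idx)])
  stage_day <- stage[!duplicated(day_idx)]
  f <- factor(day_idx)
  tmean <- tapply(ext$temp_c, f, mean)
  tmin <- tapply(ext$temp_c, f, min)
  tmax <- tapply(ext$temp_c, f, max)
  rhmean <- tapply(ext$rh_pct, f, mean)
  par_tab <- data.frame(stage = c("vegetative", "reproductive", "harvest"),
                        wet_p = c(0.45, 0.35, 0.15),
                        wet_mm = c(7.2, 4.8, 3.8),
                        wind = c(4.7, 4.8, 7.8),
                        rad = c(198, 189, 180))
  i <- match(stage_day, par_tab$stage)
  i[is.na(i)] <- nrow(par_tab)
  nd <- length(dates)
  wet <- stats::rbinom(nd, 1, par_tab$wet_p[i])
  precip <- wet * stats::rgamma(nd, shape = 1.2, scale = par_tab$wet_mm[i] / 1.2)
  wind <- pmax(stats::rnorm(nd, par_tab$wind[i], 1), 0)
  rad <- pmax(stats::rnorm(nd, par_tab$rad[i], 25), 40)
  data.frame(date = dates, tmean_c = as.numeric(tmean), tmin_c = as.numeric(tmin),
             tmax_c = as.numeric(tmax), rhmean_pct = as.numeric(rhmean),
             precip_lm2 = round(precip, 1), wind_kmh = round(wind, 1),
             rad_wm2 = round(rad, 1), stringsAsFactors = FALSE)
}

#' Inject missing-at-random gaps into a sensor record table
#'
#' Marks records missing as a mixture of contiguous gaps with geometric
#' lengths (mean `gap_length_mean`) and, through the geometric distribution's
#' mass at 1, isolated single records. Present values are never altered,
#' only replaced by `NA` in the selected rows; both `temp_c` and `rh_pct`
#' are blanked together unless `variables` says otherwise.
#'
#' @param records data frame with `temp_c`, `rh_pct` columns (one sensor).
#' @param fraction target missing share, in `[0, 0.5)`.
#' @param gap_length_mean mean gap length in records (>= 1).
#' @param seed integer seed.
#' @param variables columns to blank (default both).
#' @return `records` with `NA`s injected; realized share is within a small
#'   overshoot of one gap length of the target.
#' @export
inject_missingness <- function(records, fraction, gap_length_mean = 6,
                               seed = 1L, variables = c("temp_c", "rh_pct")) {
  stopifnot(is.data.frame(records), all(variables %in% names(records)))
  if (fraction < 0 || fraction >= 0.5)
    stop("inject_missingness(): fraction must lie in [0, 0.5)", call. = FALSE)
  if (fraction == 0) return(records)
  n <- nrow(records)
  target <- round(fraction * n)
  if (target == 0L) return(records)
  with_seed(as.integer(seed), {
    miss <- logical(n)
    guard <- 0L
    while (sum(miss) < target && guard < 100L * target) {
      start <- sample.int(n, 1L)
      len <- stats::rgeom(1L, 1 / gap_length_mean) + 1L
      len <- min(len, target - sum(miss))  # cap the final gap so the target is hit exactly
      idx <- start:min(start + len - 1L, n)
      miss[idx] <- TRUE
      guard <- guard + 1L
    }
    records[miss, variables] <- NA_real_
    records
  })
}

# evaluate code with a deterministic RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
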