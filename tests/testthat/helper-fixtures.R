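# Shared fixtures, built in code. The full-cycle simulation is memoised so
# the suite pays its cost once.

.fixture_cache <- new.env(parent = emptyenv())

full_sim <- function() {
  if (is.null(.fixture_cache$full)) {
    .fixture_cache$full <- simulate_greenhouse(simulation_config(seed = 1))
  }
  .fixture_cache$full
}

full_classified <- function() {
  if (is.null(.fixture_cache$classified)) {
    sim <- full_sim()
    .fixture_cache$classified <-
      classify_records(sim$truth, sim$calendar, default_thresholds())
  }
  .fixture_cache$classified
}

# small record table on the 5-min grid with prescribed values
make_records <- function(temp, rh, start = "2024-03-14 00:00:00",
                         sensor = "S1-EQ", interval_min = 5) {
  n <- max(length(temp), length(rh))
  data.frame(
    timestamp = as.POSIXct(start, tz = "UTC") + seq(0, n - 1) * interval_min * 60,
    sensor_id = sensor,
    temp_c = rep_len(temp, n),
    rh_pct = rep_len(rh, n),
    stringsAsFactors = FALSE)
}

# daily-status table with a planted 2-rule structure:
# critical iff pct_critical_RH > 50 or pct_critical_VPD > 60
planted_daily <- function(n = 400, seed = 11) {
  set.seed(seed)
  d <- data.frame(date = seq(as.Date("2024-01-01"), by = 1, length.out = n))
  for (v in c("T", "RH", "VPD"))
    for (cc in c("optimal", "suboptimal", "critical"))
      d[[paste0("pct_", cc, "_", v)]] <- runif(n, 0, 100)
  d$status <- factor(
    ifelse(d$pct_critical_RH > 50 | d$pct_critical_VPD > 60, "critical", "optimal"),
    levels = category_levels())
  d
}

# exhaustive-search oracle for the root split: every feature, every midpoint
# between consecutive distinct values, size-weighted Gini of the children
brute_force_root_split <- function(x, y, min_leaf = 1) {
  x <- as.matrix(x)
  yi <- as.integer(factor(y))
  n <- length(yi)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    u <- sort(unique(x[, j]))
    if (length(u) < 2) next
    for (thr in (u[-1] + u[-length(u)]) / 2) {
      left <- yi[x[, j] <= thr]; right <- yi[x[, j] > thr]
      if (length(left) < min_leaf || length(right) < min_leaf) next
      score <- (length(left) * gini(tabulate(left, max(yi))) +
                  length(right) * gini(tabulate(right, max(yi)))) / n
      if (is.null(best) || score < best$score - 1e-12) {
        best <- list(feature = j, threshold = thr, score = score)
      }
    }
  }
  best
}

# Printed stage-by-period classification shares for the four quadrant
# sensors (optimal, suboptimal, critical), used as inputs to verify the
# Average-row arithmetic.
published_shares <- function() {
  rows <- list(
    c("S1-EQ", "vegetative",   "day",   33.5, 22.8, 43.7),
    c("S1-EQ", "vegetative",   "night", 11.6, 28.9, 59.5),
    c("S1-EQ", "reproductive", "day",   45.8, 29.2, 25.0),
    c("S1-EQ", "reproductive", "night",  1.2, 14.8, 84.0),
    c("S1-EQ", "harvest",      "day",   28.8, 27.4, 43.8),
    c("S1-EQ", "harvest",      "night", 15.8, 27.2, 57.0),
    c("S2-NQ", "vegetative",   "day",   30.4, 28.6, 41.0),
    c("S2-NQ", "vegetative",   "night", 15.6, 33.5, 50.9),
    c("S2-NQ", "reproductive", "day",   40.1, 28.4, 31.5),
    c("S2-NQ", "reproductive", "night",  1.0, 18.9, 80.1),
    c("S2-NQ", "harvest",      "day",   30.6, 25.1, 44.3),
    c("S2-NQ", "harvest",      "night", 18.8, 35.8, 45.4),
    c("S3-SQ", "vegetative",   "day",   48.0, 21.4, 30.6),
    c("S3-SQ", "vegetative",   "night",  1.7,  6.8, 91.5),
    c("S3-SQ", "reproductive", "day",   43.1, 35.6, 21.3),
    c("S3-SQ", "reproductive", "night",  0.6,  5.2, 94.2),
    c("S3-SQ", "harvest",      "day",   28.0, 29.4, 42.6),
    c("S3-SQ", "harvest",      "night", 18.0, 25.4, 56.6),
    c("S4-WQ", "vegetative",   "day",   44.4, 21.9, 33.7),
    c("S4-WQ", "vegetative",   "night",  2.6, 13.4, 84.0),
    c("S4-WQ", "reproductive", "day",   34.7, 44.1, 21.2),
    c("S4-WQ", "reproductive", "night",  3.0, 11.9, 85.1),
    c("S4-WQ", "harvest",      "day",   15.5, 26.5, 58.0),
    c("S4-WQ", "harvest",      "night", 26.4, 37.9, 35.7))
  df <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  names(df) <- c("sensor_id", "stage", "period",
                 "pct_optimal", "pct_suboptimal", "pct_critical")
  for (k in 4:6) df[[k]] <- as.numeric(df[[k]])
  df$n_records <- 1000L
  df
}

published_averages <- function() {
  rows <- list(
    c("S1-EQ", "day",   36.0, 26.5, 37.5), c("S1-EQ", "night",  9.5, 23.6, 66.8),
    c("S2-NQ", "day",   33.7, 27.4, 38.9), c("S2-NQ", "night", 11.8, 29.4, 58.8),
    c("S3-SQ", "day",   39.7, 28.8, 31.5), c("S3-SQ", "night",  6.8, 12.5, 80.8),
    c("S4-WQ", "day",   31.5, 30.8, 37.6), c("S4-WQ", "night", 10.7, 21.1, 68.3))
  df <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  names(df) <- c("sensor_id", "period", "pct_optimal", "pct_suboptimal", "pct_critical")
  for (k in 3:5) df[[k]] <- as.numeric(df[[k]])
  df
}
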