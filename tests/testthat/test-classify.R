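test_that("unweighted stage means reproduce every published Average cell", {
  avg <- share_stage_averages(published_shares())
  pub <- published_averages()
  for (i in seq_len(nrow(pub))) {
    got <- avg[avg$sensor_id == pub$sensor_id[i] & avg$period == pub$period[i], ]
    expect_equal(round(got$pct_optimal, 1), pub$pct_optimal[i])
    expect_equal(round(got$pct_suboptimal, 1), pub$pct_suboptimal[i])
    expect_equal(round(got$pct_critical, 1), pub$pct_critical[i])
  }
})

test_that("aggregated shares reconstruct known per-category record counts", {
  # 30 optimal (T 25), 20 suboptimal-high (T 29), 50 critical-low (T 10),
  # all within vegetative daytime, RH/VPD held optimal via RH = 65
  day_hours <- make_records(c(rep(25, 30), rep(29, 20), rep(10, 50)), 65,
                            start = "2024-03-14 06:00:00")
  cal <- phenology_calendar()
  cl <- classify_records(day_hours, cal)
  sh <- aggregate_shares(cl, mode = "per_variable", include_average = FALSE)
  t_day <- sh[sh$variable == "T" & sh$period == "day" & sh$stage == "vegetative", ]
  expect_equal(t_day$n_records, 100L)
  expect_equal(t_day$pct_optimal, 30)
  expect_equal(t_day$pct_suboptimal, 20)
  expect_equal(t_day$pct_critical, 50)
})

test_that("share rows always sum to 100 within rounding and empty cells are flagged", {
  cl <- full_classified()
  sh <- aggregate_shares(cl[cl$sensor_id != "EXTERNAL", ])
  filled <- sh[sh$n_records > 0, ]
  expect_true(all(abs(filled$pct_optimal + filled$pct_suboptimal +
                        filled$pct_critical - 100) < 0.05))
  pv <- aggregate_shares(cl[cl$sensor_id != "EXTERNAL", ], mode = "per_variable",
                         include_average = FALSE)
  filled <- pv[pv$n_records > 0, ]
  expect_true(all(abs(filled$pct_optimal + filled$pct_suboptimal +
                        filled$pct_critical - 100) < 0.05))
  # an empty cell reports missing percentages, never zeros
  tiny <- classify_records(make_records(25, 65, start = "2024-03-14 12:00:00"),
                           phenology_calendar())
  sh0 <- aggregate_shares(tiny, include_average = FALSE)
  night <- sh0[sh0$period == "night", ]
  expect_equal(night$n_records, 0L)
  expect_true(is.na(night$pct_optimal))
})

test_that("critical time decomposes exactly into low and high drivers", {
  cal <- phenology_calendar()
  # vegetative night, RH pinned at 95: critically high by the > 80 cut
  night <- make_records(17, 95, start = "2024-03-14 00:00:00", interval_min = 5)
  cl <- classify_records(night[period_of(night$timestamp) == "night", ], cal)
  dec <- critical_driver_decomposition(cl)
  rh_night <- dec[dec$variable == "RH" & dec$period == "night", ]
  expect_equal(rh_night$pct_critical_high, 100)
  expect_equal(rh_night$pct_critical_low, 0)

  # constructed half below / half above the critical temperature cuts
  half <- make_records(c(rep(10, 72), rep(40, 72)), 65,
                       start = "2024-03-14 06:00:00")
  clh <- classify_records(half, cal)
  dech <- critical_driver_decomposition(clh)
  t_day <- dech[dech$variable == "T" & dech$period == "day", ]
  expect_equal(t_day$pct_critical_low, 50)
  expect_equal(t_day$pct_critical_high, 50)

  # decomposition totals reconcile with the per-variable critical shares
  cl_full <- full_classified()
  internal <- cl_full[cl_full$sensor_id == "S1-EQ", ]
  dec_full <- critical_driver_decomposition(internal)
  pv <- aggregate_shares(internal, mode = "per_variable", include_average = FALSE)
  m <- merge(dec_full, pv, by = c("stage", "period", "variable"))
  expect_true(all(abs(m$pct_critical_low + m$pct_critical_high - m$pct_critical) < 1e-9))
})

test_that("daily status follows the majority rule with a flagged fallback", {
  cal <- phenology_calendar()
  mk_day <- function(t_day, rh_day, t_night, rh_night) {
    rbind(make_records(rep(t_night, 72), rh_night, start = "2024-03-14 00:00:00"),
          make_records(rep(t_day, 144), rh_day, start = "2024-03-14 06:00:00"),
          make_records(rep(t_night, 72), rh_night, start = "2024-03-14 18:00:00"))
  }
  # optimal T and RH all day and night, VPD whatever follows: >= 2 votes decide
  d1 <- classify_records(mk_day(25, 65, 17, 60), cal)
  st1 <- daily_status(d1)
  expect_true(st1$pct_optimal_T > 50 && st1$pct_optimal_RH > 50)
  expect_equal(as.character(st1$status), "optimal")
  expect_true(st1$rule_satisfied)

  # everything critical all day
  d2 <- classify_records(mk_day(40, 10, 5, 10), cal)
  st2 <- daily_status(d2)
  expect_equal(as.character(st2$status), "critical")
  expect_true(st2$rule_satisfied)

  # a day with a fully missing variable is excluded with a message
  d3 <- d1
  d3$cat_RH <- factor(NA_character_, levels = category_levels())
  expect_message(out <- daily_status(d3), "excluded")
  expect_null(out)
})

test_that("the explicit three-way vote cases resolve as specified", {
  # build percentage rows directly and exercise the decision logic through
  # daily_status on crafted series: two variables > 50% optimal wins
  cal <- phenology_calendar()
  recs <- rbind(
    make_records(rep(25, 100), 65, start = "2024-03-14 06:00:00"),  # optimal T/RH
    make_records(rep(40, 44), 65, start = "2024-03-14 14:20:00"))   # critical T tail
  cl <- classify_records(recs, cal)
  st <- daily_status(cl)
  expect_true(st$pct_optimal_T > 50 && st$pct_optimal_RH > 50)
  expect_equal(as.character(st$status), "optimal")

  # no category reaching two >50% votes falls back, flagged
  mixed <- rbind(
    make_records(rep(25, 80), 65, start = "2024-03-14 06:00:00"),
    make_records(rep(10, 64), 30, start = "2024-03-14 12:40:00"))
  clm <- classify_records(mixed, cal)
  stm <- daily_status(clm)
  votes <- sapply(category_levels(), function(cc)
    sum(stm[paste0("pct_", cc, "_", c("T", "RH", "VPD"))] > 50))
  if (all(votes < 2)) expect_false(stm$rule_satisfied)
  expect_s3_class(stm$status, "factor")
})

test_that("the daily status table is time-ordered and complete on the demo cycle", {
  cl <- full_classified()
  daily <- daily_status_table(cl)
  expect_equal(nrow(daily), 190)
  expect_true(!is.unsorted(daily$date))
  pct_cols <- grep("^pct_", names(daily), value = TRUE)
  for (v in c("T", "RH", "VPD")) {
    tot <- rowSums(daily[grep(paste0("_", v, "$"), pct_cols, value = TRUE)])
    expect_true(all(abs(tot - 100) < 0.05))
  }
})
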