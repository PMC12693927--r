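test_that("descriptive statistics collapse correctly for constant series", {
  rec <- make_records(rep(21.5, 576), rep(60, 576))  # two full days
  tab <- descriptive_table(rec, phenology_calendar())
  t_row <- tab[tab$variable == "T", ]
  expect_equal(t_row$mean, 21.5)
  expect_equal(t_row$min_absolute, 21.5)
  expect_equal(t_row$max_absolute, 21.5)
  expect_equal(t_row$mean_of_min, 21.5)
  expect_equal(t_row$mean_of_max, 21.5)
})

test_that("daily extrema means are the means of the per-day extrema", {
  day1 <- seq(10, 30, length.out = 288)
  day2 <- seq(12, 34, length.out = 288)
  rec <- make_records(c(day1, day2), 60)
  tab <- descriptive_table(rec, phenology_calendar())
  t_row <- tab[tab$variable == "T", ]
  expect_equal(t_row$mean_of_min, 11)
  expect_equal(t_row$mean_of_max, 32)
  expect_equal(t_row$min_absolute, 10)
  expect_equal(t_row$max_absolute, 34)
})

test_that("extremum ordering holds for every row of the demo simulation", {
  sim <- full_sim()
  tab <- descriptive_table(sim$truth, sim$calendar)
  expect_true(all(tab$min_absolute <= tab$mean_of_min + 1e-9))
  expect_true(all(tab$mean_of_min <= tab$mean_of_max))
  expect_true(all(tab$mean_of_max <= tab$max_absolute + 1e-9))
  expect_true(all(tab$mean_of_min <= tab$mean & tab$mean <= tab$mean_of_max))
})

test_that("one-way ANOVA matches hand decomposition and conserves total SS", {
  res <- one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$ss_between, 13.5)
  expect_equal(res$ss_within, 4)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 4)
  expect_equal(res$f_value, 13.5)
  expect_equal(res$p_value, pf(13.5, 1, 4, lower.tail = FALSE))

  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$f_value, 0)

  set.seed(3)
  g <- list(rnorm(10), rnorm(12, 1), rnorm(9, -1))
  res2 <- one_way_anova(g)
  all_vals <- unlist(g)
  expect_equal(res2$ss_between + res2$ss_within,
               sum((all_vals - mean(all_vals))^2))
  expect_error(one_way_anova(list(c(1, 1), c(2, 2))), "undefined")
  expect_error(one_way_anova(list(c(1, 2))), ">= 2 groups")
})

test_that("ANOVA agrees with the reference implementation on random inputs", {
  set.seed(17)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    g <- lapply(seq_len(k), function(i) rnorm(sample(5:30, 1), mean = runif(1, -2, 2)))
    mine <- one_way_anova(g)
    df <- data.frame(value = unlist(g),
                     group = factor(rep(seq_len(k), lengths(g))))
    ref <- summary(aov(value ~ group, data = df))[[1]]
    expect_equal(mine$f_value, ref$`F value`[1], tolerance = 1e-8)
    expect_equal(mine$p_value, ref$`Pr(>F)`[1], tolerance = 1e-8)
    expect_equal(mine$ss_between, ref$`Sum Sq`[1], tolerance = 1e-8)
  }
})

test_that("internal-external comparison recovers constructed offsets", {
  cal <- phenology_calendar()
  internal <- make_records(rep(20, 576), rep(70, 576))
  ext <- internal; ext$sensor_id <- "EXTERNAL"
  same <- internal_external_comparison(internal, ext, cal)
  expect_equal(same$overall$t_diff_c, 0)
  expect_equal(same$overall$rh_exceedance_pct, 0)

  warmer <- internal; warmer$temp_c <- warmer$temp_c + 2
  cmp <- internal_external_comparison(warmer, ext, cal)
  expect_equal(cmp$overall$t_diff_c, 2)
  expect_equal(cmp$by_period$t_diff_c, c(2, 2))
  expect_equal(cmp$by_stage$t_diff_c, 2)
  expect_error(internal_external_comparison(
    internal, data.frame(date = as.Date("2030-01-01"), tmax_c = 1, tmin_c = 0,
                         rhmean_pct = 50), cal), "no overlap")
})

test_that("the simulator round-trips its configured day/night temperature asymmetry", {
  sim <- full_sim()
  cmp <- internal_external_comparison(
    sim$truth[sim$truth$sensor_id != "EXTERNAL", ],
    sim$truth[sim$truth$sensor_id == "EXTERNAL", ], sim$calendar)
  cfg <- sim$config
  w <- sim$calendar$stages$duration_days / sum(sim$calendar$stages$duration_days)
  conf_day <- sum(w * cfg$stage_means$t_day) + mean(cfg$quadrant_offsets$t_offset) -
    cfg$external_means[["t_day"]]
  conf_night <- sum(w * cfg$stage_means$t_night) + mean(cfg$quadrant_offsets$t_offset) -
    cfg$external_means[["t_night"]]
  expect_equal(cmp$by_period$t_diff_c[cmp$by_period$period == "day"],
               unname(conf_day), tolerance = 0.3)
  expect_equal(cmp$by_period$t_diff_c[cmp$by_period$period == "night"],
               unname(conf_night), tolerance = 0.3)
  # the day/night contrast mirrors a passively ventilated cover: larger by day
  expect_gt(cmp$by_period$t_diff_c[cmp$by_period$period == "day"],
            cmp$by_period$t_diff_c[cmp$by_period$period == "night"])
})

test_that("the PAR transmission coefficient is the mean pairwise ratio", {
  expect_equal(transmission_coefficient(100, 100), 1)
  out <- runif(50, 100, 1000)
  expect_equal(transmission_coefficient(0.6 * out, out), 0.6)
  expect_equal(transmission_coefficient(120, 200), 0.6)
  expect_warning(tc <- transmission_coefficient(c(60, 50), c(100, 0)), "dropped")
  expect_equal(tc, 0.6)
  expect_error(suppressWarnings(transmission_coefficient(1, 0)), "no valid")
})

test_that("economic indicators follow from the category weights", {
  eco <- economics(c(first = 37507.7, second = 29591.8,
                     third = 16295.6, fourth = 4607.3),
                   plant_density = 1.14, total_cost = 30800.9,
                   gross_income = 44001.3)
  expect_equal(eco$total_yield_kg_ha, 88002.4, tolerance = 1e-6)
  expect_equal(round(eco$categories$share_pct[1:3], 1), c(42.6, 33.6, 18.5))
  expect_equal(round(eco$marketable_share_pct, 1), 76.2)
  expect_equal(eco$gross_profit, 13200.4)
  expect_equal(round(eco$benefit_cost_ratio, 1), 1.4)
  expect_equal(eco$benefit_cost_ratio * eco$total_cost, eco$gross_income)
  expect_equal(eco$yield_per_plant_kg, 88002.4 / 11400, tolerance = 1e-9)
  expect_equal(sum(eco$categories$share_pct), 100, tolerance = 0.1)

  equal4 <- economics(c(a = 5, b = 5, c = 5, d = 5), 1, 10, 20)
  expect_equal(equal4$categories$share_pct, rep(25, 4))
  expect_error(economics(c(a = 0, b = 0), 1, 10, 20), "zero")
})
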