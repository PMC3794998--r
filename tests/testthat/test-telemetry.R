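test_that("great-circle distances match closed-form values", {
  expect_equal(great_circle_km(70, -150, 70, -150), 0)
  expect_equal(great_circle_km(0, 0, 0, 180), 6371.0088 * pi, tolerance = 1e-9)
  expect_equal(great_circle_km(10, 37, 11, 37), 6371.0088 * pi / 180,
               tolerance = 1e-9)
  skip_if_not_installed("geosphere")
  ref <- geosphere::distHaversine(c(-150, 70), c(-140, 72), r = 6371008.8) / 1000
  expect_equal(great_circle_km(70, -150, 72, -140), ref, tolerance = 1e-9)
})

test_that("the season split follows the calendar-month rule", {
  expect_equal(season_of(as.POSIXct("2006-01-15", tz = "UTC")), "ice_bound")
  expect_equal(season_of(as.POSIXct("2006-07-04", tz = "UTC")), "open_water")
  expect_equal(season_of(as.POSIXct("2006-05-31 23:59:59", tz = "UTC")),
               "ice_bound")
  expect_equal(season_of(as.POSIXct("2006-06-01 00:00:00", tz = "UTC")),
               "open_water")
  expect_equal(season_of(as.POSIXct("2006-12-01", tz = "UTC")), "ice_bound")
})

test_that("the speed filter removes injected violations and is idempotent", {
  tr <- stationary_track()
  expect_identical(speed_filter(tr)$records, tr$records)

  spec <- movement_regime_spec(seed = 9)
  tr1 <- simulate_track(spec, inject_outliers = 1L)
  f1 <- speed_filter(tr1)
  expect_equal(nrow(f1$filter_log), 1)
  expect_true(all(sealmix:::implied_speeds(f1$records) <= 2))
  # the removed point is the injected teleport (500 km from its neighbour)
  clean <- simulate_track(spec)
  expect_equal(unname(as.matrix(f1$records[, c("lat", "lon")])),
               unname(as.matrix(clean$records[, c("lat", "lon")])))
  # idempotence
  f2 <- speed_filter(f1)
  expect_identical(f2$records, f1$records)
  # an irreconcilable 2-point teleport reduces to a single retained fix
  f3 <- speed_filter(telemetry_track("x", data.frame(
    timestamp = as.POSIXct("2006-01-01", tz = "UTC") + c(0, 3600),
    lat = c(0, 50), lon = 0)))
  expect_equal(nrow(f3$records), 1)
})

test_that("seasonal comparisons report NA for a missing season", {
  rec <- data.frame(
    timestamp = as.POSIXct("2006-01-10", tz = "UTC") + 86400 * (0:9),
    lat = 70 + (0:9) / 50, lon = -150)
  tr <- telemetry_track("winter_only", rec)
  s <- seasonal_distance_test(tr, n_perm = 99, seed = 1)
  expect_true(is.na(s$p))
  expect_true(is.na(s$open_water[["mean"]]))
  expect_equal(s$ice_bound[["n"]], 10)
  expect_gte(s$ice_bound[["max"]], s$ice_bound[["mean"]])
})

test_that("a strong seasonal contrast is detected, deterministically", {
  tr <- simulate_track(movement_regime_spec(winter_sd_km = 5,
                                            summer_mean_km = 800, seed = 12))
  s1 <- seasonal_distance_test(tr, n_perm = 999, seed = 4)
  expect_lte(s1$p, 0.001)
  expect_identical(s1$p, seasonal_distance_test(tr, n_perm = 999, seed = 4)$p)
})

test_that("haulout summaries follow the daily mid-range rule", {
  # constant series: strict inequality means exceedance 0 everywhere
  hs_const <- haulout_summary(make_haulout_series(rep(0.4, 24), 3))
  expect_true(all(hs_const$exceedance == 0))

  # 2-day toy with a 6-hour elevated block: mid-range = 0.5
  prof <- rep(0.2, 24); prof[7:12] <- 0.8   # hours 6..11
  hs <- haulout_summary(make_haulout_series(prof, 2))
  expect_equal(hs$exceedance[7:12], rep(1, 6))
  expect_equal(hs$exceedance[-(7:12)], rep(0, 18))
  expect_equal(hs$n_days, 2)
  expect_equal(hs$min_dry_minutes, 0.2 * 60)

  # all-wet day: wet bout spans the day
  prof2 <- rep(0, 24)
  hs2 <- haulout_summary(make_haulout_series(prof2, 1))
  expect_gte(hs2$longest_wet_bout_h, 24)

  # exceedance invariant under positive scaling of a day's values (min = 0)
  prof3 <- rep(0, 24); prof3[10:15] <- c(0.2, 0.5, 0.9, 0.9, 0.5, 0.2)
  hs3a <- haulout_summary(make_haulout_series(prof3, 2))
  hs3b <- haulout_summary(make_haulout_series(prof3 * 0.5, 2))
  expect_equal(hs3a$exceedance, hs3b$exceedance)

  # timestamps survive a CSV round trip even when midnight prints date-only
  s_rt <- make_haulout_series(prof, 2)
  tf <- withr::local_tempfile(fileext = ".csv")
  write.csv(s_rt, tf, row.names = FALSE)
  hs_rt <- haulout_summary(read.csv(tf))
  expect_equal(hs_rt$exceedance, hs$exceedance)

  # incomplete days are excluded; all days incomplete is an error
  s <- make_haulout_series(prof, 2)
  expect_error(haulout_summary(s[s$timestamp < s$timestamp[15], ]),
               "complete day")
})

test_that("monthly localization aggregates by calendar month per animal", {
  tr <- simulate_track(movement_regime_spec(obs_per_month = 6, seed = 3))
  tab <- monthly_localization(list(tr))
  expect_equal(nrow(tab), 12)
  expect_equal(unique(tab$n), 6)
  # summer months exceed winter months for the regime fixture
  month_num <- as.integer(substr(tab$month, 6, 7))
  expect_gt(min(tab$mean_distance_km[month_num %in% 7:10]),
            max(tab$mean_distance_km[month_num %in% c(1, 2, 3)]))
  # a stationary track stays within noise scale
  tab0 <- monthly_localization(stationary_track(48))
  expect_true(all(tab0$mean_distance_km < 1))
})
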