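mk_monthly <- function(rows) {
  tibble::tibble(
    cell_id = rows$cell %||% "C01",
    year = rows$year,
    month = rows$month,
    tmean_c = rows$tmean
  )
}

test_that("seasonal aggregation averages months with the December shift", {
  m <- mk_monthly(list(year = 2015L, month = 6:8, tmean = c(20, 24, 28)))
  out <- seasonal_aggregate(m)
  expect_equal(out$tmean_c[out$season == "summer"], 24.0)

  winter <- mk_monthly(list(year = c(2014L, 2015L, 2015L),
                            month = c(12L, 1L, 2L),
                            tmean = c(8, 6, 7)))
  out <- seasonal_aggregate(winter)
  w <- out[out$season == "winter", ]
  expect_equal(w$year, 2015)
  expect_equal(w$tmean_c, 7.0)
})

test_that("seasonal aggregation matches a group-by oracle and drops gaps", {
  set.seed(11)
  m <- tidyr::expand_grid(cell_id = c("C01", "C02"), year = 2014:2016,
                          month = 1:12) |>
    dplyr::mutate(tmean_c = rnorm(dplyr::n(), 15, 8),
                  ppt_mm = abs(rnorm(dplyr::n(), 30, 20)))
  out <- seasonal_aggregate(m)
  # independent oracle: reassign months to seasons and average directly
  season_of <- c("winter", "winter", "spring", "spring", "spring", "summer",
                 "summer", "summer", "fall", "fall", "fall", "winter")
  mo <- m |>
    dplyr::mutate(season = season_of[month],
                  syear = year + (month == 12))
  for (i in sample(nrow(out), 10)) {
    ref <- mo[mo$cell_id == out$cell_id[i] & mo$syear == out$year[i] &
                mo$season == out$season[i], ]
    expect_equal(out$tmean_c[i], mean(ref$tmean_c), tolerance = 1e-12)
    expect_equal(out$ppt_mm[i], mean(ref$ppt_mm), tolerance = 1e-12)
  }
  # winters of the first year lack the prior December and must be absent
  expect_false(any(out$season == "winter" & out$year == 2014))
  # permutation invariance over input row order
  out2 <- seasonal_aggregate(m[sample(nrow(m)), ])
  expect_equal(out, out2)
})

mk_daily <- function(cell, dates, tmax) {
  tibble::tibble(cell_id = cell, date = dates, tmax_c = tmax,
                 srad_wm2 = 300, dayl_hours = 12)
}

test_that("hot-day thresholds are pooled 90th percentiles per month", {
  dates <- seq(as.Date("2009-06-01"), as.Date("2018-06-30"), by = "day")
  june <- dates[format(dates, "%m") == "06"]
  d <- mk_daily("C01", june, 30.0)
  thr <- derive_hot_thresholds(d, 2009:2018)
  expect_equal(thr$threshold_c[thr$month == 6], 30.0)

  set.seed(4)
  vals <- runif(length(june), 20, 40)
  d2 <- mk_daily("C01", june, vals)
  thr2 <- derive_hot_thresholds(d2, 2009:2018)
  expect_equal(thr2$threshold_c, oracle_quantile(vals, 0.9),
               tolerance = 1e-12)

  # too few pooled days is an error, not a silent guess
  expect_error(derive_hot_thresholds(mk_daily("C01", june[1:20], 25), 2009:2018),
               class = "yieldgap_insufficient_data")
})

test_that("thresholds track a monotone seasonal cycle", {
  dates <- seq(as.Date("2009-01-01"), as.Date("2013-12-31"), by = "day")
  mo <- as.integer(format(dates, "%m"))
  set.seed(9)
  d <- mk_daily("C01", dates, mo * 2 + rnorm(length(dates), 0, 0.5))
  thr <- derive_hot_thresholds(d, 2009:2013)
  expect_true(all(diff(thr$threshold_c[order(thr$month)]) > 0))
})

test_that("hot days are counted with strict exceedance", {
  june <- seq(as.Date("2015-06-01"), as.Date("2015-06-30"), by = "day")
  tmax <- rep(25, 30)
  tmax[c(3, 10, 20)] <- 31
  d <- mk_daily("C01", june, tmax)
  thr <- tibble::tibble(cell_id = "C01", month = 6L, threshold_c = 30)
  out <- count_hot_days(d, thr)
  expect_equal(out$hotdays, 3L)
  # at the threshold exactly is not "exceeding"
  thr$threshold_c <- 31
  expect_equal(count_hot_days(d, thr)$hotdays, 0L)
  expect_error(count_hot_days(d, thr[0, ]), class = "yieldgap_config_error")
})

test_that("thresholds flag close to 10% of their own calibration days", {
  sim <- small_sim()
  yrs <- sim$config$years
  d <- sim$daily |>
    dplyr::filter(as.integer(format(date, "%Y")) %in% yrs)
  thr <- derive_hot_thresholds(d, yrs)
  counts <- count_hot_days(d, thr)
  frac <- sum(counts$hotdays) / nrow(d)
  expect_gt(frac, 0.09)
  expect_lt(frac, 0.11)
})

test_that("long-term climatology reduces to means and flags sparse cells", {
  m <- tidyr::expand_grid(cell_id = "C01", year = 2009:2018, month = 1:12) |>
    dplyr::mutate(tmean_c = 12)
  ltm <- long_term_climatology(m, 2009:2018)
  expect_equal(ltm$ltm_tmean_c_annual, 12)
  expect_equal(ltm$ltm_tmean_c_summer, 12)

  m2 <- m |> dplyr::mutate(tmean_c = rep(10:19, each = 12))
  ltm2 <- long_term_climatology(m2, 2009:2018)
  expect_equal(ltm2$ltm_tmean_c_annual, 14.5)

  set.seed(2)
  m3 <- m |> dplyr::mutate(tmean_c = rnorm(dplyr::n(), 15, 5))
  ltm3 <- long_term_climatology(m3, 2009:2018)
  expect_equal(ltm3$ltm_tmean_c_annual, mean(m3$tmean_c), tolerance = 1e-12)
  expect_equal(ltm3$ltm_tmean_c_summer,
               mean(m3$tmean_c[m3$month %in% 6:8]), tolerance = 1e-12)

  expect_error(long_term_climatology(m[m$year < 2015, ], 2009:2018),
               class = "yieldgap_insufficient_data")
})

test_that("orchards join to their nearest climate cell, ties to lowest id", {
  cells <- tibble::tibble(cell_id = c("C01", "C02", "C03"),
                          latitude = c(35, 36, 37), longitude = -120)
  plots <- tibble::tibble(orchard_id = c("A", "B"),
                          latitude = c(35.1, 36.5), longitude = -120)
  out <- assign_cells(plots, cells)
  expect_equal(out$cell_id, c("C01", "C02"))  # 36.5 ties C02/C03 -> lowest id
})

test_that("the feature table matches its manifest and is deterministic", {
  ft <- small_features()
  manifest <- features_manifest()
  keys <- c("plot_id", "orchard_id", "cell_id", "year",
            "yield_kernel_lbs_acre")
  expect_equal(setdiff(names(ft), keys), manifest$column)
  expect_false(anyNA(ft))
  sim <- small_sim()
  ft2 <- suppressMessages(
    build_feature_table(sim$plots, sim$monthly, sim$daily))
  expect_identical(ft, ft2)
  # row order of the climate inputs must not matter
  ft3 <- suppressMessages(build_feature_table(
    sim$plots, sim$monthly[sample(nrow(sim$monthly)), ], sim$daily))
  expect_equal(ft, ft3)
})

test_that("plot-years without previous-year climate are dropped", {
  sim <- small_sim()
  first <- min(sim$config$years)
  monthly_trunc <- sim$monthly |> dplyr::filter(year >= first)
  daily_trunc <- sim$daily |>
    dplyr::filter(as.integer(format(date, "%Y")) >= first)
  expect_message(
    ft <- build_feature_table(sim$plots, monthly_trunc, daily_trunc),
    "Dropped"
  )
  # the first year has no previous-year lag at all; the second loses its
  # previous winter (which would need December two years before the span)
  expect_false(first %in% ft$year)
  expect_equal(sort(unique(ft$year)), (first + 2):max(sim$config$years))
})

test_that("feature values agree with hand-computed aggregates", {
  sim <- small_sim()
  ft <- small_features()
  row <- ft[ft$year == 2014, ][1, ]
  m <- sim$monthly
  pick <- function(yr, mo) {
    m[m$cell_id == row$cell_id & m$year == yr & m$month == mo, ]
  }
  expect_equal(row$tmax_m06_cur, pick(2014, 6)$tmax_c)
  expect_equal(row$ppt_m11_prev, pick(2013, 11)$ppt_mm)
  expect_equal(row$tmean_winter_cur,
               mean(c(pick(2013, 12)$tmean_c, pick(2014, 1)$tmean_c,
                      pick(2014, 2)$tmean_c)),
               tolerance = 1e-12)
  daily <- sim$daily |>
    dplyr::filter(cell_id == row$cell_id,
                  format(date, "%Y-%m") == "2014-07")
  expect_equal(row$srad_m07_cur, mean(daily$srad_wm2), tolerance = 1e-12)
  # seasonal means preserve the tmin <= tmean <= tmax ordering
  expect_true(all(ft$tmin_summer_cur <= ft$tmean_summer_cur &
                    ft$tmean_summer_cur <= ft$tmax_summer_cur))
})
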