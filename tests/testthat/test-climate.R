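test_that("division aggregation equals a brute-force group-and-mean oracle", {
  set.seed(101)
  for (rep in 1:5) {
    st <- data.frame(
      station_id = sample(sprintf("S%02d", 1:6), 60, replace = TRUE),
      division = sample(1:3, 60, replace = TRUE),
      year = sample(2000:2002, 60, replace = TRUE),
      month = sample(1:12, 60, replace = TRUE),
      temp_c = round(stats::rnorm(60, 8, 5), 2)
    )
    st <- st[!duplicated(st[, c("station_id", "year", "month")]), ]
    # a station reports for exactly one division
    st$division <- ave(st$division, st$station_id, FUN = function(x) x[1])
    agg <- aggregate_division_monthly(st)
    for (i in sample(nrow(agg), min(10, nrow(agg)))) {
      sel <- st$division == agg$division[i] & st$year == agg$year[i] &
        st$month == agg$month[i]
      expect_equal(agg$mean_temp_c[i], mean(st$temp_c[sel]), tolerance = 1e-12)
      expect_identical(agg$n_stations[i], sum(sel))
    }
  }
})

test_that("aggregation handles the single-station case and rejects bad input", {
  one <- data.frame(station_id = "A", division = 1, year = 2000, month = 2,
                    temp_c = 5.0)
  agg <- aggregate_division_monthly(one)
  expect_equal(agg$mean_temp_c, 5.0)
  expect_identical(agg$n_stations, 1L)

  three <- data.frame(station_id = c("A", "B", "C"), division = 1,
                      year = 2000, month = 2, temp_c = c(4, 5, 6))
  expect_equal(aggregate_division_monthly(three)$mean_temp_c, 5.0)

  dup <- rbind(one, one)
  expect_error(aggregate_division_monthly(dup), "duplicate.*A\\|2000\\|2")
  expect_error(aggregate_division_monthly(one[0, ]), "empty")
  bad <- one; bad$temp_c <- NA
  expect_error(aggregate_division_monthly(bad), "non-finite")
})

test_that("window_mean averages the requested months and wraps the year", {
  ser <- make_division_series(1, years = 1949:1951,
                              temp_fun = function(d, y, m) 10)
  expect_equal(window_mean(ser, 1950, 5, 4), 10)

  ser2 <- make_division_series(1, years = 1950:1950,
                               temp_fun = function(d, y, m) 2 * m)
  # Feb=4, Mar=6, Apr=8, May=10 -> mean 7
  expect_equal(window_mean(ser2, 1950, 5, 4), 7)

  # February end with n=4 reaches Nov and Dec of the prior year
  ser3 <- make_division_series(1, years = 1949:1950,
                               temp_fun = function(d, y, m) {
                                 if (y == 1949 && m == 11) 1
                                 else if (y == 1949 && m == 12) 2
                                 else if (y == 1950 && m == 1) 3
                                 else if (y == 1950 && m == 2) 4
                                 else 99
                               })
  expect_equal(window_mean(ser3, 1950, 2, 4), mean(c(1, 2, 3, 4)))

  # missing month is an error naming the gap
  gap <- ser2[!(ser2$month == 3), ]
  class(gap) <- class(ser2)
  expect_error(window_mean(gap, 1950, 5, 4), "missing month 1950-03")
})

test_that("window_mean is invariant to input record order", {
  set.seed(7)
  ser <- make_division_series(2, years = 2000:2001,
                              temp_fun = function(d, y, m) rnorm(1))
  shuf <- ser[sample(nrow(ser)), ]
  class(shuf) <- class(ser)
  expect_equal(window_mean(ser, 2001, 3, 6, division = 2),
               window_mean(shuf, 2001, 3, 6, division = 2))
})

test_that("seasonal_trend recovers a constructed linear warming exactly", {
  ser <- make_division_series(1, years = 1900:1999, months = 2:5,
                              temp_fun = function(d, y, m) {
                                5 + 0.01 * (y - 1900) + m / 10
                              })
  tr <- seasonal_trend(ser, season_months = 2:5)
  expect_equal(tr$slope_c_per_year, 0.01, tolerance = 1e-10)
  expect_equal(tr$total_change_c, 0.01 * 99, tolerance = 1e-8)
  expect_lt(tr$p_value, 1e-12)
  # anomalies are centred on the full-record baseline
  expect_lt(abs(mean(tr$anomalies)), 1e-9)

  flat <- make_division_series(1, years = 1900:1909, months = 2:5,
                               temp_fun = function(d, y, m) 4)
  tf <- seasonal_trend(flat, season_months = 2:5)
  expect_equal(tf$slope_c_per_year, 0, tolerance = 1e-12)
  expect_equal(tf$total_change_c, 0, tolerance = 1e-12)
})

test_that("trend on anomalies equals trend on raw seasonal means", {
  set.seed(11)
  ser <- make_division_series(1, years = 1950:2009, months = 2:5,
                              temp_fun = function(d, y, m) {
                                3 + 0.008 * (y - 1950) + stats::rnorm(1)
                              })
  tr <- seasonal_trend(ser, season_months = 2:5)
  raw_yearly <- tapply(ser$mean_temp_c, ser$year, mean)
  raw_slope <- unname(stats::coef(stats::lm(raw_yearly ~ as.integer(names(raw_yearly))))[2])
  expect_equal(tr$slope_c_per_year, raw_slope, tolerance = 1e-9)
})

test_that("years with incomplete seasonal coverage are excluded with a warning", {
  ser <- make_division_series(1, years = 1990:1999, months = 2:5,
                              temp_fun = function(d, y, m) y - 1990)
  ser <- ser[!(ser$year == 1995 & ser$month == 3), ]
  class(ser) <- c("division_monthly", "data.frame")
  expect_warning(tr <- seasonal_trend(ser, season_months = 2:5),
                 "1 year\\(s\\) excluded")
  expect_false(1995 %in% tr$years)
})

test_that("statewide series is the unweighted mean over divisions", {
  ser <- make_division_series(1:3, years = 2000,
                              temp_fun = function(d, y, m) d * 10)
  sw <- statewide_series(ser)
  expect_true(all(sw$mean_temp_c == 20))
  expect_true(all(sw$n_stations == 3L))
})

test_that("USHCN fixed-width adapter parses values and division map", {
  line1 <- sprintf("%-11s %4d%s", "USH00331234", 1950,
                   paste(sprintf("%6d  a", c(-310, -190, 340, 940, 1530, 2020,
                                             2230, 2150, 1800, 1160, 530, -60)),
                         collapse = ""))
  line2 <- sprintf("%-11s %4d%s", "USH00335678", 1950,
                   paste(sprintf("%6d  a", c(-9999, rep(100, 11))),
                         collapse = ""))
  f <- withr::local_tempfile(lines = c(line1, line2))
  st <- read_ushcn_fixed(f, c(USH00331234 = 10L, USH00335678 = 2L))
  expect_equal(nrow(st), 12 + 11)
  expect_equal(st$temp_c[st$station_id == "USH00331234" & st$month == 5], 15.3)
  expect_false(1 %in% st$month[st$station_id == "USH00335678"])
  expect_identical(unique(st$division[st$station_id == "USH00331234"]), 10L)
})
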