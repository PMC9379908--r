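test_that("season extraction returns 122 calendar-ordered days, leap or not", {
  rec <- make_record(3, start_year = 2019)   # covers leap year 2020
  for (y in 2019:2021) {
    s <- extract_season(rec, y)
    expect_equal(nrow(s), 122)               # 31 + 30 + 31 + 30
    expect_true(all(diff(s$date) == 1))
    expect_equal(sum(s$rain_mm),
                 sum(rec$rain_mm[rec$date >= as.Date(sprintf("%d-03-01", y)) &
                                   rec$date <= as.Date(sprintf("%d-06-30", y))]))
  }
  # independent calendar enumeration oracle for the leap season
  expect_equal(length(seq(as.Date("2020-03-01"), as.Date("2020-06-30"), "day")),
               122)
  expect_error(extract_season(rec, 1990), "incomplete")
})

test_that("mean_daily_rate is the arithmetic mean of the 122 values", {
  expect_equal(mean_daily_rate(rep(0, 122)), 0)
  expect_equal(mean_daily_rate(rep(2.5, 122)), 2.5)
  set.seed(1)
  x <- rgamma(122, 1, 1)
  expect_equal(mean_daily_rate(x), sum(x) / 122)
  rates <- season_mean_rates(make_record(2))
  expect_equal(nrow(rates), 2)
})

test_that("rolling mean matches a nested-loop oracle and handles edges", {
  expect_equal(rolling_mean(rep(3, 15)), rep(3, 15))
  expect_equal(rolling_mean(1:10, width = 1), as.numeric(1:10))
  set.seed(2)
  x <- rnorm(20)
  got <- rolling_mean(x, width = 5)
  oracle <- numeric(20)
  for (i in 1:20) {                          # symmetric truncation
    h <- min(2, i - 1, 20 - i)
    acc <- 0
    for (j in (i - h):(i + h)) acc <- acc + x[j]
    oracle[i] <- acc / (2 * h + 1)
  }
  expect_equal(got, oracle)
  expect_error(rolling_mean(x, width = 4), "odd")
})

test_that("rolling mean commutes with affine transforms", {
  set.seed(3)
  x <- rnorm(30)
  expect_equal(rolling_mean(2 * x + 5, 11), 2 * rolling_mean(x, 11) + 5)
})

test_that("heavy-rain threshold is the reference 99th percentile", {
  rec <- make_record(4, start_year = 1950)
  # constant record: threshold equals the constant, every day qualifies
  const <- rec
  const$rain_mm <- 3
  thr <- heavy_rain_threshold(const, 1950:1953)
  expect_equal(thr, 3)
  expect_true(all(const$rain_mm >= thr))

  # order-statistic oracle on uniform draws
  set.seed(4)
  u <- rec
  u$rain_mm <- runif(nrow(u), 0, 10)
  thr_u <- heavy_rain_threshold(u, 1950:1953)
  x <- sort(u$rain_mm)
  n <- length(x)
  h <- (n - 1) * 0.99 + 1                    # type-7 plotting position
  oracle <- x[floor(h)] + (h - floor(h)) * (x[floor(h) + 1] - x[floor(h)])
  expect_equal(thr_u, oracle)
  expect_equal(thr_u, 9.9, tolerance = 0.02)
  # by construction the exceedance fraction is >= 1% and minimal
  frac <- mean(u$rain_mm >= thr_u)
  expect_gte(frac, 0.01)
  expect_lt(frac, 0.01 + 2 / n)
})

test_that("drought classes partition the SPI line at 0/-1/-1.5/-2", {
  expect_equal(as.character(classify_drought(c(0.5, -0.3, -1.2, -1.7, -2.5))),
               c("none", "mild", "moderate", "severe", "extreme"))
  # boundary values: "moderate and above" means SPI <= -1, severe <= -1.5
  expect_equal(as.character(classify_drought(c(0, -1, -1.5, -2))),
               c("mild", "moderate", "severe", "extreme"))
  expect_equal(as.character(classify_drought(-1.2)), "moderate")
})

test_that("decade summary counts months and heavy days like a hand count", {
  rec <- make_record(20, start_year = 1950, seed = 9)
  spis <- calc_spi(rec)
  thr <- heavy_rain_threshold(rec, 1950:1969)
  ds <- decade_summary(rec, spis, thr)
  expect_equal(ds$decade, c(1950, 1960))
  # independent counting oracle
  for (d in ds$decade) {
    yrs <- d:(d + 9)
    days <- do.call(rbind, lapply(yrs, function(y) extract_season(rec, y)))
    expect_equal(ds$heavy_day_pct[ds$decade == d],
                 100 * sum(days$rain_mm >= thr) / nrow(days))
    sp <- spis$spi[spis$year %in% yrs]
    expect_equal(ds$moderate_plus_drought_pct[ds$decade == d],
                 100 * sum(sp <= -1) / 40)
    expect_equal(ds$severe_plus_drought_pct[ds$decade == d],
                 100 * sum(sp <= -1.5) / 40)
  }
  # all-zero SPI decade has zero drought percentages
  spis0 <- spis
  spis0$spi <- 0
  ds0 <- decade_summary(rec, spis0, thr)
  expect_equal(ds0$moderate_plus_drought_pct, c(0, 0))
  expect_equal(ds0$severe_plus_drought_pct, c(0, 0))
  # partial decades are flagged and excluded by default
  rec25 <- make_record(25, start_year = 1950, seed = 9)
  expect_warning(decade_summary(rec25, calc_spi(rec25), thr), "incomplete")
})
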