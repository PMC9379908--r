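test_that("pearson matches the closed form and flags degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -2 * x + 5), -1)
  set.seed(40)
  a <- rnorm(10); b <- rnorm(10)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson(a, b), oracle)
  expect_warning(r0 <- pearson(rep(1, 5), x), "zero variance")
  expect_true(is.na(r0))
  expect_warning(r1 <- pearson(1:2, 2:3), "fewer than 3")
  expect_true(is.na(r1))
  expect_error(pearson(1:4, 1:5), "equal length")
})

test_that("run_study produces a consistent, deterministic report", {
  rec <- make_record(4, start_year = 2001, seed = 50)
  cfg <- study_config(grid = coarse_grid(14), model = fast_config())
  rep1 <- suppressWarnings(run_study(rec, cfg))
  rep2 <- suppressWarnings(run_study(rec, cfg))
  expect_identical(rep1$seasons, rep2$seasons)      # determinism
  expect_identical(rep1$correlations, rep2$correlations)
  expect_equal(nrow(rep1$seasons), 4)
  expect_true(all(rep1$seasons$stability > 0 & rep1$seasons$stability <= 1))
  expect_true(all(rep1$seasons$n_close >= 1))
  # season rows are internally consistent with their surfaces
  for (y in rep1$seasons$year) {
    s <- rep1$surfaces[[as.character(y)]]
    expect_equal(rep1$seasons$max_uptake[rep1$seasons$year == y],
                 max(s$uptake_kg_ha))
  }
  expect_true(all(abs(rep1$correlations$r) <= 1, na.rm = TRUE))
  gl <- glance(rep1)
  expect_equal(gl$n_seasons, 4)
  expect_identical(tidy(rep1), rep1$seasons)
})

test_that("study report round-trips through CSV for recomputation", {
  rec <- make_record(3, start_year = 2001, seed = 51)
  cfg <- study_config(grid = coarse_grid(21), model = fast_config())
  rep <- suppressWarnings(run_study(rec, cfg))
  dir <- withr::local_tempdir()
  write_study_report(rep, dir)
  seasons <- readr::read_csv(file.path(dir, "seasons.csv"),
                             show_col_types = FALSE)
  expect_equal(seasons$max_uptake, rep$seasons$max_uptake)
  # correlations recomputed from the persisted per-season table match
  r_disk <- suppressWarnings(pearson(seasons$mean_rate, seasons$max_uptake))
  r_mem <- rep$correlations$r[rep$correlations$x == "mean_rate" &
                                rep$correlations$y == "max_uptake" &
                                rep$correlations$series == "raw"]
  expect_equal(r_disk, r_mem)
  # per-season surface files restore the optimizer analytics
  y <- rep$seasons$year[1]
  s <- read_surface_csv(file.path(dir, sprintf("surface_%d.csv", y)))
  expect_equal(find_optimum(s)$uptake_kg_ha,
               rep$seasons$max_uptake[1])
})

test_that("a single-season study flags the empty correlation table", {
  rec <- make_record(1, seed = 52)
  cfg <- study_config(grid = coarse_grid(35), model = fast_config())
  ws <- capture_warnings(rep <- run_study(rec, cfg))
  expect_true(any(grepl("fewer than 3", ws)))
  expect_equal(nrow(rep$seasons), 1)
  expect_equal(nrow(rep$correlations), 0)
})

test_that("fixed strategy efficiency follows hand-computed ratios", {
  mk <- function(u) {
    s <- tibble::tibble(t1 = c(10, 10, 20), t2 = c(10, 20, 20),
                        uptake_kg_ha = u)
    structure(s, class = c("uptake_surface", class(s)))
  }
  # two toy seasons with known ratios at (10, 20): 80/100 and 90/120
  surfaces <- list(mk(c(50, 80, 100)), mk(c(120, 90, 60)))
  expect_equal(fixed_strategy_efficiency(surfaces, 10, 20),
               mean(c(80, 75)))
  # picking each season's own optimum gives 100%
  expect_equal(fixed_strategy_efficiency(list(mk(c(1, 2, 3))), 20, 20), 100)
  expect_error(fixed_strategy_efficiency(surfaces, 11, 19), "not on the grid")
})

test_that("leaching correlates positively with post-fertilization rain", {
  rec <- generate_weather(weather_preset("historic", n_years = 12,
                                         start_year = 2001, seed = 53))
  # widen the contrast: scale alternate seasons up to span dry -> wet
  fac <- rep(c(0.5, 1, 2), length.out = 12)
  rec$rain_mm <- rec$rain_mm *
    fac[as.integer(format(rec$date, "%Y")) - 2000]
  out <- leaching_rainfall_correlation(rec, fertilizer_schedule(14.4, 36),
                                       fast_config(), window = 21)
  expect_equal(nrow(out$data), 12)
  expect_gt(out$r, 0)
  # window 0 gives a zero vector: undefined, flagged
  expect_warning(
    out0 <- leaching_rainfall_correlation(rec, fertilizer_schedule(14.4, 36),
                                          fast_config(), window = 0),
    "zero variance")
  expect_true(is.na(out0$r))
})
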