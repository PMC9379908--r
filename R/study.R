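# Orchestration of the full multi-season study.

#' Configure a timing study
#'
#' @param grid a [timing_grid()]; the exhaustive default (1.2-day
#'   resolution) costs ~1711 season simulations per year, so exploratory
#'   runs usually pass a coarser grid.
#' @param model a [model_config()].
#' @param total_n,split_first seasonal fertilizer rate and first-pulse
#'   fraction shared by all pairs.
#' @param radius stability neighborhood radius (days).
#' @param tol close-to-optimal tolerance.
#' @param spi a [spi_config()].
#' @param heavy_ref_years reference years for the heavy-rain percentile
#'   (`NULL` to skip decade heavy-day percentages when the record does not
#'   cover them).
#' @param rolling_width width of the rolling means used for the smoothed
#'   correlation variants (years, odd).
#' @return list of class `study_config`.
#' @export
study_config <- function(grid = timing_grid(), model = model_config(),
                         total_n = 144, split_first = 1 / 3,
                         radius = 2.4, tol = 0.05,
                         spi = spi_config(), heavy_ref_years = NULL,
                         rolling_width = 11) {
  stopifnot(inherits(grid, "timing_grid"), inherits(model, "model_config"),
            inherits(spi, "spi_config"))
  structure(list(grid = grid, model = model, total_n = total_n,
                 split_first = split_first, radius = radius, tol = tol,
                 spi = spi, heavy_ref_years = heavy_ref_years,
                 rolling_width = rolling_width),
            class = "study_config")
}

#' Pearson product-moment correlation with degeneracy handling
#'
#' @param x,y numeric vectors of equal length.
#' @return Pearson r in `[-1, 1]`, or `NA` (with a warning) when fewer than
#'   3 complete pairs remain or either side has zero variance.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    warn("fewer than 3 complete pairs; correlation undefined")
    return(NA_real_)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("zero variance; correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "pearson")
}

#' Run the full timing study over a multi-year record
#'
#' For every complete season in the record: computes the uptake surface on
#' the configured grid, the precipitation-optimal pair, the close-to-optimal
#' set and season stability, plus the season's mean daily rate and mean
#' 1-month SPI. Aggregates decadal medians over all close-to-optimal uptakes
#' and timings, and Pearson correlations between precipitation metrics and
#' the optimizer outputs, on raw yearly values and on rolling means.
#'
#' @param record tibble `date`, `rain_mm` covering one or more complete
#'   seasons.
#' @param config a [study_config()].
#' @param years subset of seasons to run (default: all complete seasons).
#' @return object of class `study_report`: list with tibbles `seasons`,
#'   `decades`, `correlations`, the named list `surfaces`, and `config`.
#' @export
run_study <- function(record, config = study_config(), years = NULL) {
  stopifnot(inherits(config, "study_config"))
  yrs <- years %||% season_years(record)
  if (!length(yrs)) abort("record contains no complete season")

  spis <- calc_spi(record, config$spi)
  surfaces <- lapply(yrs, function(y) {
    compute_uptake_surface(extract_season(record, y), config$grid,
                           config$model, total_n = config$total_n,
                           split_first = config$split_first)
  })
  names(surfaces) <- yrs

  seasons <- purrr::map2_dfr(surfaces, yrs, function(s, y) {
    sm <- summarize_surface(s, radius = config$radius, tol = config$tol)
    sm$year <- as.integer(y)
    sm$mean_rate <- mean_daily_rate(extract_season(record, y))
    sm$mean_spi <- mean(spis$spi[spis$year == y], na.rm = TRUE)
    sm
  }) |>
    dplyr::select("year", "mean_rate", "mean_spi", dplyr::everything())

  decades <- study_decades(surfaces, seasons, record, spis, config)
  correlations <- study_correlations(seasons, config$rolling_width)

  structure(list(seasons = seasons, decades = decades,
                 correlations = correlations, surfaces = surfaces,
                 config = config),
            class = "study_report")
}

study_decades <- function(surfaces, seasons, record, spis, config) {
  close_all <- purrr::map2_dfr(surfaces, as.integer(names(surfaces)),
                               function(s, y) {
    cl <- close_to_optimal(s, tol = config$tol)
    cl$year <- y
    cl
  })
  close_all$decade <- (close_all$year %/% 10L) * 10L
  dec <- close_all |>
    dplyr::group_by(.data$decade) |>
    dplyr::summarise(
      median_close_uptake = median(.data$uptake_kg_ha),
      median_close_t1 = median(.data$t1),
      median_close_t2 = median(.data$t2),
      .groups = "drop")
  ncl <- seasons |>
    dplyr::mutate(decade = (.data$year %/% 10L) * 10L) |>
    dplyr::group_by(.data$decade) |>
    dplyr::summarise(mean_n_close = mean(.data$n_close),
                     n_years = dplyr::n(), .groups = "drop")
  out <- dplyr::left_join(dec, ncl, by = "decade")
  if (!is.null(config$heavy_ref_years)) {
    thr <- heavy_rain_threshold(record, config$heavy_ref_years)
    extra <- decade_summary(record, spis, thr, complete_only = FALSE)
    out <- dplyr::left_join(out, extra, by = "decade")
  }
  out
}

study_correlations <- function(seasons, rolling_width) {
  if (nrow(seasons) < 3) {
    warn("fewer than 3 seasons; correlation table empty")
    return(tibble::tibble(x = character(), y = character(),
                          series = character(), r = double(), n = integer()))
  }
  pairs <- list(
    c("mean_rate", "max_uptake"), c("mean_spi", "max_uptake"),
    c("mean_rate", "median_t1"), c("mean_rate", "median_t2"),
    c("mean_spi", "median_t1"), c("mean_spi", "median_t2"),
    c("median_t1", "median_t2"))
  sm <- seasons[order(seasons$year), ]
  purrr::map_dfr(pairs, function(p) {
    raw <- suppressWarnings(pearson(sm[[p[1]]], sm[[p[2]]]))
    rol <- suppressWarnings(pearson(rolling_mean(sm[[p[1]]], rolling_width),
                                    rolling_mean(sm[[p[2]]], rolling_width)))
    tibble::tibble(x = p[1], y = p[2],
                   series = c("raw", "rolling"), r = c(raw, rol),
                   n = nrow(sm))
  })
}

#' Uptake of a fixed timing strategy relative to each season's optimum
#'
#' For every season surface, the uptake at `(t1, t2)` divided by that
#' season's maximum uptake; returns the mean percentage over seasons. This
#' quantifies how well a farmer sticking to one historical timing pair would
#' do against the precipitation-optimal strategy.
#'
#' @param surfaces a `study_report`, or a list of uptake surfaces.
#' @param t1,t2 the fixed pair (must lie on every surface's grid).
#' @return mean efficiency in percent (0-100].
#' @export
fixed_strategy_efficiency <- function(surfaces, t1, t2) {
  if (inherits(surfaces, "study_report")) surfaces <- surfaces$surfaces
  eff <- vapply(surfaces, function(s) {
    s <- as_surface(s)
    eps <- 1e-8
    at <- which(abs(s$t1 - t1) < eps & abs(s$t2 - t2) < eps)
    if (!length(at)) abort(sprintf("pair (%g, %g) is not on the grid", t1, t2))
    100 * s$uptake_kg_ha[at[1]] / max(s$uptake_kg_ha)
  }, numeric(1))
  mean(eff)
}

#' Correlation of nitrogen leaching with post-fertilization rainfall
#'
#' Simulates every season at one fixed schedule and correlates the leached
#' N against the cumulative rainfall in the `window` days after the end of
#' the second fertilizer pulse.
#'
#' @param record tibble `date`, `rain_mm`.
#' @param schedule a [fertilizer_schedule()].
#' @param config a [model_config()].
#' @param window days of rainfall accumulated after the final pulse
#'   (default 21).
#' @return list with `r` (Pearson), and the per-season tibble `data`
#'   (`year`, `leached_n`, `rain_after_mm`).
#' @export
leaching_rainfall_correlation <- function(record, schedule,
                                          config = model_config(),
                                          window = 21) {
  yrs <- season_years(record)
  if (length(yrs) < 3) abort("need at least 3 complete seasons")
  dat <- purrr::map_dfr(yrs, function(y) {
    season <- extract_season(record, y)
    res <- simulate_season(season, schedule, config)
    i0 <- floor(schedule$t2 + schedule$pulse_duration)
    idx <- seq(i0 + 1, min(i0 + window, nrow(season)))
    tibble::tibble(year = y, leached_n = res$leached_n,
                   rain_after_mm = if (window > 0) sum(season$rain_mm[idx]) else 0)
  })
  r <- pearson(dat$rain_after_mm, dat$leached_n)
  list(r = r, data = dat)
}

#' Write the study report tables to a directory
#'
#' Writes `seasons.csv`, `decades.csv`, `correlations.csv` and one
#' `surface_<year>.csv` per season, so every analytic can be recomputed
#' from disk without re-simulation.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$seasons, file.path(dir, "seasons.csv"))
  readr::write_csv(report$decades, file.path(dir, "decades.csv"))
  readr::write_csv(report$correlations, file.path(dir, "correlations.csv"))
  for (y in names(report$surfaces))
    write_surface_csv(report$surfaces[[y]],
                      file.path(dir, sprintf("surface_%s.csv", y)))
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d seasons (%d-%d), %d pairs/season\n",
              nrow(x$seasons), min(x$seasons$year), max(x$seasons$year),
              nrow(x$config$grid)))
  print(x$seasons, n = 5)
  invisible(x)
}
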