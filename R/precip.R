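# Growing-season precipitation analytics.

season_dates <- function(year) {
  seq(as.Date(sprintf("%d-03-01", year)), as.Date(sprintf("%d-06-30", year)),
      by = "day")
}

season_years <- function(record) {
  yrs <- sort(unique(as.integer(format(record$date, "%Y"))))
  keep <- vapply(yrs, function(y) all(season_dates(y) %in% record$date),
                 logical(1))
  yrs[keep]
}

#' Extract one growing season from a daily record
#'
#' The growing season runs 1 March to 30 June: 31 + 30 + 31 + 30 = 122 days
#' in every year, leap or not, since the window excludes February.
#'
#' @param record tibble `date`, `rain_mm` (from [read_rain_csv()] or
#'   [generate_weather()]).
#' @param year calendar year.
#' @return tibble `year`, `date`, `rain_mm` with exactly 122 rows.
#' @export
extract_season <- function(record, year) {
  want <- season_dates(year)
  idx <- match(want, record$date)
  if (anyNA(idx)) {
    missing <- want[is.na(idx)]
    abort(sprintf("season %d incomplete: %d missing day(s) starting %s",
                  year, length(missing), format(missing[1])))
  }
  tibble::tibble(year = as.integer(year), date = want,
                 rain_mm = record$rain_mm[idx])
}

#' Mean daily precipitation rate of a season
#'
#' @param season a season tibble from [extract_season()] or a numeric vector
#'   of daily rates.
#' @return mean rate (mm/day).
#' @export
mean_daily_rate <- function(season) {
  mean(forcing_rain_mm(season))
}

#' Per-season mean daily rates for all complete seasons
#'
#' @param record tibble `date`, `rain_mm`.
#' @return tibble `year`, `mean_rate_mm_d`, one row per complete season.
#' @export
season_mean_rates <- function(record) {
  yrs <- season_years(record)
  if (!length(yrs)) abort("record contains no complete 1 Mar - 30 Jun season")
  tibble::tibble(
    year = yrs,
    mean_rate_mm_d = vapply(yrs, function(y) mean(extract_season(record, y)$rain_mm),
                            numeric(1)))
}

#' Centered rolling mean with symmetric edge truncation
#'
#' At positions closer than `(width - 1) / 2` to either end the half-width
#' shrinks to what fits on the shorter side, so every output value is the
#' mean of a window centered on its position. `width = 1` is the identity.
#'
#' @param x numeric series (yearly values).
#' @param width odd window width (years), default 11.
#' @return numeric vector of the same length as `x`.
#' @export
rolling_mean <- function(x, width = 11) {
  if (width %% 2 != 1 || width < 1) abort("`width` must be odd and >= 1")
  n <- length(x)
  h <- (width - 1) / 2
  vapply(seq_len(n), function(i) {
    hi <- min(h, i - 1, n - i)
    mean(x[(i - hi):(i + hi)])
  }, numeric(1))
}

#' Heavy-rainfall threshold from a reference period
#'
#' The threshold is the empirical 99th percentile (linear-interpolation
#' quantile, type 7) of all in-season daily rates in the reference years; a
#' heavy rainfall event is any day with rainfall equal to or above it.
#'
#' @param record tibble `date`, `rain_mm`.
#' @param ref_years reference years (default 1950:1979).
#' @param prob percentile defining "heavy" (default 0.99).
#' @return threshold (mm/day).
#' @export
heavy_rain_threshold <- function(record, ref_years = 1950:1979, prob = 0.99) {
  have <- intersect(ref_years, season_years(record))
  if (!length(have)) abort("no complete reference seasons in record")
  if (!setequal(have, ref_years))
    warn(sprintf("only %d of %d reference years available", length(have),
                 length(ref_years)))
  x <- unlist(lapply(have, function(y) extract_season(record, y)$rain_mm))
  unname(quantile(x, prob, type = 7))
}

#' Classify SPI values into drought classes
#'
#' Classes partition the SPI line at 0, -1, -1.5 and -2: `none` (SPI > 0),
#' `mild` (0 >= SPI > -1), `moderate` (-1 >= SPI > -1.5), `severe`
#' (-1.5 >= SPI > -2), `extreme` (SPI <= -2). "Moderate drought and above"
#' therefore means SPI <= -1 and "severe and above" SPI <= -1.5.
#'
#' @param spi numeric SPI values.
#' @return factor with levels none/mild/moderate/severe/extreme.
#' @export
classify_drought <- function(spi) {
  cut(spi, breaks = c(-Inf, -2, -1.5, -1, 0, Inf),
      labels = c("extreme", "severe", "moderate", "mild", "none"),
      right = TRUE) |>
    factor(levels = c("none", "mild", "moderate", "severe", "extreme"))
}

#' Per-decade heavy-rainfall and drought summary
#'
#' For each complete calendar decade (e.g. 1950-1959 = "1950s"): the
#' percentage of in-season days at or above the heavy-rain threshold, and
#' the percentage of the decade's 40 season-months classified moderate
#' drought or worse (SPI <= -1) and severe or worse (SPI <= -1.5).
#'
#' @param record tibble `date`, `rain_mm`.
#' @param spi_tbl per-month SPI table from [calc_spi()].
#' @param threshold heavy-rain threshold (mm/day), e.g. from
#'   [heavy_rain_threshold()].
#' @param complete_only drop decades with fewer than 10 complete seasons
#'   (default TRUE, with a warning naming them).
#' @return tibble `decade`, `heavy_day_pct`, `moderate_plus_drought_pct`,
#'   `severe_plus_drought_pct`.
#' @export
decade_summary <- function(record, spi_tbl, threshold, complete_only = TRUE) {
  yrs <- season_years(record)
  days <- purrr::map_dfr(yrs, function(y) extract_season(record, y))
  days$decade <- (days$year %/% 10L) * 10L
  spi_tbl$decade <- (spi_tbl$year %/% 10L) * 10L

  by_dec <- days |>
    dplyr::group_by(.data$decade) |>
    dplyr::summarise(n_years = dplyr::n_distinct(.data$year),
                     heavy_day_pct = 100 * mean(.data$rain_mm >= threshold),
                     .groups = "drop")
  spi_dec <- spi_tbl |>
    dplyr::group_by(.data$decade) |>
    dplyr::summarise(
      moderate_plus_drought_pct = 100 * mean(.data$spi <= -1, na.rm = TRUE),
      severe_plus_drought_pct = 100 * mean(.data$spi <= -1.5, na.rm = TRUE),
      .groups = "drop")
  out <- dplyr::left_join(by_dec, spi_dec, by = "decade")
  if (complete_only && any(out$n_years < 10)) {
    bad <- out$decade[out$n_years < 10]
    warn(paste("dropping incomplete decade(s):",
               paste0(bad, "s", collapse = ", ")))
    out <- out[out$n_years >= 10, ]
  }
  dplyr::select(out, -"n_years")
}
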