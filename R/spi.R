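#' Configure the Standardized Precipitation Index calculation
#'
#' @param aggregation_months totals are aggregated over this many calendar
#'   months ending in the indexed month (default 1, the shortest viable
#'   aggregation for within-season soil-moisture analysis). Months whose
#'   aggregation window reaches before March are reported as missing, since
#'   the record only covers the growing season.
#' @param fit_years years used to fit the reference gamma distribution
#'   (default `NULL` = every complete season in the record).
#' @param zero_handling use the mixed distribution
#'   `H(x) = q + (1 - q) G(x)` where `q` is the fraction of zero totals and
#'   `G` the gamma CDF fitted to the positive totals (default TRUE; with
#'   FALSE, zero months make the fit fail unless absent).
#' @return a list of class `spi_config`.
#' @export
spi_config <- function(aggregation_months = 1, fit_years = NULL,
                       zero_handling = TRUE) {
  if (aggregation_months < 1) abort("`aggregation_months` must be >= 1")
  structure(list(aggregation_months = as.integer(aggregation_months),
                 fit_years = fit_years,
                 zero_handling = isTRUE(zero_handling)),
            class = "spi_config")
}

monthly_totals <- function(record) {
  yrs <- season_years(record)
  purrr::map_dfr(yrs, function(y) extract_season(record, y)) |>
    dplyr::mutate(month = as.integer(format(.data$date, "%m"))) |>
    dplyr::group_by(.data$year, .data$month) |>
    dplyr::summarise(total_mm = sum(.data$rain_mm), .groups = "drop")
}

fit_gamma_ml <- function(x) {
  # exact gamma maximum likelihood via the profile equation: the MLE of the
  # shape k solves log(k) - digamma(k) = log(mean(x)) - mean(log(x)), and
  # the rate is then k / mean(x)
  s <- log(mean(x)) - mean(log(x))
  if (!is.finite(s) || s <= 0)            # degenerate: all values equal
    return(list(shape = mean(x)^2 / max(stats::var(x), 1e-12),
                rate = mean(x) / max(stats::var(x), 1e-12)))
  k0 <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)   # Minka start
  k <- stats::uniroot(function(k) log(k) - digamma(k) - s,
                      lower = k0 / 10, upper = k0 * 10,
                      extendInt = "yes", tol = 1e-12)$root
  list(shape = k, rate = k / mean(x))
}

#' Standardized Precipitation Index for the growing-season months
#'
#' For each season month (March-June), monthly totals are aggregated over
#' `aggregation_months`, a gamma distribution is fitted per calendar month
#' across the fit years by maximum likelihood, and each total is transformed
#' through the fitted CDF to a standard-normal quantile:
#' `SPI = qnorm(q + (1 - q) * G(x))` with `q` the zero fraction (mixed
#' distribution) and `G` the fitted gamma CDF. A month whose fit window is
#' degenerate (all totals zero) gets `NA`.
#'
#' @param record tibble `date`, `rain_mm` covering complete seasons.
#' @param config a [spi_config()].
#' @return tibble `year`, `month`, `total_mm`, `spi`, `drought_class`.
#' @export
calc_spi <- function(record, config = spi_config()) {
  stopifnot(inherits(config, "spi_config"))
  tot <- monthly_totals(record)
  k <- config$aggregation_months
  if (k > 1) {
    roll_k <- function(x) vapply(seq_along(x), function(i)
      if (i >= k) sum(x[(i - k + 1):i]) else NA_real_, numeric(1))
    tot <- tot |>
      dplyr::group_by(.data$year) |>
      dplyr::arrange(.data$month, .by_group = TRUE) |>
      dplyr::mutate(total_mm = roll_k(.data$total_mm)) |>
      dplyr::ungroup()
  }
  fit_years <- config$fit_years %||% unique(tot$year)
  out <- tot |>
    dplyr::group_by(.data$month) |>
    dplyr::group_modify(function(d, key) {
      ref <- d$total_mm[d$year %in% fit_years & !is.na(d$total_mm)]
      if (length(ref) < 20 && length(ref) > 0)
        warn(sprintf("month %d: only %d years in fit window; SPI fit is weak",
                     key$month, length(ref)))
      if (sum(ref > 0) < 4) {
        if (length(ref) && !all(ref == 0))
          warn(sprintf("month %d: too few wet months to fit; SPI set missing",
                       key$month))
        d$spi <- NA_real_
        return(d)
      }
      q0 <- mean(ref == 0)
      if (q0 > 0 && !config$zero_handling)
        abort("zero monthly totals present; enable `zero_handling`")
      g <- fit_gamma_ml(ref[ref > 0])
      cdf <- q0 + (1 - q0) *
        pgamma(d$total_mm, shape = g$shape, rate = g$rate)
      d$spi <- qnorm(pmin(pmax(cdf, 1e-9), 1 - 1e-9))
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(drought_class = classify_drought(.data$spi)) |>
    dplyr::arrange(.data$year, .data$month) |>
    dplyr::select("year", "month", "total_mm", "spi", "drought_class")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
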