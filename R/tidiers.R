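# broom-style tidiers for result objects.

#' Tidy a season result into a long ledger
#'
#' @param x a `season_result` from [simulate_season()].
#' @param ... unused.
#' @return tibble `quantity`, `value`, `unit` covering the nitrogen and
#'   water ledgers.
#' @export
tidy.season_result <- function(x, ...) {
  tibble::tibble(
    quantity = c("uptake_n", "uptake_no3", "uptake_nh4", "leached_n",
                 "applied_n", "initial_n", "final_n", "balance_residual_n",
                 "rain", "runoff", "drainage", "transpiration",
                 "storage_change", "balance_residual_water"),
    value = c(x$uptake_n, x$uptake_no3, x$uptake_nh4, x$leached_n,
              x$applied_n, x$initial_n, x$final_n, x$balance_residual_n,
              x$rain_mm, x$runoff_mm, x$drainage_mm, x$transpiration_mm,
              x$storage_change_mm, x$balance_residual_water_mm),
    unit = c(rep("kg N/ha", 8), rep("mm", 6)))
}

#' One-row summary of a season result
#'
#' @inheritParams tidy.season_result
#' @return one-row tibble with the season's headline quantities.
#' @export
glance.season_result <- function(x, ...) {
  tibble::tibble(year = x$year, uptake_n = x$uptake_n,
                 leached_n = x$leached_n, applied_n = x$applied_n,
                 rain_mm = x$rain_mm, drainage_mm = x$drainage_mm,
                 balance_residual_n = x$balance_residual_n,
                 balance_residual_water_mm = x$balance_residual_water_mm)
}

#' Tidy a study report (per-season table)
#'
#' @param x a `study_report`.
#' @param ... unused.
#' @export
tidy.study_report <- function(x, ...) x$seasons

#' One-row summary of a study report
#'
#' @inheritParams tidy.study_report
#' @export
glance.study_report <- function(x, ...) {
  s <- x$seasons
  tibble::tibble(
    n_seasons = nrow(s), first_year = min(s$year), last_year = max(s$year),
    mean_rate = mean(s$mean_rate), median_max_uptake = median(s$max_uptake),
    median_t2 = median(s$median_t2), mean_n_close = mean(s$n_close),
    mean_stability = mean(s$stability))
}

#' Heat map of an uptake surface
#'
#' @param object an `uptake_surface`.
#' @param ... unused.
#' @return a ggplot: uptake (kg N/ha) over the admissible (t1, t2) triangle.
#' @export
autoplot.uptake_surface <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t1, .data$t2,
                                       fill = .data$uptake_kg_ha)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "uptake\n(kg N/ha)") +
    ggplot2::labs(x = "first application day", y = "second application day",
                  title = if (!is.na(attr(object, "year") %||% NA))
                    paste("season", attr(object, "year")) else NULL) +
    ggplot2::coord_equal()
}

#' Yearly study trajectories
#'
#' @param object a `study_report`.
#' @param ... unused.
#' @return a ggplot of yearly maximum uptake with its rolling mean.
#' @export
autoplot.study_report <- function(object, ...) {
  s <- object$seasons[order(object$seasons$year), ]
  s$roll <- rolling_mean(s$max_uptake, object$config$rolling_width)
  ggplot2::ggplot(s, ggplot2::aes(.data$year, .data$max_uptake)) +
    ggplot2::geom_line(alpha = 0.45) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$roll), linewidth = 1) +
    ggplot2::labs(x = "year", y = "maximum N uptake (kg N/ha)")
}

#' Decadal drought and heavy-rainfall summary plot
#'
#' @param decades tibble from [decade_summary()].
#' @return a ggplot with one panel per metric.
#' @export
plot_decade_summary <- function(decades) {
  long <- tidyr::pivot_longer(decades, -"decade",
                              names_to = "metric", values_to = "pct")
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$decade), .data$pct)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "decade", y = "% of days / months")
}
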