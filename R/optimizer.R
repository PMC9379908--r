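# Exhaustive split-fertilization timing enumeration and analytics.

#' Admissible fertilization timing grid
#'
#' All pairs `(t1, t2)` with `t_min <= t1 <= t2 <= t_max` on a regular grid.
#' The default 1.2-day resolution over the first 70 days of the season gives
#' 58 grid points and 58 * 59 / 2 = 1711 pairs.
#'
#' @param resolution grid spacing (days), default 1.2.
#' @param t_max latest admissible day, default 70.
#' @param t_min earliest admissible day, default `resolution` (no day-0
#'   application).
#' @return tibble `t1`, `t2` of class `timing_grid`, with attributes
#'   `points`, `resolution`, `t_max`.
#' @export
timing_grid <- function(resolution = 1.2, t_max = 70, t_min = resolution) {
  check_pos(resolution, "resolution"); check_pos(t_max, "t_max")
  if (t_min > t_max) abort("`t_min` must be <= `t_max`")
  pts <- seq(t_min, t_max, by = resolution)
  pairs <- tidyr::expand_grid(t1 = pts, t2 = pts) |>
    dplyr::filter(.data$t1 <= .data$t2)
  structure(pairs, points = pts, resolution = resolution, t_max = t_max,
            class = c("timing_grid", class(pairs)))
}

#' Uptake surface: one season simulated at every timing pair
#'
#' Runs [simulate_season()] once per admissible `(t1, t2)` pair. Pair
#' evaluations are independent, so results do not depend on evaluation
#' order. Any solver failure aborts with the season and pair in the message.
#'
#' @param forcing season forcing (see [simulate_season()]).
#' @param grid a [timing_grid()].
#' @param config a [model_config()].
#' @param total_n,split_first,pulse_duration schedule parameters shared by
#'   every pair (see [fertilizer_schedule()]).
#' @return tibble `t1`, `t2`, `uptake_kg_ha` of class `uptake_surface`, with
#'   the grid attributes and `year` carried along.
#' @export
compute_uptake_surface <- function(forcing, grid, config = model_config(),
                                   total_n = 144, split_first = 1 / 3,
                                   pulse_duration = 1) {
  stopifnot(inherits(grid, "timing_grid"))
  year <- if (is.data.frame(forcing) && "year" %in% names(forcing))
    forcing$year[1] else NA_integer_
  uptake <- purrr::map2_dbl(grid$t1, grid$t2, function(a, b) {
    res <- tryCatch(
      simulate_season(forcing,
                      fertilizer_schedule(a, b, total_n = total_n,
                                          split_first = split_first,
                                          pulse_duration = pulse_duration),
                      config),
      error = function(e) abort(sprintf(
        "season %s, pair (%g, %g): %s",
        ifelse(is.na(year), "?", year), a, b, conditionMessage(e))))
    res$uptake_n
  })
  out <- tibble::tibble(t1 = grid$t1, t2 = grid$t2, uptake_kg_ha = uptake)
  structure(out, points = attr(grid, "points"),
            resolution = attr(grid, "resolution"),
            t_max = attr(grid, "t_max"), year = year,
            class = c("uptake_surface", class(out)))
}

as_surface <- function(x) {
  if (!all(c("t1", "t2", "uptake_kg_ha") %in% names(x)))
    abort("surface needs columns t1, t2, uptake_kg_ha")
  if (!nrow(x)) abort("empty uptake surface")
  if (any(x$uptake_kg_ha < 0)) abort("uptake must be >= 0")
  x
}

#' Precipitation-optimal timing pair of a surface
#'
#' The pair maximizing uptake; exact ties are broken lexicographically by
#' `(t1, t2)`, favoring the earliest pair, so the result is deterministic
#' and independent of row order.
#'
#' @param surface an [compute_uptake_surface()] result (or any tibble with
#'   `t1`, `t2`, `uptake_kg_ha`).
#' @return one-row tibble `t1`, `t2`, `uptake_kg_ha`.
#' @export
find_optimum <- function(surface) {
  s <- as_surface(surface)
  mx <- max(s$uptake_kg_ha)
  cand <- s[s$uptake_kg_ha == mx, c("t1", "t2", "uptake_kg_ha")]
  cand <- cand[order(cand$t1, cand$t2), ]
  tibble::tibble(t1 = cand$t1[1], t2 = cand$t2[1],
                 uptake_kg_ha = cand$uptake_kg_ha[1])
}

#' Close-to-optimal timing pairs
#'
#' All pairs achieving uptake within `tol` (default 5%) of the season
#' maximum, i.e. `uptake >= (1 - tol) * max`. Always contains the optimum.
#'
#' @param surface an uptake surface.
#' @param tol relative tolerance, default 0.05.
#' @return tibble of the qualifying rows of `surface`.
#' @export
close_to_optimal <- function(surface, tol = 0.05) {
  s <- as_surface(surface)
  tibble::as_tibble(s[s$uptake_kg_ha >= (1 - tol) * max(s$uptake_kg_ha),
                      c("t1", "t2", "uptake_kg_ha")])
}

#' Stability of a timing pair
#'
#' For the pair `(t1*, t2*)`, consider the neighborhood `S_r`: all grid
#' pairs within `radius` days of it in both coordinates (a Chebyshev box,
#' clipped wherever it leaves the admissible `t1 <= t2 <= t_max` triangle).
#' Stability is the minimum uptake over `S_r` as a proportion of the uptake
#' at the pair itself: a stability of 0.75 means a farmer missing the pair
#' by up to `radius` days each side is still guaranteed 75% of its uptake.
#'
#' @param surface an uptake surface (complete over its grid).
#' @param t1,t2 the pair (must lie on the grid).
#' @param radius neighborhood radius r in days, default 2.4.
#' @return stability in (0, 1].
#' @export
stability <- function(surface, t1, t2, radius = 2.4) {
  s <- as_surface(surface)
  eps <- 1e-8
  center <- which(abs(s$t1 - t1) < eps & abs(s$t2 - t2) < eps)
  if (!length(center)) abort(sprintf("pair (%g, %g) is not on the grid", t1, t2))
  u0 <- s$uptake_kg_ha[center[1]]
  if (u0 <= 0) abort("stability undefined at a pair with zero uptake")
  nb <- abs(s$t1 - t1) <= radius + eps & abs(s$t2 - t2) <= radius + eps
  min(s$uptake_kg_ha[nb]) / u0
}

#' Season stability
#'
#' Mean [stability()] over all close-to-optimal pairs of the season.
#'
#' @inheritParams stability
#' @param tol close-to-optimal tolerance, default 0.05.
#' @return mean stability in (0, 1].
#' @export
season_stability <- function(surface, radius = 2.4, tol = 0.05) {
  s <- as_surface(surface)
  cl <- close_to_optimal(s, tol = tol)
  mean(purrr::map2_dbl(cl$t1, cl$t2,
                       function(a, b) stability(s, a, b, radius = radius)))
}

#' One-row season summary of an uptake surface
#'
#' Collects the optimizer analytics for one season: the optimum, the
#' close-to-optimal set size and its median timings, and season stability.
#' Medians over even-sized sets use the usual midpoint convention.
#'
#' @inheritParams season_stability
#' @return one-row tibble `year`, `best_t1`, `best_t2`, `max_uptake`,
#'   `n_close`, `median_t1`, `median_t2`, `stability`.
#' @export
summarize_surface <- function(surface, radius = 2.4, tol = 0.05) {
  s <- as_surface(surface)
  opt <- find_optimum(s)
  cl <- close_to_optimal(s, tol = tol)
  tibble::tibble(
    year = attr(surface, "year") %||% NA_integer_,
    best_t1 = opt$t1, best_t2 = opt$t2, max_uptake = opt$uptake_kg_ha,
    n_close = nrow(cl),
    median_t1 = median(cl$t1), median_t2 = median(cl$t2),
    stability = season_stability(s, radius = radius, tol = tol))
}

#' Persist / restore an uptake surface as long-format CSV
#'
#' @param surface an uptake surface.
#' @param path CSV path (`t1, t2, uptake_kg_ha`).
#' @export
write_surface_csv <- function(surface, path) {
  readr::write_csv(as_surface(surface), path)
  invisible(path)
}

#' @rdname write_surface_csv
#' @export
read_surface_csv <- function(path) {
  s <- readr::read_csv(path, col_types = readr::cols(
    t1 = readr::col_double(), t2 = readr::col_double(),
    uptake_kg_ha = readr::col_double()))
  structure(as_surface(s), class = c("uptake_surface", class(s)))
}
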