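# Shared fixtures: small records, coarse grids and a fast model config.

coarse_grid <- function(by = 14) timing_grid(resolution = by, t_max = 70)

# model configuration kept cheap for unit tests: shallower column, coarser
# nodes; physics unchanged
fast_config <- function(...) {
  model_config(grid = column_grid(depth = 80, dz = 2), ...)
}

# deterministic synthetic record with n complete seasons
make_record <- function(n_years = 3, start_year = 2001, seed = 42,
                        regime = "historic") {
  generate_weather(weather_preset(regime, n_years = n_years,
                                  start_year = start_year, seed = seed))
}

# random triangular uptake surface on an arbitrary grid (for optimizer
# oracle tests; no simulation involved)
random_surface <- function(points = seq(7, 70, by = 7), seed = 1,
                           base = 150, spread = 30) {
  set.seed(seed)
  g <- tidyr::expand_grid(t1 = points, t2 = points) |>
    dplyr::filter(t1 <= t2)
  s <- tibble::tibble(t1 = g$t1, t2 = g$t2,
                      uptake_kg_ha = base + runif(nrow(g), -spread, spread))
  structure(s, points = points, resolution = diff(points[1:2]), t_max = max(points),
            year = NA_integer_, class = c("uptake_surface", class(s)))
}
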