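# splitN

Precipitation decides the fate of fertilizer nitrogen: rain carries
surface-applied N into the root zone — or straight past it. `splitN` is an
R package for studying how the *timing* of split nitrogen fertilization
interacts with a growing season's rainfall pattern. It is aimed at
soil-plant modelers and agronomy researchers who want a mechanistic,
testable pipeline from daily rainfall to optimal application days.

The package has four layers:

1. **A mechanistic 1-D soil-crop column** (`simulate_season()`, compiled
   core): Richards' equation for variably saturated water flow
   (van Genuchten-Mualem silt loam, mixed form, damped Newton),
   advection-dispersion of nitrate and ammonium driven by the simulated
   Darcy flux (implicit upwind finite volumes, linear NH4 sorption), a
   first-order organic/mineral N cycle with nitrification, logistic maize
   root growth and Michaelis-Menten root uptake, two ammonium-nitrate
   pulses (one third at `t1`, two thirds at `t2`, 144 kg N ha^-1 per
   season), free-drainage leaching, and closed water/N ledgers.
2. **An exhaustive timing optimizer** (`compute_uptake_surface()`,
   `find_optimum()`, `close_to_optimal()`, `stability()`): the model is
   solved for every pair `t1 <= t2 <= 70` days (default 1.2-day
   resolution, 1711 pairs), giving the uptake surface from which the
   precipitation-optimal pair, the set of pairs within 5% of the maximum,
   and a neighborhood stability metric (radius 2.4 days) are read off.
3. **Precipitation analytics** (`season_mean_rates()`, `rolling_mean()`,
   `heavy_rain_threshold()`, `calc_spi()`, `decade_summary()`): seasonal
   mean daily rates with 11-year rolling means, heavy-rainfall days
   against a reference-period 99th percentile, and a 1-month Standardized
   Precipitation Index (gamma maximum likelihood per calendar month,
   zero-inflation mixture, classes at 0/-1/-1.5/-2).
4. **A study pipeline and weather generator** (`run_study()`,
   `generate_weather()`): Markov-gamma synthetic daily rainfall with
   historic-like (~1.7 mm/day), wet (~3.5) and dry (~1.2) presets, and an
   orchestrator producing per-season tables, decadal medians, and Pearson
   correlations between precipitation metrics and the optimizer outputs.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()` draws uptake-surface heat
maps and study trajectories.

## A worked example

```r
library(splitN)

rec    <- generate_weather(weather_preset("historic", n_years = 3, seed = 1))
season <- extract_season(rec, 1951)
mean_daily_rate(season)
#> [1] 1.692528

res <- simulate_season(season, fertilizer_schedule(t1 = 14.4, t2 = 36))
res
#> <season_result> year 1951
#>   N uptake    166.7 kg N/ha   leached    9.0   applied  144.0
#>   rain  206.5 mm  drainage   40.4  transpiration  210.6  runoff   0.0
#>   residuals: N -1.55e-12 kg/ha, water -0.000215 mm
```

166.7 kg N ha^-1 of the 383.2 kg available (48.2 mineral + 191 organic
initial + 144 applied) ends up in the crop; only 9 kg leaches in this
average-rainfall season, and both balance residuals are negligible — the
ledgers close. Scanning all timing pairs on a coarse grid:

```r
surf <- compute_uptake_surface(season, timing_grid(resolution = 7))
summarize_surface(surf)
#> # A tibble: 1 x 8
#>    year best_t1 best_t2 max_uptake n_close median_t1 median_t2 stability
#>   <int>   <dbl>   <dbl>      <dbl>   <int>     <dbl>     <dbl>     <dbl>
#> 1  1951      21      35       167.      22      17.5        35         1
autoplot(surf)
```

The precipitation-optimal pair for this season is days (21, 35) at
167 kg N ha^-1; 22 of the 55 pairs come within 5% of it (on this 7-day
grid a 2.4-day neighborhood contains only the pair itself, hence
stability 1; the full-resolution 1.2-day grid resolves the metric). A multi-season
study, including SPI and correlations, is one call:

```r
report <- run_study(rec, study_config(grid = timing_grid(resolution = 14)))
report$seasons        # per-season optima, n_close, stability, mean rate, SPI
report$correlations   # Pearson r, raw and 11-year rolling
write_study_report(report, "results/")
```

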