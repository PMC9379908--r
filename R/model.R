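# Wrappers around the compiled column kernel.

build_pars <- function(config, schedule, save_daily = FALSE,
                       bottom_no_flow = NULL, psi_profile = NULL) {
  ctl <- config$control
  if (!is.null(bottom_no_flow)) ctl$bottom_no_flow <- bottom_no_flow
  ini <- list(psi_init = config$pools$psi_init,
              no3_mg_cm2 = kg_ha_to_mg_cm2(config$pools$no3),
              nh4_mg_cm2 = kg_ha_to_mg_cm2(config$pools$nh4),
              org_mg_cm2 = kg_ha_to_mg_cm2(config$pools$org))
  if (!is.null(psi_profile)) ini$psi_profile <- as.numeric(psi_profile)
  list(
    hydraulics = unclass(config$hydraulics),
    grid = unclass(config$grid),
    transport = unclass(config$transport),
    reactions = unclass(config$reactions),
    roots = unclass(config$roots),
    uptake = unclass(config$uptake),
    init = ini,
    fertilizer = list(t1 = schedule$t1, t2 = schedule$t2,
                      total_mg_cm2 = kg_ha_to_mg_cm2(schedule$total_n),
                      split_first = schedule$split_first,
                      pulse_duration = schedule$pulse_duration),
    numerics = list(dt_max = ctl$dt_max, dt_min = ctl$dt_min,
                    max_picard = ctl$max_picard,
                    bottom_no_flow = ctl$bottom_no_flow,
                    save_daily = isTRUE(save_daily))
  )
}

forcing_rain_mm <- function(forcing) {
  if (is.data.frame(forcing)) {
    if (!"rain_mm" %in% names(forcing))
      abort("forcing data frame needs a `rain_mm` column")
    rain <- forcing$rain_mm
  } else {
    rain <- as.numeric(forcing)
  }
  if (anyNA(rain) || any(rain < 0)) abort("rainfall must be non-negative")
  rain
}

#' Initialize the soil column state
#'
#' Builds the discretized initial state: uniform pressure head at
#' `pools$psi_init` and uniform concentration profiles whose depth integrals
#' equal the configured area densities. Ammonium is partitioned between
#' solution and the sorbed phase via the linear `kd_nh4` isotherm, so the
#' reported pool integral covers both phases.
#'
#' @param config a [model_config()].
#' @return a tibble with one row per node: `depth` (cm, node center), `psi`,
#'   `theta`, `c_no3`, `c_nh4` (mg N / cm^3 water), `c_org` (mg N / cm^3
#'   soil), plus attributes `pool_integrals` (kg N / ha) for verification.
#' @export
init_column <- function(config) {
  stopifnot(inherits(config, "model_config"))
  g <- config$grid
  n <- round(g$depth / g$dz)
  depth <- (seq_len(n) - 0.5) * g$dz
  psi <- rep(config$pools$psi_init, n)
  theta <- vg_theta_r(psi, config$hydraulics)
  bnh4 <- config$transport$bulk_density * config$transport$kd_nh4
  c_no3 <- kg_ha_to_mg_cm2(config$pools$no3) / (theta[1] * g$depth)
  c_nh4 <- kg_ha_to_mg_cm2(config$pools$nh4) / ((theta[1] + bnh4) * g$depth)
  c_org <- kg_ha_to_mg_cm2(config$pools$org) / g$depth
  out <- tibble::tibble(depth = depth, psi = psi, theta = theta,
                        c_no3 = c_no3, c_nh4 = c_nh4, c_org = c_org)
  attr(out, "pool_integrals") <- c(
    no3 = mg_cm2_to_kg_ha(sum(theta * c_no3) * g$dz),
    nh4 = mg_cm2_to_kg_ha(sum((theta + bnh4) * c_nh4) * g$dz),
    org = mg_cm2_to_kg_ha(n * c_org * g$dz))
  out
}

#' Logistic root profile
#'
#' Rooting-front depth and root length density (RLD) at season day `t`.
#' Both follow logistic curves in time from `initial_fraction` of their
#' asymptote; RLD declines exponentially with depth and is zero below the
#' front. The profile is deterministic and independent of the water and
#' nitrogen state (crop growth is never water- or N-limited).
#'
#' @param t day of season (>= 0).
#' @param params a [root_params()].
#' @param depths node depths (cm) at which to evaluate RLD.
#' @return a tibble `depth`, `rld` (cm root / cm^3 soil) with attribute
#'   `root_depth` (cm, the front position).
#' @export
root_profile <- function(t, params = root_params(),
                         depths = seq(0.5, 79.5, by = 1)) {
  stopifnot(inherits(params, "root_params"), t >= 0)
  f0 <- params$initial_fraction
  z0 <- params$sowing_depth
  lgst <- function(rate) 1 / (1 + (1 / f0 - 1) * exp(-rate * t))
  zr <- z0 + (params$max_root_depth - z0) * lgst(params$depth_growth_rate)
  rld <- ifelse(depths >= z0 & depths <= zr,
                params$max_rld_surface * lgst(params$rld_growth_rate) *
                  exp(-params$rld_depth_shape * (depths - z0)),
                0)
  out <- tibble::tibble(depth = depths, rld = rld)
  attr(out, "root_depth") <- zr
  out
}

#' Simulate one growing season of the coupled soil-crop column
#'
#' Runs the 1-D column for the length of the forcing series (122 days for a
#' 1 March - 30 June season): variably saturated water flow under the daily
#' rain flux with free drainage at the bottom, advection-dispersion of
#' nitrate and ammonium with the Darcy flux of each sub-step, first-order
#' organic/mineral transformations, and root water and Michaelis-Menten N
#' uptake on the growing logistic root profile. Fertilizer enters as two
#' dissolved surface pulses per `schedule`.
#'
#' @param forcing a season forcing: either the tibble returned by
#'   [extract_season()] (column `rain_mm`) or a bare numeric vector of daily
#'   rainfall (mm/day).
#' @param schedule a [fertilizer_schedule()].
#' @param config a [model_config()].
#' @param save_daily also return daily column summaries.
#' @return an object of class `season_result`: a list with cumulative
#'   `uptake_n`, `leached_n`, `applied_n` (kg N / ha), the water ledger
#'   (`rain_mm`, `runoff_mm`, `drainage_mm`, `transpiration_mm`,
#'   `storage_change_mm`), closure residuals, final state profiles and,
#'   optionally, a `daily` tibble. Use [tidy()] / [glance()] to get tabular
#'   views.
#' @export
simulate_season <- function(forcing, schedule, config = model_config(),
                            save_daily = FALSE) {
  stopifnot(inherits(schedule, "fertilizer_schedule"),
            inherits(config, "model_config"))
  rain <- forcing_rain_mm(forcing)
  res <- cpp_run_column(rain / 10, build_pars(config, schedule, save_daily))
  year <- if (is.data.frame(forcing) && "year" %in% names(forcing))
    forcing$year[1] else NA_integer_
  out <- list(
    year = year,
    uptake_n = mg_cm2_to_kg_ha(res$uptake_no3 + res$uptake_nh4),
    uptake_no3 = mg_cm2_to_kg_ha(res$uptake_no3),
    uptake_nh4 = mg_cm2_to_kg_ha(res$uptake_nh4),
    leached_n = mg_cm2_to_kg_ha(res$leach_no3 + res$leach_nh4),
    applied_n = mg_cm2_to_kg_ha(res$applied),
    initial_n = mg_cm2_to_kg_ha(res$n_init),
    final_n = mg_cm2_to_kg_ha(res$n_final),
    balance_residual_n = mg_cm2_to_kg_ha(res$n_residual),
    rain_mm = res$rain_cm * 10,
    runoff_mm = res$runoff_cm * 10,
    drainage_mm = res$drain_cm * 10,
    transpiration_mm = res$transp_cm * 10,
    storage_change_mm = (res$storage_final_cm - res$storage_init_cm) * 10,
    balance_residual_water_mm = res$water_residual_cm * 10,
    schedule = schedule,
    state = tibble::tibble(
      depth = (seq_along(res$psi) - 0.5) * config$grid$dz,
      psi = res$psi, theta = res$theta,
      c_no3 = res$c_no3, c_nh4 = res$c_nh4, c_org = res$c_org)
  )
  if (save_daily) {
    d <- res$daily
    out$daily <- tibble::tibble(
      day = seq_along(d$cum_uptake),
      cum_uptake_kg_ha = mg_cm2_to_kg_ha(d$cum_uptake),
      cum_leach_kg_ha = mg_cm2_to_kg_ha(d$cum_leach),
      cum_drain_mm = d$cum_drain * 10,
      water_storage_mm = d$water_storage * 10,
      mineral_n_kg_ha = mg_cm2_to_kg_ha(d$mineral_n),
      organic_n_kg_ha = mg_cm2_to_kg_ha(d$organic_n))
  }
  class(out) <- "season_result"
  out
}

#' @export
print.season_result <- function(x, ...) {
  cat("<season_result>",
      if (!is.na(x$year)) paste0(" year ", x$year) else "", "\n", sep = "")
  cat(sprintf("  N uptake  %7.1f kg N/ha   leached %6.1f   applied %6.1f\n",
              x$uptake_n, x$leached_n, x$applied_n))
  cat(sprintf("  rain %6.1f mm  drainage %6.1f  transpiration %6.1f  runoff %5.1f\n",
              x$rain_mm, x$drainage_mm, x$transpiration_mm, x$runoff_mm))
  cat(sprintf("  residuals: N %.3g kg/ha, water %.3g mm\n",
              x$balance_residual_n, x$balance_residual_water_mm))
  invisible(x)
}

#' Advance water flow only (verification interface)
#'
#' Runs the Richards solver alone: transport, reactions and uptake are
#' switched off and the transpiration sink is zero, so the run isolates the
#' water step for stationarity, steady-flux and mass-balance checks.
#'
#' @param psi_profile initial pressure head per node (cm).
#' @param rain_mm daily surface flux (mm/day), one value per day.
#' @param config a [model_config()].
#' @param bottom_no_flow use a no-flow bottom boundary instead of free
#'   drainage.
#' @return list with final `psi`, `theta` and the water ledger (mm).
#' @export
richards_advance <- function(psi_profile, rain_mm, config = model_config(),
                             bottom_no_flow = FALSE) {
  cfg <- config
  cfg$uptake$vmax_n <- 0
  cfg$uptake$transpiration_potential <- 0
  cfg$reactions[] <- lapply(cfg$reactions, function(x) 0)
  cfg$pools$no3 <- 0; cfg$pools$nh4 <- 0; cfg$pools$org <- 0
  sched <- fertilizer_schedule(1, 2, total_n = 0)
  sched$total_n <- 0
  res <- cpp_run_column(as.numeric(rain_mm) / 10,
                        build_pars(cfg, sched, bottom_no_flow = bottom_no_flow,
                                   psi_profile = psi_profile))
  list(psi = res$psi, theta = res$theta,
       rain_mm = res$rain_cm * 10, runoff_mm = res$runoff_cm * 10,
       drainage_mm = res$drain_cm * 10,
       storage_change_mm = (res$storage_final_cm - res$storage_init_cm) * 10,
       residual_mm = res$water_residual_cm * 10)
}

#' Saturated-column breakthrough run (verification interface)
#'
#' Implicit upwind finite-volume advection-dispersion in a saturated column
#' with constant Darcy flux and a constant inlet concentration, for
#' comparison against the closed-form continuous-injection breakthrough
#' solution.
#'
#' @param n_nodes,dz grid.
#' @param theta constant water content.
#' @param q constant Darcy flux (cm/day, downward).
#' @param disp hydrodynamic dispersion coefficient D (cm^2/day).
#' @param c_in inlet concentration.
#' @param out_times times (days) at which to return the profile.
#' @param dt time step (days).
#' @return matrix `length(out_times)` x `n_nodes` of concentrations.
#' @export
ade_breakthrough <- function(n_nodes, dz, theta, q, disp, c_in, out_times,
                             dt = 0.002) {
  cpp_ade_column(as.integer(n_nodes), dz, theta, q, disp, c_in,
                 as.numeric(out_times), dt)
}

#' Closed-form continuous-injection breakthrough (Ogata-Banks)
#'
#' Analytic solution of the 1-D advection-dispersion equation with constant
#' inlet concentration `c_in`, pore velocity `v` and dispersion `disp`:
#' independent oracle for [ade_breakthrough()].
#'
#' @param x distances (cm).
#' @param t time (days).
#' @param v pore-water velocity (cm/day).
#' @param disp dispersion coefficient (cm^2/day).
#' @param c_in inlet concentration.
#' @return concentrations at `x`.
#' @export
ogata_banks <- function(x, t, v, disp, c_in = 1) {
  erfc <- function(z) 2 * stats::pnorm(z * sqrt(2), lower.tail = FALSE)
  a <- erfc((x - v * t) / (2 * sqrt(disp * t)))
  b <- exp(pmin(v * x / disp, 700)) * erfc((x + v * t) / (2 * sqrt(disp * t)))
  0.5 * c_in * (a + b)
}
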