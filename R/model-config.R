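#' Soil hydraulic parameters (van Genuchten-Mualem)
#'
#' Defaults are literature values for a silt loam: residual and saturated
#' water contents, the van Genuchten shape parameters and the saturated
#' conductivity used by the Mualem closure.
#'
#' @param theta_r,theta_s residual / saturated volumetric water content (-).
#' @param alpha inverse air-entry scale (1/cm).
#' @param n_vg pore-size distribution index (-), must exceed 1.
#' @param ks saturated hydraulic conductivity (cm/day).
#' @return a list of class `soil_hydraulics`.
#' @export
soil_hydraulics <- function(theta_r = 0.067, theta_s = 0.45,
                            alpha = 0.02, n_vg = 1.41, ks = 10.8) {
  if (!(theta_r >= 0 && theta_r < theta_s && theta_s <= 1))
    abort("need 0 <= theta_r < theta_s <= 1")
  check_pos(alpha, "alpha"); check_pos(ks, "ks")
  if (n_vg <= 1) abort("`n_vg` must be > 1")
  structure(list(theta_r = theta_r, theta_s = theta_s, alpha = alpha,
                 n_vg = n_vg, ks = ks), class = "soil_hydraulics")
}

#' Solute transport parameters
#'
#' @param diff_no3,diff_nh4 free-water molecular diffusion coefficients
#'   (cm^2/day); reduced in soil by a Millington-Quirk tortuosity factor.
#' @param dispersivity longitudinal dispersivity (cm).
#' @param kd_nh4 linear sorption coefficient for ammonium (cm^3/g).
#' @param bulk_density soil bulk density (g/cm^3).
#' @return a list of class `transport_params`.
#' @export
transport_params <- function(diff_no3 = 1.4, diff_nh4 = 1.5,
                             dispersivity = 3, kd_nh4 = 1.5,
                             bulk_density = 1.35) {
  for (nm in c("diff_no3", "diff_nh4", "dispersivity", "kd_nh4"))
    check_pos(get(nm), nm, strict = FALSE)
  check_pos(bulk_density, "bulk_density")
  structure(list(diff_no3 = diff_no3, diff_nh4 = diff_nh4,
                 dispersivity = dispersivity, kd_nh4 = kd_nh4,
                 bulk_density = bulk_density), class = "transport_params")
}

#' First-order nitrogen cycle rate constants
#'
#' Reversible bio-mediated transformations between the organic pool and the
#' two mineral pools, plus nitrification of ammonium to nitrate. All rates
#' are first-order (1/day) on the bulk pool at each depth.
#'
#' @param k_org_to_nh4 mineralization to ammonium (1/day).
#' @param k_nh4_to_org ammonium immobilization (1/day).
#' @param k_org_to_no3 direct mineralization to nitrate (1/day).
#' @param k_no3_to_org nitrate immobilization (1/day).
#' @param k_nitrification ammonium to nitrate (1/day).
#' @return a list of class `reaction_params`.
#' @export
reaction_params <- function(k_org_to_nh4 = 0.004, k_nh4_to_org = 0.01,
                            k_org_to_no3 = 0.001, k_no3_to_org = 0.01,
                            k_nitrification = 0.2) {
  p <- list(k_org_to_nh4 = k_org_to_nh4, k_nh4_to_org = k_nh4_to_org,
            k_org_to_no3 = k_org_to_no3, k_no3_to_org = k_no3_to_org,
            k_nitrification = k_nitrification)
  for (nm in names(p)) check_pos(p[[nm]], nm, strict = FALSE)
  structure(p, class = "reaction_params")
}

#' Logistic root growth parameters (maize-like)
#'
#' The rooting front and the root length density (RLD) each follow a logistic
#' curve in time starting from `initial_fraction` of their asymptote; RLD is
#' zero above `sowing_depth` (seminal roots descend from the seed, leaving
#' the very surface unexplored) and below the front, and declines
#' exponentially with depth between them. Default rates put the logistic
#' midpoint near day 26, so the root system is close to mature by mid-season
#' as for spring-sown maize.
#'
#' @param max_root_depth asymptotic rooting depth (cm).
#' @param depth_growth_rate logistic rate of the rooting front (1/day).
#' @param max_rld_surface asymptotic RLD at the sowing depth
#'   (cm root / cm^3 soil).
#' @param rld_growth_rate logistic rate of RLD growth (1/day).
#' @param rld_depth_shape exponential decline of RLD with depth (1/cm).
#' @param initial_fraction logistic starting fraction at day 0.
#' @param sowing_depth top of the rooted zone (cm); surface-applied
#'   fertilizer must be transported below it before roots can reach it.
#' @return a list of class `root_params`.
#' @export
root_params <- function(max_root_depth = 50, depth_growth_rate = 0.2,
                        max_rld_surface = 3, rld_growth_rate = 0.2,
                        rld_depth_shape = 0.03, initial_fraction = 0.005,
                        sowing_depth = 10) {
  p <- list(max_root_depth = max_root_depth,
            depth_growth_rate = depth_growth_rate,
            max_rld_surface = max_rld_surface,
            rld_growth_rate = rld_growth_rate,
            rld_depth_shape = rld_depth_shape,
            initial_fraction = initial_fraction,
            sowing_depth = sowing_depth)
  for (nm in names(p)) check_pos(p[[nm]], nm)
  if (initial_fraction >= 1) abort("`initial_fraction` must be < 1")
  if (sowing_depth >= max_root_depth)
    abort("`sowing_depth` must be < `max_root_depth`")
  structure(p, class = "root_params")
}

#' Root water and nitrogen uptake parameters
#'
#' Nitrogen uptake per unit root length follows Michaelis-Menten kinetics on
#' the local solution concentration; water extraction is distributed over the
#' root profile up to a transpiration demand and shut down linearly between
#' `psi_stress` and `psi_wilt`.
#'
#' @param vmax_n maximal N uptake rate (mg N per cm root per day).
#' @param km_n half-saturation solution concentration (mg N / cm^3 water).
#' @param transpiration_potential daily water demand (mm/day).
#' @param psi_wilt,psi_stress pressure heads (cm, negative) bounding the
#'   water-stress ramp of the root water sink.
#' @return a list of class `uptake_params`.
#' @export
uptake_params <- function(vmax_n = 1.2e-3, km_n = 0.1,
                          transpiration_potential = 1.8,
                          psi_wilt = -15000, psi_stress = -800) {
  check_pos(vmax_n, "vmax_n", strict = FALSE)
  check_pos(km_n, "km_n")
  check_pos(transpiration_potential, "transpiration_potential", strict = FALSE)
  if (psi_wilt >= psi_stress || psi_stress >= 0)
    abort("need psi_wilt < psi_stress < 0")
  structure(list(vmax_n = vmax_n, km_n = km_n,
                 transpiration_potential = transpiration_potential,
                 psi_wilt = psi_wilt, psi_stress = psi_stress),
            class = "uptake_params")
}

#' Split fertilization schedule
#'
#' Two pulses of ammonium nitrate (N split 50:50 between NH4+ and NO3-)
#' applied as a dissolved surface flux: `split_first` of `total_n` over
#' `pulse_duration` days starting at `t1`, the remainder at `t2`.
#'
#' @param t1,t2 application days of season (0 < t1 <= t2 <= 70 by default
#'   convention; `t_max` only enforced by the timing grid, not here).
#' @param total_n seasonal rate (kg N / ha), default 144.
#' @param split_first fraction applied at `t1`, default 1/3.
#' @param pulse_duration days over which each pulse dissolves, default 1.
#' @return a list of class `fertilizer_schedule`.
#' @export
fertilizer_schedule <- function(t1, t2, total_n = 144, split_first = 1 / 3,
                                pulse_duration = 1) {
  check_pos(t1, "t1"); check_pos(t2, "t2")
  if (t1 > t2) abort("need t1 <= t2")
  check_pos(total_n, "total_n", strict = FALSE)
  check_pos(pulse_duration, "pulse_duration")
  if (split_first <= 0 || split_first >= 1)
    abort("`split_first` must be in (0, 1)")
  structure(list(t1 = t1, t2 = t2, total_n = total_n,
                 split_first = split_first, pulse_duration = pulse_duration),
            class = "fertilizer_schedule")
}

#' Initial column nitrogen pools and moisture
#'
#' Pools are spread uniformly over the column depth so that the depth
#' integral of each pool equals the stated area density. Defaults: 41.6 kg
#' N/ha nitrate, 6.6 kg N/ha ammonium (solution + sorbed) and 191 kg N/ha
#' organic N; water initialized at a uniform field-capacity pressure head.
#'
#' @param no3,nh4,org initial pools (kg N / ha).
#' @param psi_init initial uniform pressure head (cm, negative).
#' @return a list of class `initial_pools`.
#' @export
initial_pools <- function(no3 = 41.6, nh4 = 6.6, org = 191, psi_init = -100) {
  for (nm in c("no3", "nh4", "org")) check_pos(get(nm), nm, strict = FALSE)
  if (psi_init > 0) abort("`psi_init` must be <= 0")
  structure(list(no3 = no3, nh4 = nh4, org = org, psi_init = psi_init),
            class = "initial_pools")
}

#' Column discretization
#'
#' @param depth column depth (cm).
#' @param dz node spacing (cm); `depth / dz` must be a whole number.
#' @return a list of class `column_grid`.
#' @export
column_grid <- function(depth = 80, dz = 1) {
  check_pos(depth, "depth"); check_pos(dz, "dz")
  if (abs(depth / dz - round(depth / dz)) > 1e-9)
    abort("`depth` must be a whole multiple of `dz`")
  if (round(depth / dz) < 3) abort("column needs at least 3 nodes")
  structure(list(depth = depth, dz = dz), class = "column_grid")
}

#' Time-integration controls for the column solver
#'
#' @param dt_max,dt_min bounds of the adaptive sub-daily step (days).
#' @param max_picard Picard iteration cap per water step before the step is
#'   halved; exhaustion at `dt_min` is a hard error.
#' @param bottom_no_flow replace the free-drainage bottom boundary with a
#'   no-flow boundary (used in verification runs).
#' @return a list of class `solver_control`.
#' @export
solver_control <- function(dt_max = 0.25, dt_min = 1e-6, max_picard = 30,
                           bottom_no_flow = FALSE) {
  check_pos(dt_max, "dt_max"); check_pos(dt_min, "dt_min")
  if (dt_min > dt_max) abort("need dt_min <= dt_max")
  structure(list(dt_max = dt_max, dt_min = dt_min,
                 max_picard = as.integer(max_picard),
                 bottom_no_flow = isTRUE(bottom_no_flow)),
            class = "solver_control")
}

#' Full soil-crop model configuration
#'
#' Bundles all parameter groups of the column model. Every argument has a
#' documented default; pass replacements built with the corresponding
#' constructor to change any group.
#'
#' @param hydraulics [soil_hydraulics()].
#' @param transport [transport_params()].
#' @param reactions [reaction_params()].
#' @param roots [root_params()].
#' @param uptake [uptake_params()].
#' @param pools [initial_pools()].
#' @param grid [column_grid()].
#' @param control [solver_control()].
#' @return a list of class `model_config`.
#' @export
model_config <- function(hydraulics = soil_hydraulics(),
                         transport = transport_params(),
                         reactions = reaction_params(),
                         roots = root_params(),
                         uptake = uptake_params(),
                         pools = initial_pools(),
                         grid = column_grid(),
                         control = solver_control()) {
  stopifnot(inherits(hydraulics, "soil_hydraulics"),
            inherits(transport, "transport_params"),
            inherits(reactions, "reaction_params"),
            inherits(roots, "root_params"),
            inherits(uptake, "uptake_params"),
            inherits(pools, "initial_pools"),
            inherits(grid, "column_grid"),
            inherits(control, "solver_control"))
  if (grid$depth < roots$max_root_depth)
    warn("column shallower than `max_root_depth`; roots will be truncated")
  structure(list(hydraulics = hydraulics, transport = transport,
                 reactions = reactions, roots = roots, uptake = uptake,
                 pools = pools, grid = grid, control = control),
            class = "model_config")
}
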