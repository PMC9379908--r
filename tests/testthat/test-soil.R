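test_that("initial pools integrate exactly to the configured area densities", {
  cfg <- model_config()
  col <- init_column(cfg)
  pools <- attr(col, "pool_integrals")
  expect_equal(unname(pools["no3"]), 41.6)
  expect_equal(unname(pools["nh4"]), 6.6)
  expect_equal(unname(pools["org"]), 191)
  # closed-form integral oracle: uniform profile, halved node spacing
  cfg2 <- model_config(grid = column_grid(depth = 80, dz = 0.5))
  pools2 <- attr(init_column(cfg2), "pool_integrals")
  expect_equal(unname(pools2), unname(pools), tolerance = 1e-10)
  # zero-inventory configuration
  z <- model_config(pools = initial_pools(no3 = 0, nh4 = 0, org = 0))
  expect_true(all(attr(init_column(z), "pool_integrals") == 0))
  expect_error(column_grid(depth = 80, dz = 33), "multiple")
})

test_that("hydrostatic equilibrium is stationary under no-flow boundaries", {
  cfg <- model_config()
  n <- 80
  z <- seq(0.5, 79.5, by = 1)
  psi_b <- -120
  psi0 <- psi_b + (z - max(z))          # total head constant (z downward)
  out <- richards_advance(psi0, rain_mm = rep(0, 5), cfg,
                          bottom_no_flow = TRUE)
  expect_equal(out$psi, psi0, tolerance = 1e-3)
  expect_equal(out$residual_mm, 0, tolerance = 1e-6)
})

test_that("constant rain below Ks approaches the analytic steady state", {
  cfg <- model_config()
  q <- 3                                  # mm/day, well below Ks = 108 mm/d
  out <- richards_advance(rep(-100, 80), rain_mm = rep(q, 400), cfg)
  # oracle: steady uniform downward flux has K(psi) = q; invert numerically
  f <- function(psi) vg_k_r(psi, cfg$hydraulics) - q / 10
  psi_star <- uniroot(f, c(-500, -1), tol = 1e-10)$root
  mid <- 20:60                            # away from both boundaries
  expect_equal(out$psi[mid], rep(psi_star, length(mid)), tolerance = 0.02)
  # at steady state drainage matches rain
  out2 <- richards_advance(out$psi, rain_mm = rep(q, 5), cfg)
  expect_equal(out2$drainage_mm, 5 * q, tolerance = 0.01)
})

test_that("water balance closes for wet, dry and deluge forcing", {
  cfg <- model_config()
  sched <- fertilizer_schedule(14.4, 36)
  for (regime in c("historic", "wet", "dry")) {
    rec <- make_record(1, seed = 21, regime = regime)
    res <- simulate_season(extract_season(rec, 2001), sched, cfg)
    expect_lt(abs(res$balance_residual_water_mm),
              0.005 * max(res$rain_mm, 1))
    expect_lt(abs(res$balance_residual_n),
              0.01 * (res$initial_n + res$applied_n))
  }
})

test_that("saturated-column breakthrough matches the closed-form solution", {
  # continuous injection into a saturated column at constant pore velocity;
  # compare against the analytic advection-dispersion breakthrough profile
  theta <- 0.45
  v <- 10                                  # cm/day pore velocity
  q <- v * theta
  disp <- 20                               # cm^2/day
  dz <- 0.05                               # fine grid: upwinding adds
  times <- c(1, 2, 4)                      # ~v*dz/2 numerical dispersion
  prof <- ade_breakthrough(n_nodes = 2000, dz = dz, theta = theta, q = q,
                           disp = disp, c_in = 1, out_times = times,
                           dt = 5e-4)
  x <- (seq_len(2000) - 0.5) * dz
  for (i in seq_along(times)) {
    exact <- ogata_banks(x, times[i], v, disp, c_in = 1)
    expect_lt(max(abs(prof[i, ] - exact)), 0.02)   # within 2% of inlet
  }
})

test_that("transport conserves mass with zero velocity and no reactions", {
  cfg <- model_config(
    reactions = reaction_params(0, 0, 0, 0, 0),
    uptake = uptake_params(vmax_n = 0, transpiration_potential = 0),
    control = solver_control(bottom_no_flow = TRUE))
  sched <- fertilizer_schedule(5, 20, total_n = 0)
  # uniform head, no flow anywhere: total mass of each species constant
  res <- simulate_season(rep(0, 40), sched, cfg)
  expect_equal(res$final_n, res$initial_n, tolerance = 1e-8)
  expect_equal(res$leached_n, 0)
  expect_equal(res$uptake_n, 0)
})

test_that("reaction-only organic pool decays exponentially", {
  k <- 0.01
  cfg <- model_config(
    reactions = reaction_params(k_org_to_nh4 = k, k_nh4_to_org = 0,
                                k_org_to_no3 = 0, k_no3_to_org = 0,
                                k_nitrification = 0),
    uptake = uptake_params(vmax_n = 0, transpiration_potential = 0),
    pools = initial_pools(no3 = 0, nh4 = 0, org = 191),
    control = solver_control(bottom_no_flow = TRUE))
  sched <- fertilizer_schedule(5, 20, total_n = 0)
  days <- 60
  res <- simulate_season(rep(0, days), sched, cfg)
  org_final <- mg_cm2_to_kg_ha(sum(res$state$c_org) * cfg$grid$dz)
  expect_equal(org_final, 191 * exp(-k * days), tolerance = 2e-3)
  # total N unchanged (mineralized N stays in the closed column)
  expect_equal(res$final_n, 191, tolerance = 1e-8)
})

test_that("root profile follows the closed-form logistic in time and depth", {
  p <- root_params()
  rp0 <- root_profile(0, p)
  expect_true(all(rp0$rld <= 0.01 * p$max_rld_surface))  # logistic seed
  # front is nondecreasing and saturates at max_root_depth
  depths <- vapply(seq(0, 200, by = 10),
                   function(t) attr(root_profile(t, p), "root_depth"),
                   numeric(1))
  expect_true(all(diff(depths) >= 0))
  expect_equal(depths[length(depths)], p$max_root_depth, tolerance = 1e-6)
  # direct formula evaluation oracle at t = 30
  t <- 30
  lg <- function(r) 1 / (1 + (1 / 0.005 - 1) * exp(-r * t))
  zr <- 10 + 40 * lg(0.2)
  rp <- root_profile(t, p)
  expect_equal(attr(rp, "root_depth"), zr)
  z <- 20.5
  expect_equal(rp$rld[rp$depth == z], 3 * lg(0.2) * exp(-0.03 * (z - 10)))
  expect_true(all(rp$rld[rp$depth < 10 | rp$depth > zr] == 0))
})

test_that("fertilizer application integrates exactly and is never negative", {
  cfg <- fast_config()
  rec <- make_record(1, seed = 30)
  season <- extract_season(rec, 2001)
  res <- simulate_season(season, fertilizer_schedule(14.4, 36), cfg)
  expect_equal(res$applied_n, 144, tolerance = 1e-12)
  expect_true(res$uptake_n >= 0 && res$leached_n >= 0)
  expect_true(all(res$state$theta >= cfg$hydraulics$theta_r - 1e-9))
  expect_true(all(res$state$theta <= cfg$hydraulics$theta_s + 1e-9))
  expect_true(all(res$state$c_no3 >= -1e-12))
  # uptake cannot exceed what was ever available
  expect_lt(res$uptake_n, res$initial_n + res$applied_n)
  # a t1 = t2 schedule concentrates the whole dose at one time
  res2 <- simulate_season(season, fertilizer_schedule(36, 36), cfg)
  expect_equal(res2$applied_n, 144, tolerance = 1e-12)
})

test_that("no-fertilizer uptake is bounded by initial plus mineralized N", {
  cfg <- fast_config()
  rec <- make_record(1, seed = 31)
  res <- simulate_season(extract_season(rec, 2001),
                         fertilizer_schedule(14.4, 36, total_n = 0), cfg)
  expect_equal(res$applied_n, 0)
  expect_lt(res$uptake_n, res$initial_n)
})

test_that("doubling rainfall on a wet season strictly increases leaching", {
  cfg <- fast_config()
  rec <- make_record(1, seed = 32, regime = "historic")
  season <- extract_season(rec, 2001)
  sched <- fertilizer_schedule(14.4, 36)
  base <- simulate_season(season, sched, cfg)
  doubled <- season
  doubled$rain_mm <- 2 * doubled$rain_mm
  wet <- simulate_season(doubled, sched, cfg)
  expect_gt(wet$leached_n, base$leached_n)
})

test_that("grid and time refinement changes uptake by less than 2%", {
  rec <- make_record(1, seed = 33)
  season <- extract_season(rec, 2001)
  sched <- fertilizer_schedule(14.4, 36)
  coarse <- simulate_season(season, sched, model_config(
    grid = column_grid(depth = 80, dz = 2),
    control = solver_control(dt_max = 0.25)))
  fine <- simulate_season(season, sched, model_config(
    grid = column_grid(depth = 80, dz = 1),
    control = solver_control(dt_max = 0.125)))
  expect_lt(abs(fine$uptake_n - coarse$uptake_n) / fine$uptake_n, 0.02)
})

test_that("season_result tidiers expose the ledgers", {
  cfg <- fast_config()
  rec <- make_record(1, seed = 34)
  res <- simulate_season(extract_season(rec, 2001),
                         fertilizer_schedule(14.4, 36), cfg,
                         save_daily = TRUE)
  td <- tidy(res)
  expect_true(all(c("quantity", "value", "unit") %in% names(td)))
  expect_equal(td$value[td$quantity == "applied_n"], 144, tolerance = 1e-12)
  gl <- glance(res)
  expect_equal(gl$uptake_n, res$uptake_n)
  expect_equal(nrow(res$daily), 122)
  # cumulative series are nondecreasing
  expect_true(all(diff(res$daily$cum_uptake_kg_ha) >= -1e-9))
  expect_true(all(diff(res$daily$cum_leach_kg_ha) >= -1e-9))
})
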