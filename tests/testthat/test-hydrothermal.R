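test_that("snow step follows the degree-day rule", {
  p <- hydro_params(degree_day_factor = 3, melt_threshold = 0)
  # below threshold: no melt, precip accumulates as snow
  s <- snow_step(10, 5, -1, p)
  expect_equal(s$swe, 15)
  expect_equal(s$melt_mm, 0)
  expect_equal(s$rain_mm, 0)
  # nothing to melt
  s <- snow_step(0, 0, 5, p)
  expect_equal(s$melt_mm, 0)
  # melt = min(swe, factor * excess): 3 * 2 = 6 from a 10 mm pack
  s <- snow_step(10, 0, 2, p)
  expect_equal(s$melt_mm, 6)
  expect_equal(s$swe, 4)
  # melt capped by available snow
  s <- snow_step(2, 0, 10, p)
  expect_equal(s$melt_mm, 2)
  expect_equal(s$swe, 0)
})

test_that("production step conserves mass and follows the flux order", {
  p <- hydro_params()
  z <- list(soil = 0, ground = 0, lake = 0)
  r <- production_step(z, 0, -5, p)
  expect_equal(r$runoff_mm, 0)
  expect_equal(unlist(r$state), unlist(z))

  # soil at capacity, 5 mm input, no ET: the 5 mm spill to the lake reservoir
  p2 <- hydro_params(soil_capacity = 100, infiltration_coeff = 0,
                     soil_drain_coeff = 0, ground_drain_coeff = 0,
                     lake_drain_coeff = 0.1, et_coeff = 0)
  r <- production_step(list(soil = 100, ground = 0, lake = 0), 5, 10, p2)
  expect_equal(r$state$soil, 100)
  expect_equal(r$state$lake, 5 * 0.9)
  expect_equal(r$runoff_mm, 0.5)

  # conservation over random states and inputs
  set.seed(42)
  for (k in 1:50) {
    st <- list(soil = runif(1, 0, 120), ground = runif(1, 0, 200),
               lake = runif(1, 0, 100))
    input <- runif(1, 0, 40); ta <- runif(1, -10, 25)
    r <- production_step(st, input, ta, p)
    ds <- sum(unlist(r$state)) - sum(unlist(st))
    expect_lt(abs(ds - (input - r$et_mm - r$runoff_mm)), 1e-9)
  }
})

test_that("routing translates an impulse downstream with one-day lag", {
  g <- line_grid(2)
  p <- hydro_params(routing_coeff = 1)
  # impulse of 10 mm in the upstream cell (cell 2)
  r1 <- route_step(g, c(0, 10), c(0, 0), c(0, 0), p)
  v <- 10 / 1000 * g$cells$area_km2[2] * 1e6
  expect_equal(r1$outflow_m3[2], v)
  expect_equal(r1$outflow_m3[1], 0)
  r2 <- route_step(g, c(0, 0), r1$storage, r1$outflow_m3, p)
  expect_equal(r2$outflow_m3[1], v)   # pure translation
})

test_that("routing conserves volume through the network", {
  g <- small_grid(8)
  p <- hydro_params(routing_coeff = 0.4)
  storage <- numeric(8); prev <- numeric(8)
  set.seed(1)
  total_in <- 0; total_out <- 0
  for (t in 1:200) {
    runoff <- if (t <= 5) runif(8, 0, 5) else numeric(8)
    total_in <- total_in + sum(runoff / 1000 * g$cells$area_km2 * 1e6)
    r <- route_step(g, runoff, storage, prev, p)
    storage <- r$storage
    prev <- r$outflow_m3
    total_out <- total_out + r$outflow_m3[g$outlet_id]
  }
  in_transit <- sum(prev[setdiff(seq_len(8), g$outlet_id)])
  expect_lt(abs(total_in - total_out - sum(storage) - in_transit), 1e-6)
})

test_that("thermal step has the equilibrium fixed point and mixes by discharge", {
  g <- line_grid(3)
  tp <- thermal_params(exchange_coeff = 0.3, eq_temp_offset = 0,
                       eq_temp_radiation_gain = 0)
  n <- 3
  # fixed point: water at T_eq stays at T_eq
  t_eq <- rep(12, n)
  out <- thermal_step(g, t_eq, rep(100, n), rep(50, n), numeric(n),
                      air_temp = rep(12, n), shortwave = numeric(n), tp)
  expect_equal(out, t_eq)
  # exchange_coeff 1: temperature jumps to T_eq in one step (no inflow)
  tp1 <- thermal_params(exchange_coeff = 1, eq_temp_offset = 0,
                        eq_temp_radiation_gain = 0)
  out <- thermal_step(g, c(4, 4, 4), numeric(n), numeric(n), numeric(n),
                      air_temp = rep(15, n), shortwave = numeric(n), tp1)
  expect_equal(out, rep(15, n))
})

test_that("two equal-discharge inflows mix to their mean when exchange is off", {
  # confluence: cells 2 and 3 both drain into cell 1
  g <- make_watershed(3, seed = 2)
  g$cells$downstream_id <- c(NA, 1L, 1L)
  g$cells$n_sub <- rep(1L, 3); g$sub_fractions <- rep(list(1), 3)
  tp <- thermal_params(exchange_coeff = 1e-12)
  wt <- c(0, 10, 20)
  out <- thermal_step(g, wt, upstream_outflow_m3 = c(0, 500, 500),
                      local_runoff_m3 = numeric(3), dam_release_m3 = numeric(3),
                      air_temp = rep(0, 3), shortwave = numeric(3), tp)
  expect_equal(out[1], 15, tolerance = 1e-9)
})

test_that("negative discharge is rejected by the thermal step", {
  g <- line_grid(2)
  expect_error(thermal_step(g, c(4, 4), c(-1, 0), numeric(2), numeric(2),
                            c(5, 5), numeric(2), thermal_params()),
               "negative discharge")
})

test_that("compiled engine matches the naive step-function loop to 1e-10", {
  g <- line_grid(3)
  f <- small_forcing(g, 1999, seed = 13)
  hp <- hydro_params(); tp <- thermal_params()
  ref <- naive_simulate(g, f, hp, tp, spinup = 0)
  cube <- simulate_hydrothermal(g, f, hp, tp, spinup = 0)
  expect_lt(max(abs(cube$discharge - ref$discharge)), 1e-10)
  expect_lt(max(abs(cube$water_temp - ref$water_temp)), 1e-10)
})

test_that("engine matches the naive loop on a branched multi-subarea grid", {
  g <- small_grid(6, seed = 21)
  f <- small_forcing(g, 2000, seed = 14)
  hp <- hydro_params(degree_day_factor = 5, routing_coeff = 0.3)
  tp <- thermal_params(exchange_coeff = 0.4)
  dam <- rep(0.5, length(f$dates))
  ref <- naive_simulate(g, f, hp, tp, spinup = 30, dam_release = dam)
  cube <- simulate_hydrothermal(g, f, hp, tp, spinup = 30, dam_release = dam)
  expect_lt(max(abs(cube$discharge - ref$discharge)), 1e-10)
  expect_lt(max(abs(cube$water_temp - ref$water_temp)), 1e-10)
})

test_that("a single-cell run converges to the linear-reservoir steady state", {
  g <- make_watershed(1, seed = 1)
  f <- make_meteorology(g, 2000:2009, seed = 3, amplitude = 0, noise_sd = 0,
                        mean_temp = 10, precip_prob = 1, precip_mean = 4)
  f$precip[] <- 3   # constant input
  cube <- simulate_hydrothermal(g, f, spinup = 365)
  q <- cube$discharge[, 1]
  n <- length(q)
  expect_lt(abs(q[n] - q[n - 1]), 1e-6)
  # steady state: outflow equals net input (precip - ET)
  expect_gt(q[n], 0)
})

test_that("simulation is deterministic and excludes spin-up days", {
  g <- small_grid(5)
  f <- small_forcing(g, 1999:2000)
  a <- simulate_hydrothermal(g, f)
  b <- simulate_hydrothermal(g, f)
  expect_identical(a$discharge, b$discharge)
  expect_identical(a$water_temp, b$water_temp)
  expect_equal(length(a$dates), length(f$dates) - 365)
  expect_equal(min(a$dates), f$dates[366])
})

test_that("water temperature respects its floor and discharge stays nonnegative", {
  g <- small_grid(8)
  f <- small_forcing(g, 1999:2001, mean_temp = -2)  # cold watershed
  cube <- simulate_hydrothermal(g, f)
  expect_true(all(cube$water_temp >= 0))
  expect_true(all(cube$discharge >= 0))
})

test_that("uniform warming never cools the river anywhere", {
  g <- small_grid(10)
  f0 <- small_forcing(g, 1999:2002)
  f2 <- make_meteorology(g, 1999:2002, seed = 2, warming_offset = 2)
  c0 <- simulate_hydrothermal(g, f0)
  c2 <- simulate_hydrothermal(g, f2)
  expect_true(all(c2$water_temp >= c0$water_temp - 1e-12))
})

test_that("forcing shorter than spin-up is rejected", {
  g <- small_grid(3)
  f <- small_forcing(g, 2000)
  expect_error(simulate_hydrothermal(g, f, spinup = 400), "spin-up")
})

test_that("parameter constructors validate their invariants", {
  expect_error(hydro_params(soil_capacity = 0), "soil_capacity")
  expect_error(hydro_params(routing_coeff = 1.5), "<= 1")
  expect_error(hydro_params(degree_day_factor = -1), ">= 0")
  expect_error(thermal_params(exchange_coeff = 0), "exchange_coeff")
  expect_error(thermal_params(min_water_temp = -1), "min_water_temp")
})
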