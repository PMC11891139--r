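test_that("decadal monthly stats reduce constant fields exactly", {
  g <- small_grid(4)
  f <- small_forcing(g, 1979:1982)
  cube <- simulate_hydrothermal(g, f)
  spec <- scenario_spec("historical", "1980s")
  spec$years <- 1980:1982
  c10 <- cube; c10$water_temp[] <- 10
  s <- decadal_monthly_stats(list(c10), spec)
  expect_equal(s$month, 5:10)   # May-October only
  expect_true(all(s$mean_temp == 10))
  expect_true(all(s$sd_temp == 0))
  # two members at constant 10 and 12 average to 11
  c12 <- cube; c12$water_temp[] <- 12
  s2 <- decadal_monthly_stats(list(c10, c12), spec)
  expect_true(all(s2$mean_temp == 11))
  # invariant to member ordering
  s2r <- decadal_monthly_stats(list(c12, c10), spec)
  expect_equal(s2$mean_temp, s2r$mean_temp)
  expect_equal(s2$sd_temp, s2r$sd_temp)
})

test_that("decadal stats demand full year coverage", {
  g <- small_grid(3)
  f <- small_forcing(g, 1979:1982)
  cube <- simulate_hydrothermal(g, f)
  expect_error(decadal_monthly_stats(list(cube),
                                     scenario_spec("historical", "1980s")),
               "lacks years")
})

test_that("percent change matches hand arithmetic and the identity cases", {
  expect_equal(percent_change(19.7, 17), 16)            # nearest integer
  expect_equal(percent_change(19.7, 17, digits = 1), 15.9)
  expect_equal(percent_change(18.6, 17, digits = 1), 9.4)
  expect_equal(percent_change(15, 15), 0)
  # antisymmetric under opposite perturbations
  expect_equal(percent_change(12 + 1, 12, digits = NA),
               -percent_change(12 - 1, 12, digits = NA))
  expect_error(percent_change(10, 0), "baseline")
})

test_that("exceedance counting respects the window and the threshold", {
  dates <- seq(as.Date("2000-01-01"), as.Date("2001-12-31"), by = "day")
  md <- format(dates, "%m-%d")
  # constant 19: never exceeds 20
  e <- exceedance_days(dates, rep(19, length(dates)))
  expect_true(all(e$n_exceed == 0))
  # constant 21: every day of the 32-day window, both years
  e <- exceedance_days(dates, rep(21, length(dates)))
  expect_equal(e$n_exceed, c(32, 32))
  # monotone under uniform warming
  set.seed(5)
  temp <- 15 + 6 * sin(2 * pi * seq_along(dates) / 365) + rnorm(length(dates))
  e0 <- exceedance_days(dates, temp)
  e2 <- exceedance_days(dates, temp + 2)
  expect_true(all(e2$n_exceed >= e0$n_exceed))
})

test_that("the release controller cools the managed window and only it", {
  g <- small_grid(8)
  # a hot summer so the window genuinely exceeds 20 degC
  f <- make_meteorology(g, 1999:2000, seed = 2, warming_offset = 5)
  rule <- stmp_rule(threshold = 20, gain = 2, max_release = 50)
  res <- stmp_controller(g, f, rule = rule)
  out_col <- match(g$outlet_id, res$cube$cell_ids)
  base_e <- exceedance_days(res$baseline$dates,
                            res$baseline$water_temp[, out_col])
  adj_e <- exceedance_days(res$cube$dates, res$cube$water_temp[, out_col])
  expect_gt(sum(base_e$n_exceed), 0)   # the probe is a real heatwave
  expect_lte(sum(adj_e$n_exceed), sum(base_e$n_exceed))
  # releases only inside the window, never above the cap
  md <- format(res$releases$date, "%m-%d")
  outside <- md < "07-20" | md > "08-20"
  expect_true(all(res$releases$release_m3s[outside] == 0))
  expect_true(all(res$releases$release_m3s <= rule$max_release))
})

test_that("the controller is inert when temperatures stay below threshold", {
  g <- small_grid(5)
  f <- small_forcing(g, 1999:2000)   # baseline peaks well below 30
  rule <- stmp_rule(threshold = 30, gain = 5, max_release = 100)
  res <- stmp_controller(g, f, rule = rule)
  expect_true(all(res$releases$release_m3s == 0))
  expect_equal(res$cube$discharge, res$baseline$discharge)
  expect_equal(res$cube$water_temp, res$baseline$water_temp)
})
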