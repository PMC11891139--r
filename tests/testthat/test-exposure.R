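test_that("default threshold table matches the tolerance data", {
  tab <- thermal_thresholds()
  expect_setequal(tab$life_stage,
                  c("embryo", "yolk_sac_larvae", "feeding_larvae18",
                    "feeding_larvae20", "juvenile"))
  expect_true(all(tab$optimal_low == 14))
  expect_equal(tab$optimal_high[tab$life_stage == "embryo"], 18)
  expect_equal(tab$optimal_high[tab$life_stage == "yolk_sac_larvae"], 20)
  expect_equal(tab$optimal_high[tab$life_stage == "feeding_larvae18"], 18)
  expect_equal(tab$optimal_high[tab$life_stage == "feeding_larvae20"], 20)
  expect_equal(tab$optimal_high[tab$life_stage == "juvenile"], 18)
  expect_true(all(is.na(tab$critical_low)))  # no critical bound by default
  # shipped CSV is identical to the built-in table
  csv <- read_thresholds_csv(system.file("extdata", "thermal_thresholds.csv",
                                         package = "riverTe"))
  expect_equal(as.data.frame(csv), as.data.frame(tab))
})

test_that("interval classification reproduces the band rules", {
  emb <- thermal_thresholds("embryo")
  ys <- thermal_thresholds("yolk_sac_larvae")
  expect_equal(classify_interval(15, 17, emb), 1L)   # inside the optimal band
  expect_equal(classify_interval(10, 12, emb), 0L)   # below it
  expect_equal(classify_interval(20.5, 22, ys), 2L)  # sub-optimal
  # straddle: conservative takes the max band, mean mode the midpoint band
  expect_equal(classify_interval(13, 15, emb, mode = "conservative"), 1L)
  expect_equal(classify_interval(13, 15, emb, mode = "mean"), 1L)
  expect_equal(classify_interval(17, 19, emb, mode = "conservative"), 2L)
  expect_equal(classify_interval(17, 19, emb, mode = "mean"), 1L)
  # boundary conventions: optimal band closed at both ends
  expect_equal(classify_interval(14, 14, emb), 1L)
  expect_equal(classify_interval(18, 18, emb), 1L)
  expect_equal(classify_interval(18.0001, 18.0001, emb), 2L)
  # category 3 reachable only with an explicit critical bound
  crit <- list(optimal_low = 14, optimal_high = 18, critical_low = 24)
  expect_equal(classify_interval(24, 25, crit), 3L)
  expect_equal(classify_interval(23, 23.9, crit), 2L)
  expect_error(classify_interval(5, 3, emb), "t_a")
  expect_error(classify_interval(15, 16, emb, mode = "upper"), "arg")
})

test_that("classifier agrees with the brute-force lattice oracle", {
  set.seed(2024)
  for (k in 1:500) {
    lo <- runif(1, 8, 16)
    thr <- list(optimal_low = lo, optimal_high = lo + runif(1, 1, 6),
                critical_low = NA_real_)
    if (runif(1) < 0.5)
      thr$critical_low <- thr$optimal_high + runif(1, 0.5, 5)
    t_a <- runif(1, -5, 30)
    t_b <- t_a + runif(1, 0, 8)
    expect_identical(classify_interval(t_a, t_b, thr),
                     lattice_classify(t_a, t_b, thr))
  }
})

test_that("band function is monotone in temperature", {
  t <- seq(-5, 35, by = 0.05)
  b <- te_band(t, 14, 18, 26)
  expect_true(all(diff(b) >= 0))
})

test_that("life-stage windows resolve to the declared calendar ranges", {
  w <- stage_window("embryo", 2055)
  expect_length(w, 41)
  expect_equal(min(w), as.Date("2055-05-15"))
  expect_equal(max(w), as.Date("2055-06-24"))
  j <- stage_window("juvenile", 2000)
  expect_equal(range(j), as.Date(c("2000-05-01", "2000-10-31")))
  expect_true(all(as.integer(format(j, "%m")) %in% 5:10))
  # yolk-sac window overlaps the embryo window from 24 May to 24 June
  ys <- stage_window("yolk_sac_larvae", 2000)
  emb <- stage_window("embryo", 2000)
  ov <- range(as.Date(intersect(ys, emb), origin = "1970-01-01"))
  expect_equal(ov, as.Date(c("2000-05-24", "2000-06-24")))
  expect_error(stage_window("adult", 2000), "unknown life stage")
})

test_that("daily categories cover only the stage window", {
  g <- small_grid(3)
  f <- small_forcing(g, 1999:2000)
  cube <- simulate_hydrothermal(g, f)
  cube$water_temp[] <- 16
  d <- daily_te(cube, thermal_thresholds("embryo"))
  expect_true(all(d$te == 1L))
  expect_equal(sort(unique(d$date)), stage_window("embryo", 2000))
  cube$water_temp[] <- 5
  d0 <- daily_te(cube, thermal_thresholds("embryo"))
  expect_true(all(d0$te == 0L))
})

test_that("a mid-window temperature step flips the category on the step day", {
  g <- small_grid(1)
  f <- small_forcing(g, 1999:2000)
  cube <- simulate_hydrothermal(g, f)
  step_day <- as.Date("2000-06-15")
  cube$water_temp[] <- ifelse(cube$dates < step_day, 16, 21)
  d <- daily_te(cube, thermal_thresholds("yolk_sac_larvae"))
  expect_true(all(d$te[d$date < step_day] == 1L))
  expect_true(all(d$te[d$date >= step_day] == 2L))
})

test_that("exposure aggregation averages categories in the declared order", {
  g <- small_grid(2)
  f <- small_forcing(g, 1999:2000)
  cube <- simulate_hydrothermal(g, f)
  cube$water_temp[] <- 16
  d1 <- daily_te(cube, thermal_thresholds("embryo"))
  cube2 <- cube; cube2$water_temp[] <- 21
  d2 <- daily_te(cube2, thermal_thresholds("embryo"))
  # one member, constant category 1
  s1 <- aggregate_te(list(d1))
  expect_true(all(s1$mean_te == 1))
  expect_true(all(s1$sd_te == 0))
  # two members at constant categories 1 and 2 average to 1.5
  s12 <- aggregate_te(list(d1, d2))
  expect_true(all(s12$mean_te == 1.5))
  expect_true(all(s12$sd_te > 0))
  expect_true(all(s12$mean_te >= 0 & s12$mean_te <= 3))
})

test_that("warming never decreases the exposure index (monotonicity)", {
  g <- small_grid(5)
  f0 <- small_forcing(g, 1999:2000)
  f2 <- make_meteorology(g, 1999:2000, seed = 2, warming_offset = 2)
  c0 <- simulate_hydrothermal(g, f0)
  c2 <- simulate_hydrothermal(g, f2)
  for (ls in thermal_thresholds()$life_stage) {
    thr <- thermal_thresholds(ls)
    s0 <- aggregate_te(list(daily_te(c0, thr)))
    s2 <- aggregate_te(list(daily_te(c2, thr)))
    key0 <- paste(s0$scope, s0$month)
    key2 <- paste(s2$scope, s2$month)
    expect_identical(key0, key2)
    expect_true(all(s2$mean_te >= s0$mean_te))
  }
})

test_that("with default thresholds the aggregated index never exceeds 2", {
  g <- small_grid(4)
  f <- make_meteorology(g, 1999:2000, seed = 2, warming_offset = 10)
  cube <- simulate_hydrothermal(g, f)
  s <- aggregate_te(list(daily_te(cube, thermal_thresholds("juvenile"))))
  expect_true(all(s$mean_te <= 2))
})

test_that("habitat masks select cells and average their exposure", {
  g <- small_grid(10)
  masks <- make_habitat_masks(g, seed = 4)
  expect_length(masks, 4)
  for (m in masks) expect_gte(length(mask_cells(g, m)), 1)

  f <- small_forcing(g, 1999:2000)
  cube <- simulate_hydrothermal(g, f)
  cube$water_temp[] <- 16
  s <- aggregate_te(list(daily_te(cube, thermal_thresholds("embryo"))),
                    life_stage = "embryo")
  h <- habitat_te(s, masks, g)
  # uniform field: every habitat inherits the uniform value
  expect_true(all(h$mean_te == 1))
  expect_setequal(unique(h$scope), vapply(masks, `[[`, "", "name"))

  # two-cell mask with cell values 1 and 2 averages to 1.5
  m1 <- masks[[1]]
  ids <- mask_cells(g, m1)
  s2 <- s[s$month == s$month[1], ]
  s2 <- s2[s2$scope %in% as.character(g$cells$id), ]
  if (length(ids) >= 2) {
    s2$mean_te[s2$scope == as.character(ids[1])] <- 1
    s2$mean_te[s2$scope == as.character(ids[2])] <- 2
    s2 <- s2[s2$scope %in% as.character(ids[1:2]), ]
    class(s2) <- c("exposure_summary", "data.frame")
    h2 <- habitat_te(s2, structure(list(m1), class = "habitat_masks"), g)
    expect_equal(h2$mean_te, 1.5)
  }
})

test_that("a mask away from every cell is rejected", {
  g <- small_grid(4)
  far <- list(name = "nowhere",
              polygon = cbind(lon = c(0, 1, 1, 0, 0), lat = c(0, 0, 1, 1, 0)))
  expect_error(mask_cells(g, far), "intersects no grid cell")
})
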