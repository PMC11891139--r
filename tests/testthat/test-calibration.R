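test_that("rmse follows the gap-aware pairing rule", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2), c(2, 4)), sqrt(2.5))
  # gaps drop pairs, nothing else
  expect_equal(rmse(c(1, 9, 2), c(2, NA, 4)), sqrt(2.5))
  expect_true(is.na(rmse(c(1, 2), c(NA, NA))))
  expect_error(rmse(1:3, 1:2), "time index")
})

test_that("nse matches its definition", {
  obs <- c(2, 4, 6, 8)
  expect_equal(nse(obs, obs), 1)
  expect_equal(nse(rep(mean(obs), 4), obs), 0)
  expect_equal(nse(c(1, 2), c(2, 4)), 1 - 5 / 2)
  expect_error(nse(c(1, 2), c(3, 3)), "variance")
})

test_that("CMA-ES solves a 4-D sphere within the evaluation budget", {
  sphere <- function(x) sum(x^2)
  cfg <- calibration_config(
    list(a = c(-5, 5), b = c(-5, 5), c = c(-5, 5), d = c(-5, 5)),
    max_evaluations = 5000, seed = 3)
  r <- cma_es_minimize(sphere, cfg)
  expect_lt(r$best_objective, 1e-6)
  expect_lte(r$n_evaluations, 5000)
  expect_true(all(r$best_params >= -5 & r$best_params <= 5))
})

test_that("CMA-ES is deterministic given the seed and its trace never rises", {
  rosen <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  cfg <- calibration_config(list(x = c(-2, 2), y = c(-2, 2)),
                            max_evaluations = 400, seed = 8)
  r1 <- cma_es_minimize(rosen, cfg)
  r2 <- cma_es_minimize(rosen, cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_params, r2$best_params)
  expect_true(all(diff(r1$trace) <= 0))
})

test_that("a collapsed box returns that point immediately", {
  cfg <- calibration_config(list(a = c(2, 2), b = c(-1, -1)),
                            max_evaluations = 100, seed = 1)
  r <- cma_es_minimize(function(x) sum(x^2), cfg)
  expect_equal(unname(r$best_params), c(2, -1))
  expect_equal(r$n_evaluations, 1L)
})

test_that("an objective that is never finite raises an optimization error", {
  cfg <- calibration_config(list(a = c(0, 1)), max_evaluations = 50, seed = 1)
  expect_error(cma_es_minimize(function(x) NaN, cfg), "non-finite")
})

test_that("two-step calibration recovers truth from noiseless observations", {
  g <- small_grid(8)
  f <- small_forcing(g, 1999:2002)
  truth_h <- hydro_params(degree_day_factor = 4, routing_coeff = 0.5)
  truth_t <- thermal_params(exchange_coeff = 0.3, eq_temp_offset = 1)
  obs <- make_observations(g, f, truth_h, truth_t,
                           stations = c(g$outlet_id, 4),
                           noise_sd = c(flow = 0, temp = 0), seed = 3)
  fit <- calibrate_two_step(
    g, f, obs, obs,
    hydro_config = calibration_config(
      list(degree_day_factor = c(0.5, 8), routing_coeff = c(0.1, 0.95)),
      max_evaluations = 600, seed = 21),
    thermal_config = calibration_config(
      list(exchange_coeff = c(0.05, 0.9), eq_temp_offset = c(-3, 5)),
      max_evaluations = 600, seed = 22))
  expect_s3_class(fit, "hydrothermal_fit")
  expect_lt(fit$hydro_result$best_objective, 1e-3)
  expect_lt(fit$thermal_result$best_objective, 1e-3)
  # parameters recovered, not just the fit
  expect_equal(unname(coef(fit)["hydro.degree_day_factor"]), 4, tolerance = 0.05)
  expect_equal(unname(coef(fit)["thermal.exchange_coeff"]), 0.3, tolerance = 0.05)
})

test_that("station order does not change the multi-station objective", {
  g <- small_grid(8)
  f <- small_forcing(g, 1999:2000)
  obs <- make_observations(g, f, hydro_params(), thermal_params(),
                           stations = c(g$outlet_id, 4, 6),
                           noise_sd = c(flow = 0.01, temp = 0.3), seed = 5)
  d <- obs$data[obs$data$variable == "flow", c("date", "cell_id", "value")]
  cube <- obs$truth
  score <- function(dat) {
    per <- sapply(split(dat, dat$cell_id), function(s)
      rmse(cube$discharge[match(s$date, cube$dates),
                          as.character(s$cell_id[1])], s$value))
    mean(per)
  }
  expect_equal(score(d), score(d[sample(nrow(d)), ]))
})

test_that("adding gaps only removes days from the objective", {
  sim <- c(1, 2, 3, 4, 5)
  obs <- c(1.5, 2.5, 3.5, 4.5, 5.5)
  gapped <- obs; gapped[c(2, 4)] <- NA
  expect_equal(rmse(sim, gapped), rmse(sim[c(1, 3, 5)], obs[c(1, 3, 5)]))
})

test_that("calibration without usable observations fails loudly", {
  g <- small_grid(5)
  f <- small_forcing(g, 1999:2000)
  obs <- make_observations(g, f, hydro_params(), thermal_params(), seed = 1)
  empty <- data.frame(date = as.Date(character()), cell_id = integer(),
                      value = numeric())
  expect_error(calibrate_two_step(g, f, empty, obs), "step 1")
  expect_error(calibrate_two_step(g, f, obs, empty), "step 2")
})

test_that("calibration results serialise to JSON", {
  cfg <- calibration_config(list(a = c(-1, 1)), max_evaluations = 60, seed = 2)
  r <- cma_es_minimize(function(x) (x[["a"]] - 0.3)^2, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(r, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$best_params$a, unname(r$best_params["a"]), tolerance = 1e-12)
  expect_equal(js$n_evaluations, r$n_evaluations)
})
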