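#' Fit the hydrothermal model by two-step calibration
#'
#' The model's fitting function. Estimation proceeds in two steps, as in
#' operational hydrological practice: first the hydrological parameters are
#' calibrated against observed streamflow (water temperature plays no role),
#' then, with the hydrology frozen, the thermal parameters are calibrated
#' against observed water temperature. Both searches use CMA-ES
#' (\code{\link{cma_es_minimize}}) inside user-supplied parameter boxes; the
#' objective is the unweighted mean across stations of a gap-aware RMSE (or
#' negative NSE).
#'
#' Only parameters with bounds in the step's configuration are estimated;
#' all others stay at the values in \code{hydro_start} / \code{thermal_start}.
#'
#' @param grid a \code{watershed_grid}.
#' @param forcing a \code{meteo_forcing} covering calibration period plus
#'   spin-up.
#' @param obs_flow,obs_temp long data frames with columns \code{date},
#'   \code{cell_id}, \code{value} (\code{NA} = gap), or an
#'   \code{observation_set} (the relevant variable is extracted).
#' @param hydro_config,thermal_config \code{\link{calibration_config}}
#'   objects whose bounds name members of \code{\link{hydro_params}} /
#'   \code{\link{thermal_params}}. Defaults estimate
#'   \{degree_day_factor, soil_drain_coeff, lake_drain_coeff, routing_coeff\}
#'   and \{exchange_coeff, eq_temp_offset, eq_temp_radiation_gain\}.
#' @param hydro_start,thermal_start parameter sets providing fixed values
#'   and units for everything not being estimated.
#' @param spinup spin-up days for every forward run (default 365).
#' @return An object of class \code{hydrothermal_fit} with components
#'   \code{hydro}, \code{thermal} (full parameter sets with estimates
#'   substituted), \code{hydro_result}, \code{thermal_result}
#'   (\code{calibration_result}s), \code{diagnostics} (per-station RMSE for
#'   both variables), \code{cube} (forward run at the estimates) and the
#'   inputs needed by \code{predict}/\code{simulate} methods.
#' @seealso \code{\link{predict.hydrothermal_fit}},
#'   \code{\link{residuals.hydrothermal_fit}},
#'   \code{\link{simulate.hydrothermal_fit}}
#' @export
calibrate_two_step <- function(grid, forcing, obs_flow, obs_temp,
                               hydro_config = NULL, thermal_config = NULL,
                               hydro_start = hydro_params(),
                               thermal_start = thermal_params(),
                               spinup = 365) {
  stopifnot(inherits(grid, "watershed_grid"), inherits(forcing, "meteo_forcing"))
  obs_flow <- as_obs_frame(obs_flow, "flow")
  obs_temp <- as_obs_frame(obs_temp, "water_temp")
  if (!nrow(obs_flow) || all(is.na(obs_flow$value)))
    stop("no usable flow observations for calibration step 1")
  if (!nrow(obs_temp) || all(is.na(obs_temp$value)))
    stop("no usable water-temperature observations for calibration step 2")

  if (is.null(hydro_config))
    hydro_config <- calibration_config(list(
      degree_day_factor = c(0.5, 8),
      soil_drain_coeff = c(0.005, 0.3),
      lake_drain_coeff = c(0.005, 0.3),
      routing_coeff = c(0.1, 0.95)))
  if (is.null(thermal_config))
    thermal_config <- calibration_config(list(
      exchange_coeff = c(0.05, 0.9),
      eq_temp_offset = c(-3, 5),
      eq_temp_radiation_gain = c(0, 8)), seed = hydro_config$seed + 1L)

  forward <- make_forward(grid, forcing, spinup)
  dates_out <- forcing$dates[(spinup + 1L):length(forcing$dates)]

  station_idx <- function(obs) {
    split_obs <- split(obs, obs$cell_id)
    lapply(split_obs, function(d) {
      idx <- match(d$date, dates_out)
      if (anyNA(idx)) stop("observations fall outside the simulated period")
      list(col = match(d$cell_id[1], grid$cells$id), idx = idx, value = d$value)
    })
  }
  st_flow <- station_idx(obs_flow)
  st_temp <- station_idx(obs_temp)

  score <- function(mat, stations, objective) {
    per <- vapply(stations, function(s) {
      sim <- mat[s$idx, s$col]
      if (objective == "RMSE") rmse(sim, s$value) else -nse(sim, s$value)
    }, 0)
    mean(per)
  }

  hp0 <- unlist(unclass(hydro_start))
  tp0 <- unlist(unclass(thermal_start))
  bad <- setdiff(names(hydro_config$bounds), names(hp0))
  if (length(bad)) stop("unknown hydro parameter(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(names(thermal_config$bounds), names(tp0))
  if (length(bad)) stop("unknown thermal parameter(s): ", paste(bad, collapse = ", "))

  # step 1: hydrology against flow
  obj_flow <- function(x) {
    hp <- hp0; hp[names(x)] <- x
    score(forward(hp, tp0)$discharge, st_flow, hydro_config$objective)
  }
  hydro_result <- cma_es_minimize(obj_flow, hydro_config)
  hp_hat <- hp0; hp_hat[names(hydro_result$best_params)] <- hydro_result$best_params

  # step 2: thermal against water temperature, hydrology frozen
  obj_temp <- function(x) {
    tp <- tp0; tp[names(x)] <- x
    score(forward(hp_hat, tp)$water_temp, st_temp, thermal_config$objective)
  }
  thermal_result <- cma_es_minimize(obj_temp, thermal_config)
  tp_hat <- tp0; tp_hat[names(thermal_result$best_params)] <- thermal_result$best_params

  hydro_fit <- do.call(hydro_params, as.list(hp_hat))
  thermal_fit <- do.call(thermal_params, as.list(tp_hat))
  cube <- simulate_hydrothermal(grid, forcing, hydro_fit, thermal_fit,
                                spinup = spinup)

  diag_rows <- rbind(
    station_diagnostics(cube, st_flow, "flow"),
    station_diagnostics(cube, st_temp, "water_temp"))

  structure(list(
    hydro = hydro_fit, thermal = thermal_fit,
    hydro_result = hydro_result, thermal_result = thermal_result,
    diagnostics = diag_rows, cube = cube,
    grid = grid, forcing = forcing, spinup = spinup,
    obs_flow = obs_flow, obs_temp = obs_temp,
    configs = list(hydro = hydro_config, thermal = thermal_config),
    call = match.call()
  ), class = "hydrothermal_fit")
}

as_obs_frame <- function(obs, variable) {
  if (inherits(obs, "observation_set"))
    obs <- obs$data[obs$data$variable == variable,
                    c("date", "cell_id", "value")]
  stopifnot(is.data.frame(obs),
            all(c("date", "cell_id", "value") %in% names(obs)))
  obs
}

make_forward <- function(grid, forcing, spinup) {
  nd <- length(forcing$dates)
  if (spinup < 0 || spinup >= nd)
    stop("forcing period too short for the requested spin-up")
  ds <- ifelse(is.na(grid$cells$downstream_id), 0L,
               as.integer(grid$cells$downstream_id))
  topo <- as.integer(topo_order(grid))
  sub_cell <- rep(seq_len(nrow(grid$cells)), grid$cells$n_sub)
  sub_frac <- unlist(grid$sub_fractions)
  init <- c(swe = 0, soil = 20, ground = 50, lake = 10, water_temp = 4)
  dam0 <- numeric(nd)
  keep <- (spinup + 1L):nd
  function(hp_vec, tp_vec) {
    res <- engine_simulate(
      n_cells = nrow(grid$cells), downstream = ds, topo = topo,
      area_km2 = grid$cells$area_km2,
      sub_cell = as.integer(sub_cell), sub_frac = sub_frac,
      tmean = forcing$tmean, precip = forcing$precip,
      shortwave = forcing$shortwave,
      hp = hp_vec, tp = tp_vec,
      dam_cell = as.integer(grid$dam_cell_id),
      dam_release_m3s = dam0, init = init)
    list(discharge = res$discharge[keep, , drop = FALSE],
         water_temp = res$water_temp[keep, , drop = FALSE])
  }
}

station_diagnostics <- function(cube, stations, variable) {
  mat <- if (variable == "flow") cube$discharge else cube$water_temp
  do.call(rbind, lapply(names(stations), function(cid) {
    s <- stations[[cid]]
    sim <- mat[s$idx, s$col]
    data.frame(station_cell = as.integer(cid), variable = variable,
               n_obs = sum(!is.na(s$value)),
               rmse = rmse(sim, s$value),
               nse = tryCatch(nse(sim, s$value), error = function(e) NA_real_))
  }))
}
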