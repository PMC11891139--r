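#' Generate noisy synthetic gauge observations from known-truth parameters
#'
#' Runs the forward hydrological--thermal model with "truth" parameters,
#' extracts discharge and water temperature at the requested station cells,
#' adds i.i.d. Gaussian measurement noise and masks a fraction of days at
#' random (explicit \code{NA} gaps), emulating hydrometric and temperature
#' gauge records for calibration-recovery experiments.
#'
#' @param grid a \code{watershed_grid}.
#' @param forcing a \code{meteo_forcing}.
#' @param truth_hydro a \code{\link{hydro_params}} (the truth).
#' @param truth_thermal a \code{\link{thermal_params}} (the truth).
#' @param stations integer cell ids hosting gauges; station ids are
#'   \code{"stn_<cell>"}.
#' @param noise_sd named numeric: \code{flow} (m3/s) and \code{temp} (degC)
#'   measurement noise standard deviations.
#' @param gap_fraction fraction of days masked as missing, in [0, 1).
#' @param seed integer seed (noise and gap pattern).
#' @param spinup spin-up days passed to the forward run.
#' @return An object of class \code{observation_set}: list with
#'   \code{data} (long data frame: date, station_id, cell_id, variable in
#'   \{flow, water_temp\}, value with \code{NA} gaps), \code{stations},
#'   \code{noise_sd}, \code{gap_fraction}, and the \code{truth} cube used.
#' @export
make_observations <- function(grid, forcing, truth_hydro, truth_thermal,
                              stations = grid$outlet_id,
                              noise_sd = c(flow = 0.05, temp = 0.5),
                              gap_fraction = 0, seed = 1, spinup = 365) {
  stopifnot(inherits(grid, "watershed_grid"))
  if (gap_fraction < 0 || gap_fraction >= 1)
    stop("`gap_fraction` must be in [0, 1)")
  if (!all(stations %in% grid$cells$id)) stop("unknown station cell id")
  if (!all(c("flow", "temp") %in% names(noise_sd)))
    stop("`noise_sd` needs named elements 'flow' and 'temp'")
  if (any(noise_sd < 0)) stop("noise sd must be >= 0")

  cube <- simulate_hydrothermal(grid, forcing, truth_hydro, truth_thermal,
                                spinup = spinup)
  rng <- local_rng(seed)
  nd <- length(cube$dates)
  rows <- list()
  for (cell in stations) {
    col <- match(cell, cube$cell_ids)
    for (var in c("flow", "water_temp")) {
      v <- if (var == "flow") cube$discharge[, col] else cube$water_temp[, col]
      sd_v <- if (var == "flow") noise_sd[["flow"]] else noise_sd[["temp"]]
      val <- v + if (sd_v > 0) rnorm_rng(rng, nd, sd = sd_v) else 0
      if (gap_fraction > 0) {
        gap <- runif_rng(rng, nd) < gap_fraction
        val[gap] <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        date = cube$dates, station_id = paste0("stn_", cell),
        cell_id = cell, variable = var, value = val)
    }
  }
  structure(list(data = do.call(rbind, rows), stations = stations,
                 noise_sd = noise_sd, gap_fraction = gap_fraction,
                 truth = cube),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("Synthetic gauge observations: %d stations, %d rows, %.0f%% gaps\n",
              length(x$stations), nrow(x$data),
              100 * mean(is.na(x$data$value))))
  invisible(x)
}

#' Extract one station/variable series from an observation set
#'
#' @param obs an \code{observation_set}.
#' @param cell_id station cell id.
#' @param variable \code{"flow"} or \code{"water_temp"}.
#' @return data frame with columns date, value (NA = gap).
#' @export
obs_series <- function(obs, cell_id, variable) {
  stopifnot(inherits(obs, "observation_set"))
  d <- obs$data[obs$data$cell_id == cell_id & obs$data$variable == variable, ]
  if (!nrow(d)) stop("no observations for that station/variable")
  d[order(d$date), c("date", "value")]
}

#' Write an observation set to long CSV
#' @param obs an \code{observation_set}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_observations_csv <- function(obs, path) {
  stopifnot(inherits(obs, "observation_set"))
  out <- obs$data
  out$date <- as.character(out$date)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
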