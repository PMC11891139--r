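#' Hydrological parameter set
#'
#' Parameters of the conceptual daily runoff model: degree-day snow,
#' three interconnected linear reservoirs (soil with capacity spill, ground,
#' lake) per sub-area, and a linear channel reservoir per cell.
#'
#' @param degree_day_factor snowmelt per degree above threshold (mm/degC/day).
#' @param melt_threshold air temperature separating snow from rain and
#'   enabling melt (degC).
#' @param soil_capacity soil reservoir capacity (mm); spill goes to the lake
#'   reservoir.
#' @param soil_drain_coeff,ground_drain_coeff,lake_drain_coeff linear outflow
#'   coefficients of the three reservoirs (1/day, in [0, 1]).
#' @param infiltration_coeff soil-to-ground transfer coefficient (1/day).
#' @param et_coeff temperature-index evapotranspiration rate (mm/degC/day).
#' @param routing_coeff channel linear-reservoir outflow coefficient (1/day).
#' @return A named list of class \code{hydro_params}.
#' @export
hydro_params <- function(degree_day_factor = 3, melt_threshold = 0,
                         soil_capacity = 120, soil_drain_coeff = 0.06,
                         infiltration_coeff = 0.03, ground_drain_coeff = 0.012,
                         lake_drain_coeff = 0.05, et_coeff = 0.25,
                         routing_coeff = 0.6) {
  p <- list(degree_day_factor = degree_day_factor,
            melt_threshold = melt_threshold,
            soil_capacity = soil_capacity,
            soil_drain_coeff = soil_drain_coeff,
            infiltration_coeff = infiltration_coeff,
            ground_drain_coeff = ground_drain_coeff,
            lake_drain_coeff = lake_drain_coeff,
            et_coeff = et_coeff,
            routing_coeff = routing_coeff)
  vals <- unlist(p)
  if (any(!is.finite(vals))) stop("hydro parameters must be finite")
  if (any(vals[c("degree_day_factor", "soil_drain_coeff", "infiltration_coeff",
                 "ground_drain_coeff", "lake_drain_coeff", "et_coeff",
                 "routing_coeff")] < 0))
    stop("hydro coefficients must be >= 0")
  if (any(vals[c("soil_drain_coeff", "infiltration_coeff", "ground_drain_coeff",
                 "lake_drain_coeff", "routing_coeff")] > 1))
    stop("drain/routing coefficients must be <= 1")
  if (p$soil_capacity <= 0) stop("soil_capacity must be > 0")
  structure(p, class = "hydro_params")
}

#' Thermal parameter set
#'
#' Parameters of the equilibrium-temperature water-temperature module:
#' stream temperature relaxes toward an equilibrium temperature driven by
#' air temperature and a shortwave radiation index, after discharge-weighted
#' mixing of upstream, local-runoff and dam-release inflows.
#'
#' @param exchange_coeff daily fraction of the gap to equilibrium closed by
#'   surface heat exchange (1/day, > 0).
#' @param eq_temp_offset additive offset of equilibrium temperature over
#'   mean air temperature (degC).
#' @param eq_temp_radiation_gain equilibrium-temperature gain per unit
#'   shortwave index (degC).
#' @param dam_release_temp temperature of water released at the
#'   dam-controlled headwater boundary (degC).
#' @param min_water_temp lower clip on simulated water temperature (degC).
#' @return A named list of class \code{thermal_params}.
#' @export
thermal_params <- function(exchange_coeff = 0.25, eq_temp_offset = 0.5,
                           eq_temp_radiation_gain = 2.5, dam_release_temp = 6,
                           min_water_temp = 0) {
  p <- list(exchange_coeff = exchange_coeff,
            eq_temp_offset = eq_temp_offset,
            eq_temp_radiation_gain = eq_temp_radiation_gain,
            dam_release_temp = dam_release_temp,
            min_water_temp = min_water_temp)
  if (any(!is.finite(unlist(p)))) stop("thermal parameters must be finite")
  if (p$exchange_coeff <= 0 || p$exchange_coeff > 1)
    stop("exchange_coeff must be in (0, 1]")
  if (p$min_water_temp < 0) stop("min_water_temp must be >= 0")
  structure(p, class = "thermal_params")
}

#' Degree-day snow step
#'
#' Partitions precipitation into snow (air temperature below the melt
#' threshold) or rain, melts at the degree-day rate above the threshold,
#' capped by the snow available.
#'
#' @param swe snow water equivalent (mm, >= 0); vectorised.
#' @param precip precipitation (mm/day).
#' @param air_temp daily mean air temperature (degC).
#' @param params a \code{\link{hydro_params}}.
#' @return list with \code{swe} (updated), \code{melt_mm}, \code{rain_mm}.
#' @export
snow_step <- function(swe, precip, air_temp, params) {
  stopifnot(all(swe >= 0), all(precip >= 0))
  snow <- ifelse(air_temp < params$melt_threshold, precip, 0)
  rain <- precip - snow
  potential <- params$degree_day_factor * pmax(0, air_temp - params$melt_threshold)
  melt <- pmin(swe + snow, potential)
  list(swe = swe + snow - melt, melt_mm = melt, rain_mm = rain)
}

#' Three-reservoir production step
#'
#' Vertical water budget of one hydrological response unit for one day,
#' with a fixed flux order: evapotranspiration (temperature-index, capped by
#' soil storage), soil fill with capacity spill to the lake reservoir,
#' soil-to-ground infiltration, then linear drainage of all three
#' reservoirs. The mass balance closes exactly:
#' change in storage = input - ET - runoff.
#'
#' @param state list with \code{soil}, \code{ground}, \code{lake} storages
#'   (mm); vectorised over units.
#' @param input water reaching the surface (rain + melt, mm/day).
#' @param air_temp daily mean air temperature (degC).
#' @param params a \code{\link{hydro_params}}.
#' @return list with \code{state} (updated), \code{runoff_mm}, \code{et_mm}.
#' @export
production_step <- function(state, input, air_temp, params) {
  soil <- state$soil; ground <- state$ground; lake <- state$lake
  stopifnot(all(soil >= 0), all(ground >= 0), all(lake >= 0))
  et <- pmin(params$et_coeff * pmax(0, air_temp), soil)
  soil <- soil - et
  soil <- soil + input
  spill <- pmax(0, soil - params$soil_capacity)
  soil <- soil - spill
  lake <- lake + spill
  infil <- params$infiltration_coeff * soil
  soil <- soil - infil
  ground <- ground + infil
  q_soil <- params$soil_drain_coeff * soil
  q_ground <- params$ground_drain_coeff * ground
  q_lake <- params$lake_drain_coeff * lake
  list(state = list(soil = soil - q_soil, ground = ground - q_ground,
                    lake = lake - q_lake),
       runoff_mm = q_soil + q_ground + q_lake,
       et_mm = et)
}

#' Linear-reservoir channel routing step
#'
#' Each cell's channel reservoir receives the cell's local runoff (converted
#' from mm over the cell area to m3) plus the previous day's outflow of its
#' upstream cells; outflow is \code{routing_coeff} times the resulting
#' storage. The one-day upstream lag makes the update order-independent and
#' conserves volume exactly.
#'
#' @param grid a \code{watershed_grid}.
#' @param local_runoff_mm per-cell runoff depth (mm/day).
#' @param channel_storage per-cell channel storage (m3).
#' @param prev_outflow per-cell channel outflow of the previous day (m3).
#' @param params a \code{\link{hydro_params}}.
#' @param extra_inflow_m3 optional per-cell extra inflow (m3/day), e.g. a
#'   dam release at the controlled headwater.
#' @return list with \code{outflow_m3}, \code{discharge_m3s} (outflow /
#'   86400) and \code{storage} (updated, m3).
#' @export
route_step <- function(grid, local_runoff_mm, channel_storage, prev_outflow,
                       params, extra_inflow_m3 = NULL) {
  ord <- topo_order(grid)   # validates acyclicity / single outlet
  n <- nrow(grid$cells)
  if (is.null(extra_inflow_m3)) extra_inflow_m3 <- numeric(n)
  local_m3 <- local_runoff_mm / 1000 * grid$cells$area_km2 * 1e6
  upstream_m3 <- numeric(n)
  ds <- grid$cells$downstream_id
  for (i in seq_len(n)) {
    d <- ds[i]
    if (!is.na(d)) upstream_m3[d] <- upstream_m3[d] + prev_outflow[i]
  }
  storage <- channel_storage + local_m3 + upstream_m3 + extra_inflow_m3
  outflow <- params$routing_coeff * storage
  list(outflow_m3 = outflow,
       discharge_m3s = outflow / 86400,
       storage = storage - outflow)
}

#' Equilibrium-temperature thermal step
#'
#' Updates water temperature cell by cell in upstream-to-downstream order.
#' The inflow mixture temperature is the discharge-weighted mean of
#' upstream outflow temperatures (current day), local runoff entering at the
#' equilibrium temperature, and — at the dam-controlled headwater — dam
#' release water at \code{dam_release_temp}. The mixed temperature then
#' relaxes toward the equilibrium temperature
#' \code{T_eq = air_temp + eq_temp_offset + eq_temp_radiation_gain * shortwave}
#' at rate \code{exchange_coeff}, and is clipped at \code{min_water_temp}.
#'
#' @param grid a \code{watershed_grid}.
#' @param water_temp per-cell water temperature (degC).
#' @param upstream_outflow_m3 per-cell outflow volumes of the previous day
#'   (m3), used as mixing weights for water arriving from upstream.
#' @param local_runoff_m3 per-cell local runoff volume (m3).
#' @param dam_release_m3 per-cell dam-release volume (m3; nonzero only at
#'   the dam cell).
#' @param air_temp,shortwave per-cell forcing for the day.
#' @param params a \code{\link{thermal_params}}.
#' @return updated per-cell water temperature vector.
#' @export
thermal_step <- function(grid, water_temp, upstream_outflow_m3,
                         local_runoff_m3, dam_release_m3,
                         air_temp, shortwave, params) {
  if (any(upstream_outflow_m3 < 0)) stop("negative discharge")
  ord <- topo_order(grid)
  ds <- grid$cells$downstream_id
  n <- nrow(grid$cells)
  t_eq <- air_temp + params$eq_temp_offset +
    params$eq_temp_radiation_gain * shortwave
  new_temp <- water_temp
  for (i in ord) {
    w_up <- 0; wt_up <- 0
    for (j in which(!is.na(ds) & ds == i)) {
      w_up <- w_up + upstream_outflow_m3[j]
      wt_up <- wt_up + upstream_outflow_m3[j] * new_temp[j]
    }
    w <- w_up + local_runoff_m3[i] + dam_release_m3[i]
    if (w > 0) {
      mix <- (wt_up + local_runoff_m3[i] * t_eq[i] +
                dam_release_m3[i] * params$dam_release_temp) / w
    } else {
      mix <- new_temp[i]
    }
    new_temp[i] <- mix + params$exchange_coeff * (t_eq[i] - mix)
  }
  pmax(new_temp, params$min_water_temp)
}

#' Run the coupled hydrological--thermal simulation
#'
#' Integrates the daily model over the forcing period on the watershed grid:
#' per sub-area degree-day snow and three-reservoir production, per-cell
#' linear channel routing in drainage order, and the equilibrium-temperature
#' thermal module. The first \code{spinup} days are run but excluded from
#' the returned cube. The daily loop is compiled; it matches the exported R
#' step functions exactly.
#'
#' @param grid a \code{watershed_grid}.
#' @param forcing a \code{meteo_forcing} covering the whole run (spin-up
#'   days come off the front of the forcing period).
#' @param hydro a \code{\link{hydro_params}}.
#' @param thermal a \code{\link{thermal_params}}.
#' @param spinup number of leading days discarded from outputs (default 365;
#'   must leave at least one output day).
#' @param dam_release optional dam release series (m3/s), one value per
#'   forcing day, injected at the dam-controlled headwater cell.
#' @param initial_state optional named list overriding initial storages
#'   (\code{swe}, \code{soil}, \code{ground}, \code{lake}, scalars in mm)
#'   and \code{water_temp} (degC).
#' @return An object of class \code{simulation_cube}: list with
#'   \code{dates}, \code{cell_ids}, day-by-cell matrices \code{discharge}
#'   (m3/s) and \code{water_temp} (degC), the parameter sets, and
#'   \code{balance_drift_mm} — the cumulative water-balance error expressed
#'   as mm over the watershed area.
#' @examples
#' g <- make_watershed(6, seed = 1)
#' f <- make_meteorology(g, 2000:2001, seed = 2)
#' cube <- simulate_hydrothermal(g, f, hydro_params(), thermal_params())
#' @export
simulate_hydrothermal <- function(grid, forcing, hydro = hydro_params(),
                                  thermal = thermal_params(), spinup = 365,
                                  dam_release = NULL, initial_state = NULL) {
  stopifnot(inherits(grid, "watershed_grid"), inherits(forcing, "meteo_forcing"))
  if (!inherits(hydro, "hydro_params")) hydro <- do.call(hydro_params, as.list(hydro))
  if (!inherits(thermal, "thermal_params")) thermal <- do.call(thermal_params, as.list(thermal))
  nd <- length(forcing$dates)
  if (spinup < 0 || spinup >= nd)
    stop("forcing period too short for the requested spin-up")
  n <- nrow(grid$cells)
  if (is.null(dam_release)) dam_release <- numeric(nd)
  if (length(dam_release) != nd)
    stop("`dam_release` must have one value per forcing day")
  if (any(dam_release < 0)) stop("dam release must be >= 0")

  ord <- topo_order(grid)
  init <- list(swe = 0, soil = 20, ground = 50, lake = 10, water_temp = 4)
  if (!is.null(initial_state)) init[names(initial_state)] <- initial_state

  sub_cell <- rep(seq_len(n), grid$cells$n_sub)
  sub_frac <- unlist(grid$sub_fractions)

  res <- engine_simulate(
    n_cells = n,
    downstream = ifelse(is.na(grid$cells$downstream_id), 0L,
                        as.integer(grid$cells$downstream_id)),
    topo = as.integer(ord),
    area_km2 = grid$cells$area_km2,
    sub_cell = as.integer(sub_cell), sub_frac = sub_frac,
    tmean = forcing$tmean, precip = forcing$precip,
    shortwave = forcing$shortwave,
    hp = unlist(hydro), tp = unlist(thermal),
    dam_cell = as.integer(grid$dam_cell_id),
    dam_release_m3s = dam_release,
    init = unlist(init))

  keep <- (spinup + 1L):nd
  discharge <- res$discharge[keep, , drop = FALSE]
  water_temp <- res$water_temp[keep, , drop = FALSE]
  cn <- as.character(grid$cells$id)
  dimnames(discharge) <- dimnames(water_temp) <- list(NULL, cn)

  structure(list(
    dates = forcing$dates[keep], cell_ids = grid$cells$id,
    discharge = discharge, water_temp = water_temp,
    hydro = hydro, thermal = thermal, spinup = spinup,
    balance_drift_mm = res$balance_drift_m3 /
      (sum(grid$cells$area_km2) * 1e6) * 1000
  ), class = "simulation_cube")
}

#' @export
print.simulation_cube <- function(x, ...) {
  cat(sprintf("Hydrothermal simulation cube: %d days (%s to %s), %d cells\n",
              length(x$dates), min(x$dates), max(x$dates), length(x$cell_ids)))
  cat(sprintf("  discharge %.3f-%.3f m3/s, water temp %.1f-%.1f degC\n",
              min(x$discharge), max(x$discharge),
              min(x$water_temp), max(x$water_temp)))
  cat(sprintf("  water balance drift: %.2e mm\n", x$balance_drift_mm))
  invisible(x)
}

#' Export a simulation cube as long CSV
#'
#' Long format: date, cell_id, variable (discharge_m3s / water_temp_c),
#' value.
#'
#' @param cube a \code{simulation_cube}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cube_csv <- function(cube, path) {
  stopifnot(inherits(cube, "simulation_cube"))
  nd <- length(cube$dates); nc <- length(cube$cell_ids)
  out <- data.frame(
    date = rep(as.character(cube$dates), 2 * nc),
    cell_id = c(rep(cube$cell_ids, each = nd), rep(cube$cell_ids, each = nd)),
    variable = rep(c("discharge_m3s", "water_temp_c"), each = nd * nc),
    value = c(as.vector(cube$discharge), as.vector(cube$water_temp)))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
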