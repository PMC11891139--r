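# Shared fixtures and independent oracles.

small_grid <- function(n = 12, seed = 7) make_watershed(n, seed = seed)

small_forcing <- function(grid, years = 1999:2001, seed = 2, ...)
  make_meteorology(grid, years, seed = seed, ...)

# Naive reference simulator: a plain day loop composed from the exported R
# step functions, independent of the compiled engine. Same contract as
# simulate_hydrothermal (same initial storages, spin-up handling, dam
# boundary).
naive_simulate <- function(grid, forcing, hydro, thermal, spinup = 0,
                           dam_release = NULL) {
  nd <- length(forcing$dates)
  n <- nrow(grid$cells)
  if (is.null(dam_release)) dam_release <- numeric(nd)
  n_sub <- grid$cells$n_sub
  swe <- soil <- ground <- lake <- lapply(seq_len(n), function(i)
    rep(NA_real_, n_sub[i]))
  for (i in seq_len(n)) {
    swe[[i]][] <- 0; soil[[i]][] <- 20; ground[[i]][] <- 50; lake[[i]][] <- 10
  }
  chan <- numeric(n)
  prev_out <- numeric(n)
  wtemp <- rep(4, n)
  discharge <- water_temp <- matrix(NA_real_, nd, n)
  for (t in seq_len(nd)) {
    runoff_mm <- numeric(n)
    for (i in seq_len(n)) {
      for (u in seq_len(n_sub[i])) {
        sn <- snow_step(swe[[i]][u], forcing$precip[t, i],
                        forcing$tmean[t, i], hydro)
        swe[[i]][u] <- sn$swe
        pr <- production_step(list(soil = soil[[i]][u], ground = ground[[i]][u],
                                   lake = lake[[i]][u]),
                              sn$rain_mm + sn$melt_mm,
                              forcing$tmean[t, i], hydro)
        soil[[i]][u] <- pr$state$soil
        ground[[i]][u] <- pr$state$ground
        lake[[i]][u] <- pr$state$lake
        runoff_mm[i] <- runoff_mm[i] + grid$sub_fractions[[i]][u] * pr$runoff_mm
      }
    }
    dam_m3 <- numeric(n)
    dam_m3[grid$dam_cell_id] <- dam_release[t] * 86400
    rt <- route_step(grid, runoff_mm, chan, prev_out, hydro,
                     extra_inflow_m3 = dam_m3)
    chan <- rt$storage
    local_m3 <- runoff_mm / 1000 * grid$cells$area_km2 * 1e6
    wtemp <- thermal_step(grid, wtemp, prev_out, local_m3, dam_m3,
                          forcing$tmean[t, ], forcing$shortwave[t, ], thermal)
    prev_out <- rt$outflow_m3
    discharge[t, ] <- rt$discharge_m3s
    water_temp[t, ] <- wtemp
  }
  keep <- (spinup + 1):nd
  list(discharge = discharge[keep, , drop = FALSE],
       water_temp = water_temp[keep, , drop = FALSE],
       dates = forcing$dates[keep])
}

# Brute-force lattice oracle for the interval classifier: evaluate the
# pointwise band on a fine temperature lattice spanning [t_a, t_b] and take
# the maximum.
lattice_classify <- function(t_a, t_b, thresholds, step = 0.01) {
  grid_t <- unique(c(seq(t_a, t_b, by = step), t_b))
  max(te_band(grid_t, thresholds$optimal_low, thresholds$optimal_high,
              thresholds$critical_low))
}

# A straight-line river: cell 1 outlet, k -> k-1, one sub-area per cell.
line_grid <- function(n = 3, seed = 5) {
  g <- make_watershed(n, seed = seed)
  g$cells$downstream_id <- c(NA_integer_, seq_len(n - 1))
  g$cells$n_sub <- rep(1L, n)
  g$sub_fractions <- rep(list(1), n)
  g$dam_cell_id <- n
  g
}
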