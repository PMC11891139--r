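#' Generate synthetic daily meteorological forcing
#'
#' Produces daily air temperature (mean/min/max), precipitation and a
#' dimensionless shortwave radiation index for every cell of a watershed,
#' over whole calendar years (real Gregorian calendar, leap days included).
#' Air temperature is a sinusoidal seasonal cycle plus AR(1) weather noise
#' shared across the watershed, an altitude lapse relative to the mean cell
#' altitude, and an additive warming offset. The offset may be a scalar or a
#' named per-year vector (used by scenario ensembles whose warming ramps up
#' over the century).
#'
#' @param grid a \code{watershed_grid}.
#' @param years integer vector of calendar years to cover (consecutive not
#'   required, but forcing is generated per listed year).
#' @param warming_offset additive offset on all air temperatures (degC);
#'   scalar, or a numeric vector named by year.
#' @param seed integer seed.
#' @param mean_temp annual mean air temperature at mean altitude (degC).
#' @param amplitude seasonal half-amplitude (degC).
#' @param peak_doy day of year of the seasonal maximum.
#' @param ar1_phi lag-1 autocorrelation of the weather noise.
#' @param noise_sd marginal standard deviation of the weather noise (degC);
#'   0 gives a purely deterministic cycle.
#' @param diurnal_range mean daily max minus min (degC).
#' @param lapse_rate altitudinal temperature lapse (degC per m).
#' @param precip_prob daily wet-day probability.
#' @param precip_mean mean wet-day precipitation (mm).
#' @return An object of class \code{meteo_forcing}: list with \code{dates}
#'   (Date), \code{cell_ids}, and day-by-cell matrices \code{tmean},
#'   \code{tmin}, \code{tmax}, \code{precip}, \code{shortwave} (0--1).
#' @examples
#' g <- make_watershed(5, seed = 1)
#' f <- make_meteorology(g, 2000, seed = 2)
#' range(f$tmean)
#' @export
make_meteorology <- function(grid, years, warming_offset = 0, seed = 1,
                             mean_temp = 4.5, amplitude = 10, peak_doy = 220,
                             ar1_phi = 0.7, noise_sd = 1.8,
                             diurnal_range = 6, lapse_rate = 0.0065,
                             precip_prob = 0.45, precip_mean = 4) {
  stopifnot(inherits(grid, "watershed_grid"))
  if (length(years) < 1) stop("`years` must be non-empty")
  years <- sort(unique(as.integer(years)))
  if (!all(is.finite(warming_offset))) stop("`warming_offset` must be finite")
  stopifnot(ar1_phi > -1, ar1_phi < 1, noise_sd >= 0)

  dates <- do.call(c, lapply(years, function(y)
    seq(as.Date(sprintf("%d-01-01", y)), as.Date(sprintf("%d-12-31", y)), by = "day")))
  nd <- length(dates)
  nc <- nrow(grid$cells)
  doy <- as.integer(format(dates, "%j"))

  offset_by_day <- if (length(warming_offset) == 1L && is.null(names(warming_offset))) {
    rep(warming_offset, nd)
  } else {
    if (is.null(names(warming_offset)))
      stop("vector `warming_offset` must be named by year")
    yr <- format(dates, "%Y")
    miss <- setdiff(unique(yr), names(warming_offset))
    if (length(miss)) stop("warming_offset missing years: ", paste(miss, collapse = ", "))
    as.numeric(warming_offset[yr])
  }

  rng <- local_rng(seed)
  seasonal <- mean_temp + amplitude * cos(2 * pi * (doy - peak_doy) / 365.25)
  if (noise_sd > 0) {
    innov_sd <- noise_sd * sqrt(1 - ar1_phi^2)
    eps <- rnorm_rng(rng, nd, sd = innov_sd)
    noise <- as.numeric(stats::filter(eps, ar1_phi, method = "recursive"))
  } else {
    noise <- numeric(nd)
  }
  lapse <- -lapse_rate * (grid$cells$altitude_m - mean(grid$cells$altitude_m))

  base <- seasonal + noise + offset_by_day       # day vector
  tmean <- outer(base, rep(1, nc)) + outer(rep(1, nd), lapse)
  half <- diurnal_range / 2
  tmin <- tmean - half
  tmax <- tmean + half

  wet <- runif_rng(rng, nd) < precip_prob
  amount <- rgamma_rng(rng, nd, shape = 1.2, scale = precip_mean / 1.2)
  p_day <- ifelse(wet, amount, 0)
  # seasonal wetness: modestly wetter in autumn/winter
  p_day <- p_day * (1 + 0.3 * cos(2 * pi * (doy - 330) / 365.25))
  precip <- outer(pmax(p_day, 0), rep(1, nc))

  sw_day <- pmin(1, pmax(0, 0.5 + 0.45 * cos(2 * pi * (doy - 172) / 365.25)))
  shortwave <- outer(sw_day, rep(1, nc))

  cn <- as.character(grid$cells$id)
  dimnames(tmean) <- dimnames(tmin) <- dimnames(tmax) <-
    dimnames(precip) <- dimnames(shortwave) <- list(NULL, cn)

  structure(list(
    dates = dates, cell_ids = grid$cells$id,
    tmean = tmean, tmin = tmin, tmax = tmax,
    precip = precip, shortwave = shortwave
  ), class = "meteo_forcing")
}

#' @export
print.meteo_forcing <- function(x, ...) {
  cat(sprintf("Daily meteorological forcing: %d days (%s to %s), %d cells\n",
              length(x$dates), min(x$dates), max(x$dates), length(x$cell_ids)))
  cat(sprintf("  air temp mean %.1f degC (range %.1f to %.1f), precip mean %.1f mm/d\n",
              mean(x$tmean), min(x$tmean), max(x$tmean), mean(x$precip)))
  invisible(x)
}

#' Generate a pseudo-GCM forcing ensemble for an emission scenario
#'
#' Stands in for an ensemble of eight downscaled General Circulation Models
#' under a combined climate/socio-economic scenario (SSP2-4.5 or SSP5-8.5).
#' All members share one weather realisation; they differ by an additive
#' warming offset drawn around the scenario's central warming, which ramps
#' linearly from zero at the end of the historical period (2014) to the
#' central value at the mid-century decade and keeps growing at the same
#' rate to the end of the century. The offsets are synthetic configuration,
#' not CMIP6 values.
#'
#' @param grid a \code{watershed_grid}.
#' @param years calendar years to cover.
#' @param scenario \code{"SSP2-4.5"} or \code{"SSP5-8.5"} (or
#'   \code{"historical"}, giving zero offsets).
#' @param seed integer seed (drives the shared weather realisation).
#' @param n_members ensemble size (default 8).
#' @param central_offset central warming (degC) reached by the 2050s;
#'   defaults: 1.5 for SSP2-4.5, 2.5 for SSP5-8.5, 0 for historical.
#' @param spread between-member standard deviation scale of the 2050s
#'   offsets (degC); 0 makes all members identical.
#' @param ... further arguments passed to \code{\link{make_meteorology}}.
#' @return An object of class \code{pseudo_ensemble}: list with
#'   \code{members} (list of \code{meteo_forcing}), \code{scenario},
#'   \code{member_offsets} (degC at the 2050s), \code{years}.
#' @export
make_pseudo_ensemble <- function(grid, years, scenario, seed = 1,
                                 n_members = 8, central_offset = NULL,
                                 spread = 0.4, ...) {
  known <- c("historical", "SSP2-4.5", "SSP5-8.5")
  if (!is.character(scenario) || length(scenario) != 1 || !scenario %in% known)
    stop("unknown scenario label: must be one of ",
         paste(known, collapse = ", "))
  if (is.null(central_offset))
    central_offset <- switch(scenario,
                             "historical" = 0, "SSP2-4.5" = 1.5, "SSP5-8.5" = 2.5)
  years <- sort(unique(as.integer(years)))

  # symmetric member deviations (deterministic plan, like a design)
  z <- stats::qnorm((seq_len(n_members) - 0.5) / n_members)
  member_offsets <- central_offset + spread * z

  ramp <- pmax(0, (years - 2014) / (2055 - 2014))   # 1 at the 2050s midpoint
  members <- lapply(seq_len(n_members), function(m) {
    off <- member_offsets[m] * ramp
    names(off) <- years
    make_meteorology(grid, years, warming_offset = off, seed = seed, ...)
  })

  structure(list(members = members, scenario = scenario,
                 member_offsets = member_offsets, years = years),
            class = "pseudo_ensemble")
}

#' @export
print.pseudo_ensemble <- function(x, ...) {
  cat(sprintf("Pseudo-GCM ensemble: %d members, scenario %s, years %d-%d\n",
              length(x$members), x$scenario, min(x$years), max(x$years)))
  cat("  2050s member offsets (degC):",
      paste(sprintf("%.2f", x$member_offsets), collapse = " "), "\n")
  invisible(x)
}

#' Write forcing or observations in long CSV format
#'
#' Long format: date, cell_id, variable, value — one row per day, cell and
#' variable.
#'
#' @param forcing a \code{meteo_forcing}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_forcing_csv <- function(forcing, path) {
  stopifnot(inherits(forcing, "meteo_forcing"))
  vars <- c("tmean", "tmin", "tmax", "precip", "shortwave")
  out <- do.call(rbind, lapply(vars, function(v) {
    m <- forcing[[v]]
    data.frame(date = rep(as.character(forcing$dates), ncol(m)),
               cell_id = rep(forcing$cell_ids, each = nrow(m)),
               variable = v, value = as.vector(m))
  }))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
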