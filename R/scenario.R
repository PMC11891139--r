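#' Scenario/period specification
#'
#' @param scenario \code{"historical"}, \code{"SSP2-4.5"} or
#'   \code{"SSP5-8.5"}.
#' @param period \code{"1980s"} (1980--89), \code{"2050s"} (2050--59) or
#'   \code{"2090s"} (2090--99).
#' @return list with scenario, period and \code{years}.
#' @export
scenario_spec <- function(scenario = c("historical", "SSP2-4.5", "SSP5-8.5"),
                          period = c("1980s", "2050s", "2090s")) {
  scenario <- match.arg(scenario)
  period <- match.arg(period)
  years <- switch(period, "1980s" = 1980:1989, "2050s" = 2050:2059,
                  "2090s" = 2090:2099)
  list(scenario = scenario, period = period, years = years)
}

#' Decadal monthly water-temperature statistics
#'
#' For an ensemble of simulation cubes: spatial mean over cells per day,
#' monthly mean per year and member, then mean and sd over the member-by-
#' year monthly means. Restricted to the six warmest months, May--October.
#'
#' @param cubes list of \code{simulation_cube}s (one per ensemble member).
#' @param spec a \code{\link{scenario_spec}}; all of its years must be
#'   covered by every cube.
#' @param months months to report (default 5:10, May--October).
#' @return data frame: month, scenario, period, mean_temp, sd_temp, n.
#' @export
decadal_monthly_stats <- function(cubes, spec, months = 5:10) {
  if (inherits(cubes, "simulation_cube")) cubes <- list(cubes)
  rows <- lapply(seq_along(cubes), function(m) {
    cube <- cubes[[m]]
    yr <- as.integer(format(cube$dates, "%Y"))
    mo <- as.integer(format(cube$dates, "%m"))
    missing_years <- setdiff(spec$years, unique(yr))
    if (length(missing_years))
      stop("cube lacks years: ", paste(missing_years, collapse = ", "))
    keep <- yr %in% spec$years & mo %in% months
    spatial <- rowMeans(cube$water_temp[keep, , drop = FALSE])
    stats::aggregate(
      data.frame(temp = spatial),
      by = list(month = mo[keep], year = yr[keep]),
      FUN = mean)
  })
  all <- do.call(rbind, lapply(seq_along(rows), function(m)
    cbind(rows[[m]], member = m)))
  out <- do.call(rbind, lapply(split(all, all$month), function(g)
    data.frame(month = g$month[1], scenario = spec$scenario,
               period = spec$period,
               mean_temp = mean(g$temp), sd_temp = stats::sd(g$temp),
               n = nrow(g))))
  out <- out[order(out$month), ]
  rownames(out) <- NULL
  out
}

#' Percent change relative to a baseline
#'
#' \code{100 * (projected - baseline) / baseline}, optionally rounded.
#'
#' @param projected,baseline values on a positive scale (e.g. degC);
#'   \code{baseline} must be > 0.
#' @param digits decimal places for rounding (default 0, nearest integer);
#'   \code{NA} for no rounding.
#' @return percent change.
#' @examples
#' percent_change(19.7, 17)   # 16
#' @export
percent_change <- function(projected, baseline, digits = 0) {
  if (any(baseline <= 0)) stop("baseline must be > 0")
  pc <- 100 * (projected - baseline) / baseline
  if (!is.na(digits)) pc <- round(pc, digits)
  pc
}

#' Days exceeding a temperature threshold within a calendar window
#'
#' Counts, per year, the days with temperature strictly above the threshold
#' inside the window (default: the summer temperature management window,
#' 20 July--20 August inclusive, threshold 20 degC).
#'
#' @param dates Date vector.
#' @param temp temperature series aligned with \code{dates}.
#' @param threshold exceedance threshold (degC).
#' @param window c(start, end) month-day strings "MM-DD".
#' @return data frame: year, n_exceed.
#' @export
exceedance_days <- function(dates, temp, threshold = 20,
                            window = c("07-20", "08-20")) {
  stopifnot(length(dates) == length(temp))
  md <- format(dates, "%m-%d")
  inside <- md >= window[1] & md <= window[2]
  yr <- as.integer(format(dates, "%Y"))
  out <- stats::aggregate(
    data.frame(n_exceed = as.integer(inside & !is.na(temp) & temp > threshold)),
    by = list(year = yr), FUN = sum)
  out[order(out$year), ]
}

#' Summer temperature management rule
#'
#' Proportional dam-release rule: inside the window, when the control cell's
#' simulated temperature exceeds the threshold, the release is increased by
#' \code{gain} m3/s per degC of exceedance, capped at \code{max_release}.
#' A minimal exploratory controller, not a reconstruction of operator
#' practice.
#'
#' @param threshold trigger temperature (degC, default 20).
#' @param window c(start, end) "MM-DD" (default 20 July--20 August).
#' @param gain release increment per degC of exceedance (m3/s per degC).
#' @param max_release cap on the added release (m3/s).
#' @return list of class \code{stmp_rule}.
#' @export
stmp_rule <- function(threshold = 20, window = c("07-20", "08-20"),
                      gain = 20, max_release = 150) {
  stopifnot(threshold > 0, length(window) == 2, gain >= 0, max_release >= 0)
  structure(list(threshold = threshold, window = window, gain = gain,
                 max_release = max_release), class = "stmp_rule")
}

#' Run the summer temperature management controller
#'
#' Simulates a baseline, computes the required cold-water dam release from
#' the control cell's exceedance of the rule threshold inside the rule
#' window, and re-simulates with the adjusted release entering at the
#' dam-controlled headwater at \code{dam_release_temp}.
#'
#' @param grid a \code{watershed_grid} (must have a dam-controlled cell).
#' @param forcing a \code{meteo_forcing}.
#' @param hydro,thermal parameter sets.
#' @param rule a \code{\link{stmp_rule}}.
#' @param control_cell cell whose temperature is managed (default: outlet).
#' @param spinup spin-up days.
#' @return list with \code{cube} (adjusted run), \code{baseline} (cube),
#'   \code{releases} (data frame: date, release_m3s) and the rule.
#' @export
stmp_controller <- function(grid, forcing, hydro = hydro_params(),
                            thermal = thermal_params(), rule = stmp_rule(),
                            control_cell = grid$outlet_id, spinup = 365) {
  stopifnot(inherits(rule, "stmp_rule"))
  if (is.null(grid$dam_cell_id)) stop("grid has no dam-controlled cell")
  baseline <- simulate_hydrothermal(grid, forcing, hydro, thermal,
                                    spinup = spinup)
  col <- match(control_cell, baseline$cell_ids)
  if (is.na(col)) stop("unknown control cell")
  md <- format(baseline$dates, "%m-%d")
  inside <- md >= rule$window[1] & md <= rule$window[2]
  exceed <- pmax(0, baseline$water_temp[, col] - rule$threshold)
  release_out <- ifelse(inside, pmin(rule$gain * exceed, rule$max_release), 0)
  # align with the full forcing axis (spin-up days get zero release)
  release_full <- numeric(length(forcing$dates))
  release_full[match(baseline$dates, forcing$dates)] <- release_out
  cube <- simulate_hydrothermal(grid, forcing, hydro, thermal,
                                spinup = spinup, dam_release = release_full)
  list(cube = cube, baseline = baseline,
       releases = data.frame(date = baseline$dates, release_m3s = release_out),
       rule = rule, control_cell = control_cell)
}
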