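#' @export
print.hydrothermal_fit <- function(x, ...) {
  cat("Two-step hydrothermal model fit\n")
  cat("Call: "); print(x$call)
  cat(sprintf("\nStep 1 (hydrology, %s on flow): objective %.5g, %d evaluations\n",
              x$configs$hydro$objective, x$hydro_result$best_objective,
              x$hydro_result$n_evaluations))
  print(round(x$hydro_result$best_params, 5))
  cat(sprintf("\nStep 2 (thermal, %s on water temperature): objective %.5g, %d evaluations\n",
              x$configs$thermal$objective, x$thermal_result$best_objective,
              x$thermal_result$n_evaluations))
  print(round(x$thermal_result$best_params, 5))
  invisible(x)
}

#' Coefficients of a hydrothermal fit
#'
#' @param object a \code{hydrothermal_fit}.
#' @param which \code{"estimated"} (default) for the calibrated parameters
#'   only, \code{"all"} for the complete hydro + thermal parameter vector.
#' @param ... unused.
#' @return named numeric vector; names are prefixed \code{hydro.} or
#'   \code{thermal.}.
#' @export
coef.hydrothermal_fit <- function(object, which = c("estimated", "all"), ...) {
  which <- match.arg(which)
  if (which == "estimated") {
    c(stats::setNames(object$hydro_result$best_params,
                      paste0("hydro.", names(object$hydro_result$best_params))),
      stats::setNames(object$thermal_result$best_params,
                      paste0("thermal.", names(object$thermal_result$best_params))))
  } else {
    c(stats::setNames(unlist(unclass(object$hydro)),
                      paste0("hydro.", names(object$hydro))),
      stats::setNames(unlist(unclass(object$thermal)),
                      paste0("thermal.", names(object$thermal))))
  }
}

#' @export
summary.hydrothermal_fit <- function(object, ...) {
  structure(list(
    call = object$call,
    coef = coef(object),
    objectives = c(hydro = object$hydro_result$best_objective,
                   thermal = object$thermal_result$best_objective),
    evaluations = c(hydro = object$hydro_result$n_evaluations,
                    thermal = object$thermal_result$n_evaluations),
    diagnostics = object$diagnostics,
    balance_drift_mm = object$cube$balance_drift_mm
  ), class = "summary.hydrothermal_fit")
}

#' @export
print.summary.hydrothermal_fit <- function(x, ...) {
  cat("Two-step hydrothermal model fit\n\nEstimated parameters:\n")
  print(round(x$coef, 5))
  cat(sprintf("\nObjectives: flow %.5g (%d evals), water temperature %.5g (%d evals)\n",
              x$objectives["hydro"], x$evaluations["hydro"],
              x$objectives["thermal"], x$evaluations["thermal"]))
  cat("\nPer-station diagnostics:\n")
  print(x$diagnostics, row.names = FALSE)
  cat(sprintf("\nWater-balance drift of the fitted run: %.2e mm\n",
              x$balance_drift_mm))
  invisible(x)
}

#' Predict from a fitted hydrothermal model
#'
#' Runs the forward model at the fitted parameters, on the calibration
#' forcing by default or on new forcing (e.g. a climate-scenario member).
#'
#' @param object a \code{hydrothermal_fit}.
#' @param newdata optional \code{meteo_forcing}; defaults to the
#'   calibration forcing.
#' @param spinup spin-up days (defaults to the fit's).
#' @param dam_release optional dam-release series (m3/s) per forcing day.
#' @param ... unused.
#' @return a \code{simulation_cube}.
#' @export
predict.hydrothermal_fit <- function(object, newdata = NULL, spinup = NULL,
                                     dam_release = NULL, ...) {
  forcing <- if (is.null(newdata)) object$forcing else newdata
  if (is.null(spinup)) spinup <- object$spinup
  simulate_hydrothermal(object$grid, forcing, object$hydro, object$thermal,
                        spinup = spinup, dam_release = dam_release)
}

#' Residuals of a hydrothermal fit at the gauging stations
#'
#' @param object a \code{hydrothermal_fit}.
#' @param variable \code{"water_temp"} (default) or \code{"flow"}.
#' @param ... unused.
#' @return long data frame: date, cell_id, observed, fitted, residual
#'   (observed minus fitted; gap days are dropped).
#' @export
residuals.hydrothermal_fit <- function(object, variable = c("water_temp", "flow"),
                                       ...) {
  variable <- match.arg(variable)
  obs <- if (variable == "flow") object$obs_flow else object$obs_temp
  mat <- if (variable == "flow") object$cube$discharge else object$cube$water_temp
  idx <- match(obs$date, object$cube$dates)
  col <- match(obs$cell_id, object$cube$cell_ids)
  fitted <- mat[cbind(idx, col)]
  out <- data.frame(date = obs$date, cell_id = obs$cell_id,
                    observed = obs$value, fitted = fitted,
                    residual = obs$value - fitted)
  out[!is.na(out$observed), ]
}

#' Simulate synthetic gauge records from a fitted model
#'
#' Parametric simulation: re-runs the fitted forward model and draws new
#' Gaussian measurement noise (and gaps) around it, producing replicate
#' observation sets of the same shape as the calibration data.
#'
#' @param object a \code{hydrothermal_fit}.
#' @param nsim number of replicate observation sets.
#' @param seed integer seed.
#' @param noise_sd named c(flow=, temp=) noise standard deviations; default
#'   taken from the fitted per-station temperature/flow RMSEs.
#' @param gap_fraction fraction of days masked per replicate.
#' @param ... unused.
#' @return list of \code{observation_set}s of length \code{nsim}.
#' @export
simulate.hydrothermal_fit <- function(object, nsim = 1, seed = 1,
                                      noise_sd = NULL, gap_fraction = 0, ...) {
  if (is.null(noise_sd)) {
    d <- object$diagnostics
    noise_sd <- c(flow = mean(d$rmse[d$variable == "flow"]),
                  temp = mean(d$rmse[d$variable == "water_temp"]))
  }
  stations <- unique(object$obs_temp$cell_id)
  lapply(seq_len(nsim), function(k)
    make_observations(object$grid, object$forcing, object$hydro,
                      object$thermal, stations = stations,
                      noise_sd = noise_sd, gap_fraction = gap_fraction,
                      seed = seed + k - 1L, spinup = object$spinup))
}

#' Plot a hydrothermal fit
#'
#' Observed versus fitted series at one station: water temperature (top)
#' and discharge (bottom), plus the best-so-far objective traces of both
#' calibration steps.
#'
#' @param x a \code{hydrothermal_fit}.
#' @param station cell id of the station to plot (default: first
#'   temperature station).
#' @param which \code{"series"}, \code{"trace"} or \code{"both"}.
#' @param ... passed to \code{plot.default}.
#' @return \code{x}, invisibly.
#' @export
plot.hydrothermal_fit <- function(x, station = NULL,
                                  which = c("both", "series", "trace"), ...) {
  which <- match.arg(which)
  if (is.null(station)) station <- x$obs_temp$cell_id[1]
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  nrow_panels <- if (which == "both") 3L else if (which == "series") 2L else 1L
  graphics::par(mfrow = c(nrow_panels, 1), mar = c(3, 4, 2, 1))
  col <- match(station, x$cube$cell_ids)
  if (which %in% c("both", "series")) {
    ot <- x$obs_temp[x$obs_temp$cell_id == station, ]
    plot(x$cube$dates, x$cube$water_temp[, col], type = "l",
         xlab = "", ylab = "water temp (degC)",
         main = sprintf("station cell %s", station), ...)
    graphics::points(ot$date, ot$value, pch = 16, cex = 0.3, col = "red3")
    of <- x$obs_flow[x$obs_flow$cell_id == station, ]
    plot(x$cube$dates, x$cube$discharge[, col], type = "l",
         xlab = "", ylab = "discharge (m3/s)", ...)
    if (nrow(of)) graphics::points(of$date, of$value, pch = 16, cex = 0.3,
                                   col = "red3")
  }
  if (which %in% c("both", "trace")) {
    tr1 <- x$hydro_result$trace; tr2 <- x$thermal_result$trace
    plot(seq_along(tr1), tr1, type = "l", log = "y", xlab = "generation",
         ylab = "best objective", main = "calibration traces",
         xlim = c(1, max(length(tr1), length(tr2))),
         ylim = range(c(tr1, tr2)[c(tr1, tr2) > 0]))
    graphics::lines(seq_along(tr2), tr2, col = "red3")
    graphics::legend("topright", c("hydrology", "thermal"), lty = 1,
                     col = c("black", "red3"), bty = "n")
  }
  invisible(x)
}
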