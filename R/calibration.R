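#' Root mean square error over non-missing pairs
#'
#' Gap-aware RMSE: pairs where the observation (or simulation) is missing
#' are dropped; the error is computed over the remaining pairs only.
#'
#' @param simulated,observed numeric vectors on a shared time index (equal
#'   length).
#' @return the RMSE, or \code{NA_real_} if no pair overlaps.
#' @examples
#' rmse(c(1, 2), c(2, 4))          # sqrt(2.5)
#' rmse(c(1, 9, 2), c(2, NA, 4))   # gaps ignored
#' @export
rmse <- function(simulated, observed) {
  if (length(simulated) != length(observed))
    stop("series must share a time index (equal length)")
  ok <- !is.na(simulated) & !is.na(observed)
  if (!any(ok)) return(NA_real_)
  sqrt(mean((simulated[ok] - observed[ok])^2))
}

#' Nash--Sutcliffe efficiency over non-missing pairs
#'
#' \code{1 - SSE/SST} with both sums over non-missing pairs; 1 is a perfect
#' fit, 0 matches the observed mean, negative is worse than the mean.
#'
#' @param simulated,observed numeric vectors on a shared time index.
#' @return the NSE (dimensionless).
#' @export
nse <- function(simulated, observed) {
  if (length(simulated) != length(observed))
    stop("series must share a time index (equal length)")
  ok <- !is.na(simulated) & !is.na(observed)
  if (sum(ok) < 2) stop("need >= 2 overlapping non-missing pairs")
  o <- observed[ok]; s <- simulated[ok]
  sst <- sum((o - mean(o))^2)
  if (sst == 0) stop("observed variance is zero; NSE undefined")
  1 - sum((s - o)^2) / sst
}

#' Calibration configuration
#'
#' @param bounds named list; each element \code{c(lower, upper)} for one
#'   parameter to estimate. Parameters without bounds stay fixed.
#' @param population_size CMA-ES population (default \code{4 + floor(3 log d)}).
#' @param max_evaluations objective evaluation budget (default 3000).
#' @param tol stop when the best objective improves by less than \code{tol}
#'   over 20 consecutive generations (default 1e-10).
#' @param seed integer seed for the search.
#' @param objective \code{"RMSE"} (minimised) or \code{"NSE"} (maximised,
#'   internally minimised as \code{-NSE}).
#' @return list of class \code{calibration_config}.
#' @export
calibration_config <- function(bounds, population_size = NULL,
                               max_evaluations = 3000, tol = 1e-10,
                               seed = 1, objective = c("RMSE", "NSE")) {
  objective <- match.arg(objective)
  stopifnot(is.list(bounds), length(bounds) >= 1, !is.null(names(bounds)))
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2 || !(b[1] < b[2]) && !(b[1] == b[2]))
      stop("bound for ", nm, " must be c(lower, upper) with lower <= upper")
    if (b[1] > b[2]) stop("lower > upper for ", nm)
  }
  d <- length(bounds)
  if (is.null(population_size)) population_size <- 4L + floor(3 * log(d))
  if (max_evaluations < population_size)
    stop("max_evaluations must be >= population_size")
  structure(list(bounds = bounds, population_size = as.integer(population_size),
                 max_evaluations = as.integer(max_evaluations), tol = tol,
                 seed = as.integer(seed), objective = objective),
            class = "calibration_config")
}

#' Minimise a bounded objective with CMA-ES
#'
#' Standard (mu/mu_w, lambda) covariance matrix adaptation evolution
#' strategy with rank-one and rank-mu covariance updates and cumulative
#' step-size adaptation. Candidates are clipped to the box before
#' evaluation, keeping the objective scale interpretable. Deterministic
#' given the seed.
#'
#' @param objective_fn function mapping a named parameter vector to a finite
#'   scalar to minimise.
#' @param config a \code{\link{calibration_config}} (its \code{bounds} give
#'   the search box and parameter names).
#' @return An object of class \code{calibration_result}: list with
#'   \code{best_params} (named, within bounds), \code{best_objective},
#'   \code{n_evaluations}, \code{trace} (best-so-far per generation,
#'   non-increasing) and \code{seed}.
#' @examples
#' sphere <- function(x) sum(x^2)
#' cfg <- calibration_config(list(a = c(-5, 5), b = c(-5, 5)),
#'                           max_evaluations = 600, seed = 3)
#' r <- cma_es_minimize(sphere, cfg)
#' r$best_objective < 1e-6
#' @export
cma_es_minimize <- function(objective_fn, config) {
  stopifnot(inherits(config, "calibration_config"))
  nm <- names(config$bounds)
  lower <- vapply(config$bounds, `[`, 0, 1)
  upper <- vapply(config$bounds, `[`, 0, 2)
  d <- length(nm)
  rng <- local_rng(config$seed)

  if (all(upper == lower)) {   # degenerate box: nothing to search
    x <- stats::setNames(lower, nm)
    f <- objective_fn(x)
    return(structure(list(best_params = x, best_objective = f,
                          n_evaluations = 1L, trace = f, seed = config$seed),
                     class = "calibration_result"))
  }

  scale <- upper - lower
  scale[scale == 0] <- 1
  # search in the unit box [0,1]^d
  lambda <- config$population_size
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / d) / (d + 4 + 2 * mueff / d)
  cs <- (mueff + 2) / (d + mueff + 5)
  c1 <- 2 / ((d + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((d + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (d + 1)) - 1) + cs
  chiN <- sqrt(d) * (1 - 1 / (4 * d) + 1 / (21 * d^2))

  m <- rep(0.5, d)
  sigma <- 0.3
  pc <- ps <- numeric(d)
  C <- diag(d)
  eig <- eigen(C, symmetric = TRUE)

  best_f <- Inf
  best_x <- m
  trace <- numeric(0)
  n_eval <- 0L
  stall <- 0L
  prev_best <- Inf

  while (n_eval + lambda <= config$max_evaluations) {
    B <- eig$vectors
    D <- sqrt(pmax(eig$values, 1e-20))
    Z <- matrix(rnorm_rng(rng, d * lambda), d, lambda)
    Y <- B %*% (D * Z)                  # N(0, C) samples
    X <- m + sigma * Y
    Xc <- pmin(pmax(X, 0), 1)           # clip to box for evaluation
    f <- numeric(lambda)
    for (k in seq_len(lambda)) {
      xk <- stats::setNames(lower + scale * Xc[, k], nm)
      f[k] <- objective_fn(xk)
      n_eval <- n_eval + 1L
    }
    if (all(!is.finite(f))) stop("objective non-finite on all samples")
    f[!is.finite(f)] <- max(f[is.finite(f)]) + 1e6
    ordix <- order(f)
    if (f[ordix[1]] < best_f) {
      best_f <- f[ordix[1]]
      best_x <- Xc[, ordix[1]]
    }
    trace <- c(trace, best_f)

    sel <- ordix[seq_len(mu)]
    # recombination uses the clipped coordinates so the mean stays feasible
    y_w <- (pmin(pmax(X[, sel, drop = FALSE], 0), 1) - m) %*% w / sigma
    m <- m + sigma * as.numeric(y_w)

    Cinv_sqrt_y <- B %*% ((1 / D) * crossprod(B, as.numeric(y_w)))
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * as.numeric(Cinv_sqrt_y)
    hsig <- as.numeric(sqrt(sum(ps^2)) /
      sqrt(1 - (1 - cs)^(2 * n_eval / lambda)) / chiN < 1.4 + 2 / (d + 1))
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * as.numeric(y_w)

    arty <- (pmin(pmax(X[, sel, drop = FALSE], 0), 1) - (m - sigma * as.numeric(y_w))) / sigma
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * arty %*% (w * t(arty))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    sigma <- min(sigma, 1)              # cap relative to unit box
    C <- (C + t(C)) / 2
    eig <- eigen(C, symmetric = TRUE)

    if (prev_best - best_f < config$tol) stall <- stall + 1L else stall <- 0L
    prev_best <- best_f
    if (stall >= 20L) break
  }

  structure(list(
    best_params = stats::setNames(lower + scale * best_x, nm),
    best_objective = best_f,
    n_evaluations = n_eval,
    trace = trace,
    seed = config$seed
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("CMA-ES result: objective %.6g after %d evaluations\n",
              x$best_objective, x$n_evaluations))
  print(round(x$best_params, 5))
  invisible(x)
}

#' Serialise a calibration result to JSON
#' @param result a \code{calibration_result}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_calibration_json <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  jsonlite::write_json(list(
    best_params = as.list(result$best_params),
    best_objective = result$best_objective,
    n_evaluations = result$n_evaluations,
    trace = result$trace, seed = result$seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
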