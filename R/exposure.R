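#' Life-stage thermal tolerance thresholds
#'
#' Default tolerance table for white sturgeon early life stages: the optimal
#' range (T_optR, peak physiological performance), whose upper edge starts
#' the sub-optimal range (ST_optR, loss of some critical function, < 25%
#' mortality), and an optional lower bound of the critical range (CT_LR,
#' > 50% mortality). The defaults carry no critical bound — laboratory data
#' did not support one for any stage — so the highest category reachable
#' under defaults is 2. The feeding-larvae stage has two expert-opinion
#' variants of the optimal range (upper edge 18 vs 20 degC).
#'
#' A copy of the default table ships as
#' \code{system.file("extdata", "thermal_thresholds.csv", package = "riverTe")}
#' for editing.
#'
#' @param life_stage optional subset of stages to return.
#' @return data frame of class \code{thermal_thresholds} with columns
#'   \code{life_stage}, \code{optimal_low}, \code{optimal_high},
#'   \code{critical_low} (degC, \code{NA} = no critical bound).
#' @examples
#' thermal_thresholds()
#' thermal_thresholds("embryo")
#' @export
thermal_thresholds <- function(life_stage = NULL) {
  tab <- data.frame(
    life_stage = c("embryo", "yolk_sac_larvae", "feeding_larvae18",
                   "feeding_larvae20", "juvenile"),
    optimal_low = c(14, 14, 14, 14, 14),
    optimal_high = c(18, 20, 18, 20, 18),
    critical_low = NA_real_)
  if (!is.null(life_stage)) {
    if (!all(life_stage %in% tab$life_stage))
      stop("unknown life stage: ",
           paste(setdiff(life_stage, tab$life_stage), collapse = ", "))
    tab <- tab[match(life_stage, tab$life_stage), ]
  }
  validate_thresholds(tab)
}

validate_thresholds <- function(tab) {
  stopifnot(is.data.frame(tab),
            all(c("life_stage", "optimal_low", "optimal_high",
                  "critical_low") %in% names(tab)))
  if (any(tab$optimal_low >= tab$optimal_high))
    stop("optimal_low must be < optimal_high for every stage")
  bad <- !is.na(tab$critical_low) & tab$critical_low <= tab$optimal_high
  if (any(bad)) stop("critical_low must exceed optimal_high")
  rownames(tab) <- NULL
  class(tab) <- c("thermal_thresholds", "data.frame")
  tab
}

#' Read a threshold table from CSV
#' @param path CSV with columns life_stage, optimal_low, optimal_high,
#'   critical_low (empty = none).
#' @return a validated \code{thermal_thresholds} data frame.
#' @export
read_thresholds_csv <- function(path) {
  tab <- utils::read.csv(path)
  if (!"critical_low" %in% names(tab)) tab$critical_low <- NA_real_
  tab$critical_low <- suppressWarnings(as.numeric(tab$critical_low))
  validate_thresholds(tab)
}

#' Pointwise thermal risk band of a temperature
#'
#' Band 0 below the optimal range; 1 inside it (both ends inclusive);
#' 2 above it (the sub-optimal range is open at its lower edge); 3 at or
#' above the critical bound when one is supplied. Non-decreasing in
#' temperature.
#'
#' @param t temperature (degC), vectorised.
#' @param optimal_low,optimal_high,critical_low band edges (degC;
#'   \code{critical_low} may be \code{NA}).
#' @return integer band in 0..3.
#' @export
te_band <- function(t, optimal_low, optimal_high, critical_low = NA_real_) {
  b <- ifelse(t < optimal_low, 0L, ifelse(t <= optimal_high, 1L, 2L))
  if (!is.na(critical_low)) b <- ifelse(t >= critical_low, 3L, b)
  as.integer(b)
}

#' Classify a daily temperature interval into a thermal exposure category
#'
#' Maps the day's [minimum, maximum] water-temperature interval to the
#' ordinal thermal exposure risk T_e in \{0, 1, 2, 3\}: 0 wholly below the
#' optimal range, 1 inside it, 2 in the sub-optimal range, 3 in the critical
#' range. Intervals wholly inside one band reproduce this rule exactly; for
#' intervals straddling a band edge two declared conventions are available:
#' \code{"conservative"} (default) takes the highest band touched by the
#' interval — since the band function is non-decreasing in temperature this
#' is the band of the daily maximum — and \code{"mean"} classifies the
#' interval midpoint.
#'
#' @param t_a,t_b daily minimum and maximum water temperature (degC),
#'   vectorised; requires \code{t_a <= t_b}.
#' @param thresholds one row of a \code{\link{thermal_thresholds}} table
#'   (or a list with optimal_low/optimal_high/critical_low).
#' @param mode \code{"conservative"} or \code{"mean"}.
#' @return integer vector of categories in 0..3.
#' @examples
#' emb <- thermal_thresholds("embryo")
#' classify_interval(15, 17, emb)   # 1: inside the optimal range
#' classify_interval(10, 12, emb)   # 0: below it
#' @export
classify_interval <- function(t_a, t_b, thresholds,
                              mode = c("conservative", "mean")) {
  mode <- match.arg(mode)
  if (is.data.frame(thresholds)) {
    if (nrow(thresholds) != 1)
      stop("`thresholds` must be a single life stage's row")
    thresholds <- as.list(thresholds)
  }
  if (any(t_a > t_b)) stop("t_a must be <= t_b")
  lo <- thresholds$optimal_low; hi <- thresholds$optimal_high
  cl <- thresholds$critical_low
  if (is.null(cl)) cl <- NA_real_
  if (mode == "conservative") {
    pmax(te_band(t_a, lo, hi, cl), te_band(t_b, lo, hi, cl))
  } else {
    te_band((t_a + t_b) / 2, lo, hi, cl)
  }
}

#' Life-stage presence windows
#'
#' Calendar window in which each early life stage is present in the river:
#' embryo 15 May--24 June, yolk-sac larvae 24 May--7 July, feeding larvae
#' (both threshold variants) 20 June--31 July, juvenile 1 May--31 October.
#' Windows are month-day rules resolved per calendar year, both ends
#' inclusive.
#'
#' @param life_stage one of the stages in \code{\link{thermal_thresholds}}.
#' @param year calendar year.
#' @return Date vector of the days in the window.
#' @examples
#' length(stage_window("embryo", 2055))  # 41 days
#' @export
stage_window <- function(life_stage, year) {
  w <- stage_window_table()
  row <- w[w$life_stage == life_stage, ]
  if (!nrow(row)) stop("unknown life stage: ", life_stage)
  seq(as.Date(sprintf("%d-%s", year, row$start_md)),
      as.Date(sprintf("%d-%s", year, row$end_md)), by = "day")
}

#' Table of life-stage window rules (month-day)
#' @return data frame: life_stage, start_md, end_md ("MM-DD").
#' @export
stage_window_table <- function() {
  data.frame(
    life_stage = c("embryo", "yolk_sac_larvae", "feeding_larvae18",
                   "feeding_larvae20", "juvenile"),
    start_md = c("05-15", "05-24", "06-20", "06-20", "05-01"),
    end_md = c("06-24", "07-07", "07-31", "07-31", "10-31"))
}

#' Daily thermal exposure categories over a simulation cube
#'
#' Classifies every cell and every day inside the life stage's presence
#' window(s); days outside the window are absent from the result, not zero.
#' The thermal engine produces one daily temperature; by default the daily
#' interval collapses to it (\code{t_a = t_b}), and a diurnal half-range
#' widens it symmetrically when supplied.
#'
#' @param cube a \code{simulation_cube}.
#' @param thresholds single-row \code{\link{thermal_thresholds}}.
#' @param life_stage stage whose window to use (defaults to the thresholds
#'   row's stage).
#' @param mode classification mode, see \code{\link{classify_interval}}.
#' @param diurnal_half_range half-width added/subtracted around the daily
#'   temperature (degC, default 0).
#' @return long data frame: date, cell_id, te (integer 0..3).
#' @export
daily_te <- function(cube, thresholds, life_stage = NULL,
                     mode = c("conservative", "mean"),
                     diurnal_half_range = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(cube, "simulation_cube"))
  if (is.data.frame(thresholds) && nrow(thresholds) != 1)
    stop("`thresholds` must be a single life stage's row")
  if (is.null(life_stage)) life_stage <- thresholds$life_stage
  years <- unique(as.integer(format(cube$dates, "%Y")))
  window <- do.call(c, lapply(years, function(y) stage_window(life_stage, y)))
  window <- window[window >= min(cube$dates) & window <= max(cube$dates)]
  idx <- match(window, cube$dates)
  if (anyNA(idx))
    stop("cube does not cover all window days inside its period")
  nc <- length(cube$cell_ids)
  temp <- cube$water_temp[idx, , drop = FALSE]
  te <- classify_interval(as.vector(temp) - diurnal_half_range,
                          as.vector(temp) + diurnal_half_range,
                          thresholds, mode = mode)
  data.frame(date = rep(window, nc),
             cell_id = rep(cube$cell_ids, each = length(window)),
             te = te)
}

#' Aggregate daily exposure categories to ensemble/decadal means
#'
#' Numeric aggregation of categories (0/1/2/3 taken at face value), in a
#' fixed order: mean per cell x month x year x member, then mean over
#' ensemble members, then mean over the period's years. The reported sd is
#' taken across the member-by-year monthly means, the granularity of the
#' ensemble error bars.
#'
#' @param te_list list of daily-category data frames
#'   (\code{\link{daily_te}} output), one per ensemble member.
#' @param life_stage,period,scenario labels carried into the output.
#' @return data frame of class \code{exposure_summary}: scope (cell id),
#'   life_stage, month, period, scenario, mean_te, sd_te, n.
#' @export
aggregate_te <- function(te_list, life_stage = NA_character_,
                         period = NA_character_, scenario = NA_character_) {
  if (is.data.frame(te_list)) te_list <- list(te_list)
  per_member <- lapply(seq_along(te_list), function(m) {
    d <- te_list[[m]]
    if (!nrow(d)) return(NULL)
    key <- data.frame(cell_id = d$cell_id,
                      month = as.integer(format(d$date, "%m")),
                      year = as.integer(format(d$date, "%Y")))
    agg <- stats::aggregate(d$te, by = key, FUN = mean)
    names(agg)[4] <- "te_mean"
    agg$member <- m
    agg
  })
  mm <- do.call(rbind, per_member)
  if (is.null(mm) || !nrow(mm))
    return(empty_exposure_summary())
  # mean over members (per cell, month, year), then over years; sd across
  # member x year means
  out <- do.call(rbind, lapply(split(mm, list(mm$cell_id, mm$month), drop = TRUE),
    function(g) {
      member_year <- g$te_mean     # one value per member x year
      by_year <- stats::aggregate(te_mean ~ year, g, mean)  # over members
      data.frame(scope = as.character(g$cell_id[1]), life_stage = life_stage,
                 month = g$month[1], period = period, scenario = scenario,
                 mean_te = mean(by_year$te_mean),
                 sd_te = if (length(member_year) > 1) stats::sd(member_year) else 0,
                 n = length(member_year))
    }))
  out <- out[order(out$scope, out$month), ]
  rownames(out) <- NULL
  class(out) <- c("exposure_summary", "data.frame")
  out
}

empty_exposure_summary <- function() {
  out <- data.frame(scope = character(), life_stage = character(),
                    month = integer(), period = character(),
                    scenario = character(), mean_te = numeric(),
                    sd_te = numeric(), n = integer())
  class(out) <- c("exposure_summary", "data.frame")
  out
}

#' Synthetic critical-habitat polygon masks
#'
#' Builds named rectangular lat/lon polygons over portions of the watershed,
#' standing in for designated critical-habitat reaches (default names:
#' Vanderhoof Reach, Fraser Lake, Keilor's Point, Powerline). Each mask is
#' guaranteed to contain at least one cell centroid.
#'
#' @param grid a \code{watershed_grid}.
#' @param names habitat names (one mask each; at most the number of cells).
#' @param seed integer seed choosing anchor cells.
#' @return list of class \code{habitat_masks}; each element has \code{name}
#'   and \code{polygon} (matrix of lon/lat vertices, closed ring).
#' @export
make_habitat_masks <- function(grid,
                               names = c("Vanderhoof Reach", "Fraser Lake",
                                         "Keilor's Point", "Powerline"),
                               seed = 1) {
  stopifnot(inherits(grid, "watershed_grid"))
  n <- nrow(grid$cells)
  if (length(names) > n) stop("more masks than cells")
  rng <- local_rng(seed)
  anchors <- with_rng(rng, sample.int(n, length(names)))
  h <- grid$cell_size_deg * (0.6 + 1.2 * runif_rng(rng, length(names)))
  masks <- lapply(seq_along(names), function(k) {
    cx <- grid$cells$lon[anchors[k]]; cy <- grid$cells$lat[anchors[k]]
    ring <- cbind(lon = c(cx - h[k], cx + h[k], cx + h[k], cx - h[k], cx - h[k]),
                  lat = c(cy - h[k], cy - h[k], cy + h[k], cy + h[k], cy - h[k]))
    list(name = names[k], polygon = ring)
  })
  structure(masks, class = "habitat_masks")
}

#' Cells whose centroid falls inside a habitat mask
#' @param grid a \code{watershed_grid}.
#' @param mask one element of a \code{\link{make_habitat_masks}} list.
#' @return integer cell ids.
#' @export
mask_cells <- function(grid, mask) {
  inside <- mgcv::in.out(mask$polygon,
                         cbind(grid$cells$lon, grid$cells$lat))
  ids <- grid$cells$id[inside]
  if (!length(ids)) stop("mask '", mask$name, "' intersects no grid cell")
  ids
}

#' Average exposure within critical habitats
#'
#' Area-unweighted mean of cell-level exposure summaries over the cells
#' whose centroid falls inside each habitat polygon.
#'
#' @param cell_summary an \code{exposure_summary} with cell-id scopes.
#' @param masks a \code{habitat_masks} list.
#' @param grid the \code{watershed_grid} the summary was computed on.
#' @return an \code{exposure_summary} whose scope is the habitat name.
#' @export
habitat_te <- function(cell_summary, masks, grid) {
  stopifnot(inherits(cell_summary, "exposure_summary"),
            inherits(masks, "habitat_masks"))
  rows <- lapply(masks, function(mask) {
    ids <- as.character(mask_cells(grid, mask))
    sub <- cell_summary[cell_summary$scope %in% ids, ]
    if (!nrow(sub)) return(NULL)
    do.call(rbind, lapply(split(sub, sub$month), function(g)
      data.frame(scope = mask$name, life_stage = g$life_stage[1],
                 month = g$month[1], period = g$period[1],
                 scenario = g$scenario[1],
                 mean_te = mean(g$mean_te), sd_te = mean(g$sd_te),
                 n = sum(g$n))))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_exposure_summary())
  rownames(out) <- NULL
  class(out) <- c("exposure_summary", "data.frame")
  out
}

#' Write habitat masks as GeoJSON polygons
#' @param masks a \code{habitat_masks} list.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_masks_geojson <- function(masks, path) {
  feats <- lapply(masks, function(m) list(
    type = "Feature",
    geometry = list(type = "Polygon",
                    coordinates = list(lapply(seq_len(nrow(m$polygon)),
                      function(i) as.numeric(m$polygon[i, c("lon", "lat")])))),
    properties = list(name = m$name)))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
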