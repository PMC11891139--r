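#' Generate a synthetic gridded watershed with a drainage tree
#'
#' Builds a random semi-distributed watershed on a regular lat/lon grid:
#' every cell (a whole grid square, "CE") drains to exactly one downstream
#' cell, links form a tree with a single outlet, and each cell is subdivided
#' into 1--4 sub-areas ("CP") acting as parallel hydrological response units
#' whose area fractions sum to one.
#'
#' Cell centroids are laid out by growing the drainage network upstream from
#' the outlet on the grid lattice, so neighbouring cells in the tree are also
#' spatial neighbours. Altitude increases with tree depth (distance from the
#' outlet), emulating a headwater-to-valley gradient. One headwater cell (the
#' deepest in the tree) is flagged as dam-controlled; it provides the
#' boundary where reservoir releases enter the river.
#'
#' @param n_cells number of grid cells (>= 1).
#' @param branching_factor mean number of upstream tributaries per cell;
#'   controls how dendritic the network is (default 1.5).
#' @param cell_size_deg cell edge length in degrees (default 0.005).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param origin lat/lon of the outlet centroid (degrees).
#' @return An object of class \code{watershed_grid}: a list with
#'   \code{cells} (data frame: id, lat, lon, area_km2, altitude_m,
#'   downstream_id, channel_length_km, n_sub), \code{sub_fractions} (list of
#'   per-cell area-fraction vectors), \code{cell_size_deg}, \code{outlet_id}
#'   and \code{dam_cell_id}.
#' @examples
#' g <- make_watershed(20, seed = 7)
#' sum(!is.na(g$cells$downstream_id))  # 19 directed links
#' @export
make_watershed <- function(n_cells, branching_factor = 1.5,
                           cell_size_deg = 0.005, seed = 1,
                           origin = c(lat = 54.0, lon = -124.3)) {
  if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells < 1)
    stop("`n_cells` must be a single number >= 1")
  n_cells <- as.integer(n_cells)
  stopifnot(cell_size_deg > 0, branching_factor > 0)

  rng <- local_rng(seed)

  # grow the tree upstream from the outlet on the lattice
  ij <- matrix(0L, n_cells, 2)           # lattice coordinates
  downstream <- rep(NA_integer_, n_cells)
  depth <- integer(n_cells)
  occupied <- new.env(hash = TRUE)
  assign("0,0", 1L, envir = occupied)
  frontier <- 1L
  steps <- rbind(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (n_cells > 1) {
    for (i in 2:n_cells) {
      # prefer attaching to cells with few upstream links (limits branching)
      repeat {
        w <- branching_factor / (1 + tabulate(downstream, n_cells)[frontier])
        parent <- frontier[sample_int(rng, length(frontier), prob = w)]
        free <- list()
        for (s in seq_len(4)) {
          cand <- ij[parent, ] + steps[s, ]
          key <- paste0(cand[1], ",", cand[2])
          if (!exists(key, envir = occupied, inherits = FALSE))
            free[[length(free) + 1L]] <- cand
        }
        if (length(free)) break
        frontier <- setdiff(frontier, parent)  # boxed-in cell
      }
      pos <- free[[sample_int(rng, length(free))]]
      ij[i, ] <- pos
      assign(paste0(pos[1], ",", pos[2]), i, envir = occupied)
      downstream[i] <- parent
      depth[i] <- depth[parent] + 1L
      frontier <- c(frontier, i)
    }
  }

  lat <- origin[["lat"]] + ij[, 1] * cell_size_deg
  lon <- origin[["lon"]] + ij[, 2] * cell_size_deg
  # geographic cell area (km^2); ~111.2 km per degree latitude
  area_km2 <- (cell_size_deg * 111.2) * (cell_size_deg * 111.2 * cos(lat * pi / 180))
  altitude_m <- 650 + 15 * depth + 5 * runif_rng(rng, n_cells)
  channel_length_km <- cell_size_deg * 111.2 * (1 + 0.3 * runif_rng(rng, n_cells))

  n_sub <- 1L + floor(4 * runif_rng(rng, n_cells))
  n_sub[n_sub > 4L] <- 4L
  sub_fractions <- lapply(seq_len(n_cells), function(i) {
    k <- n_sub[i]
    if (k == 1L) return(1)
    u <- runif_rng(rng, k) + 0.2     # keep fractions away from 0
    u / sum(u)
  })

  dam_cell_id <- if (n_cells == 1) 1L else which.max(depth)

  structure(list(
    cells = data.frame(
      id = seq_len(n_cells), lat = lat, lon = lon,
      area_km2 = area_km2, altitude_m = altitude_m,
      downstream_id = downstream,
      channel_length_km = channel_length_km,
      n_sub = n_sub
    ),
    sub_fractions = sub_fractions,
    cell_size_deg = cell_size_deg,
    outlet_id = 1L,
    dam_cell_id = dam_cell_id
  ), class = "watershed_grid")
}

#' Topological order of a watershed drainage tree
#'
#' Returns cell ids ordered so that every cell appears before its downstream
#' neighbour (headwaters first, outlet last). Errors if the links contain a
#' cycle or more than one outlet.
#'
#' @param grid a \code{watershed_grid}.
#' @return integer vector of cell ids in upstream-to-downstream order.
#' @export
topo_order <- function(grid) {
  stopifnot(inherits(grid, "watershed_grid"))
  ds <- grid$cells$downstream_id
  n <- nrow(grid$cells)
  if (sum(is.na(ds)) != 1L) stop("drainage network must have exactly one outlet")
  indeg <- tabulate(ds[!is.na(ds)], n)
  order <- integer(0)
  queue <- which(indeg == 0L)
  indeg_work <- indeg
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    d <- ds[v]
    if (!is.na(d)) {
      indeg_work[d] <- indeg_work[d] - 1L
      if (indeg_work[d] == 0L) queue <- c(queue, d)
    }
  }
  if (length(order) != n) stop("cycle detected in drainage links")
  order
}

#' @export
print.watershed_grid <- function(x, ...) {
  cat("Synthetic watershed grid\n")
  cat(sprintf("  cells: %d (%.3f deg squares), outlet cell %d, dam cell %d\n",
              nrow(x$cells), x$cell_size_deg, x$outlet_id, x$dam_cell_id))
  cat(sprintf("  total area: %.3f km2, altitude %.0f-%.0f m\n",
              sum(x$cells$area_km2), min(x$cells$altitude_m),
              max(x$cells$altitude_m)))
  invisible(x)
}

#' Export a watershed grid as GeoJSON
#'
#' Writes one Feature per cell (square polygon around the centroid) with
#' properties id, downstream_id, area_km2, altitude_m and sub_area_fractions.
#'
#' @param grid a \code{watershed_grid}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_watershed_geojson <- function(grid, path) {
  stopifnot(inherits(grid, "watershed_grid"))
  h <- grid$cell_size_deg / 2
  feats <- lapply(seq_len(nrow(grid$cells)), function(i) {
    c0 <- grid$cells[i, ]
    ring <- list(
      c(c0$lon - h, c0$lat - h), c(c0$lon + h, c0$lat - h),
      c(c0$lon + h, c0$lat + h), c(c0$lon - h, c0$lat + h),
      c(c0$lon - h, c0$lat - h))
    props <- list(id = c0$id, area_km2 = c0$area_km2,
                  altitude_m = c0$altitude_m,
                  sub_area_fractions = grid$sub_fractions[[i]])
    if (!is.na(c0$downstream_id)) props$downstream_id <- c0$downstream_id
    list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(ring)),
      properties = props
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# --- private RNG: generators never touch the global .Random.seed ----------

local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

runif_rng <- function(rng, n, ...) with_rng(rng, stats::runif(n, ...))
rnorm_rng <- function(rng, n, ...) with_rng(rng, stats::rnorm(n, ...))
rgamma_rng <- function(rng, n, ...) with_rng(rng, stats::rgamma(n, ...))
sample_int <- function(rng, n, size = 1, prob = NULL)
  with_rng(rng, sample.int(n, size, prob = prob))
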