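#' Baseline climate at survey locations
#'
#' Multi-year mean of the baseline-period layers at the survey's grid cell:
#' the baseline annual mean temperature `T` (degrees C) or annual
#' precipitation `P` (mm) covariates.
#'
#' @param grid a [climate_grid] containing the baseline years.
#' @param x,y projected survey coordinates.
#' @param baseline_years years to average (default: all layers in the grid).
#' @return Numeric vector of baseline means.
#' @export
extract_baseline <- function(grid, x, y, baseline_years = grid$years) {
  flat <- grid_mean(grid, baseline_years)
  idx <- cell_index(grid, x, y)
  out <- flat[idx]
  if (anyNA(out)) stop("nodata cell at ", sum(is.na(out)), " point(s)")
  out
}

#' Climate change at survey locations
#'
#' Change covariates `TC`/`PC`: the value at the survey's cell in the survey
#' year minus the baseline multi-year mean at the same cell.
#'
#' @param grid a [climate_grid] covering both the baseline and the survey
#'   years.
#' @param x,y projected survey coordinates.
#' @param year survey year(s).
#' @param baseline_years years forming the baseline mean.
#' @return Numeric vector of changes.
#' @export
extract_change <- function(grid, x, y, year, baseline_years) {
  grid_extract(grid, x, y, year) -
    extract_baseline(grid, x, y, baseline_years)
}

#' Within-cell temperature heterogeneity (THET)
#'
#' Dispersion of fine-resolution temperatures inside the survey's coarse
#' (1 km) cell — short-distance microclimatic refugia potential. The default
#' statistic is the sample standard deviation; `"range"` is available as an
#' alternative.
#'
#' @param fine a [climate_grid] at finer resolution, nested in the coarse
#'   grid (its cell_size must divide `coarse_cell`).
#' @param x,y survey coordinates.
#' @param coarse_cell coarse cell edge, metres (default 1000).
#' @param stat `"sd"` (default) or `"range"`.
#' @param year optional year; default uses the mean layer.
#' @return Numeric vector of heterogeneity values.
#' @export
temperature_heterogeneity <- function(fine, x, y, coarse_cell = 1000,
                                      stat = c("sd", "range"), year = NULL) {
  stat <- match.arg(stat)
  ratio <- coarse_cell / fine$cell_size
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1)
    stop("fine grid is not nested in the coarse cells")
  flat <- if (is.null(year)) grid_mean(fine) else
    fine$values[, , match(year, fine$years)]
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  vapply(seq_len(n), function(i) {
    c0 <- floor((x[i] - fine$origin[1]) / coarse_cell) * ratio
    r0 <- floor((y[i] - fine$origin[2]) / coarse_cell) * ratio
    rows <- r0 + seq_len(ratio); cols <- c0 + seq_len(ratio)
    if (any(rows < 1 | rows > nrow(flat) | cols < 1 | cols > ncol(flat)))
      stop("survey outside the fine grid extent")
    v <- flat[rows, cols]
    if (length(v) < 2) stop("fewer than 2 fine cells in the unit")
    if (stat == "sd") stats::sd(v) else diff(range(v))
  }, 0)
}

#' Potential habitat of a species
#'
#' A cell is potential habitat iff it is forest and its period-mean
#' temperature lies within the species' thermal tolerance limits.
#'
#' @param limits length-2 numeric, lower and upper thermal limits (degrees C).
#' @param temp_mean matrix of period-mean temperatures (e.g. [grid_mean()]).
#' @param forest_mask logical matrix, same dimensions.
#' @return Logical habitat matrix.
#' @export
potential_habitat <- function(limits, temp_mean, forest_mask) {
  stopifnot(length(limits) == 2L, all(is.finite(limits)),
            limits[1] <= limits[2],
            all(dim(temp_mean) == dim(forest_mask)))
  if (!any(forest_mask)) stop("empty forest mask")
  forest_mask & temp_mean >= limits[1] & temp_mean <= limits[2]
}

#' Past habitat proximity (HP)
#'
#' Inverse distance from an occurrence to the nearest cell centre of the
#' species' past potential habitat: `HP = 1 / (d + cell_size)`, an increasing
#' gradient of proximity. The offset of one cell size keeps the index finite
#' and strictly monotone when the point sits inside the habitat (d = 0).
#'
#' @param x,y occurrence coordinates (projected, metres).
#' @param habitat logical habitat matrix (rows = y, cols = x).
#' @param cell_size cell edge, metres.
#' @param origin grid lower-left corner.
#' @return HP values (1/m). Errors when the species has no past habitat.
#' @export
habitat_proximity <- function(x, y, habitat, cell_size = 1000,
                              origin = c(0, 0)) {
  cells <- which(habitat, arr.ind = TRUE)
  if (!nrow(cells)) stop("species has empty past habitat: HP undefined")
  cx <- origin[1] + (cells[, 2] - 0.5) * cell_size
  cy <- origin[2] + (cells[, 1] - 0.5) * cell_size
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  vapply(seq_len(n), function(i) {
    col <- floor((x[i] - origin[1]) / cell_size) + 1L
    row <- floor((y[i] - origin[2]) / cell_size) + 1L
    inside <- row >= 1 && row <= nrow(habitat) && col >= 1 &&
      col <= ncol(habitat) && habitat[row, col]
    d <- if (inside) 0 else sqrt(min((cx - x[i])^2 + (cy - y[i])^2))
    1 / (d + cell_size)
  }, 0)
}

#' Aggregation index of a binary habitat pattern
#'
#' `AI = e / e_max`, where `e` counts shared edges between habitat cells
#' (rook adjacency) and `e_max` is the largest possible edge count for that
#' many cells (achieved by the largest-square packing). 1 = maximally
#' clumped, 0 = fully dispersed; a single cell is 0 by convention
#' (no aggregation measurable).
#'
#' @param habitat logical/0-1 matrix.
#' @return AI in [0, 1]. Errors when the pattern has no habitat cell.
#' @export
aggregation_index <- function(habitat) {
  habitat <- habitat > 0
  n <- sum(habitat)
  if (n == 0) stop("zero habitat cells: AI undefined")
  e <- sum(habitat[-nrow(habitat), ] & habitat[-1, ]) +
    sum(habitat[, -ncol(habitat)] & habitat[, -1])
  k <- floor(sqrt(n)); m <- n - k^2
  e_max <- if (m == 0) 2 * k * (k - 1)
           else if (m <= k) 2 * k * (k - 1) + 2 * m - 1
           else 2 * k * (k - 1) + 2 * m - 2
  if (e_max == 0) return(0)
  e / e_max
}

#' Temporal change in habitat aggregation (dHA)
#'
#' Aggregation of the current minus the past habitat pattern inside a window
#' (typically the cells within 10 km of a survey). Negative values mean the
#' species' habitat disaggregated.
#'
#' @param past,current logical habitat matrices over the same window.
#' @return `AI(current) - AI(past)`.
#' @export
habitat_aggregation_change <- function(past, current) {
  aggregation_index(current) - aggregation_index(past)
}

#' Clip a habitat grid to a radius around a point
#'
#' Keeps cells whose centres lie within `radius` of `(x, y)`; everything else
#' becomes non-habitat. Used to evaluate [aggregation_index()] locally.
#'
#' @param habitat logical matrix.
#' @param x,y centre point (projected).
#' @param radius metres (default 10 km).
#' @param cell_size,origin grid geometry.
#' @return Logical matrix of the same dimensions.
#' @export
clip_radius <- function(habitat, x, y, radius = 10000, cell_size = 1000,
                        origin = c(0, 0)) {
  d <- dim(habitat)
  cx <- origin[1] + (rep(seq_len(d[2]), each = d[1]) - 0.5) * cell_size
  cy <- origin[2] + (rep(seq_len(d[1]), times = d[2]) - 0.5) * cell_size
  inside <- matrix((cx - x)^2 + (cy - y)^2 <= radius^2, d[1], d[2])
  habitat & inside
}

# Euclidean distance from point p to segment (a, b).
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  t <- ifelse(len2 > 0, pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2)), 0)
  sqrt((ax + t * vx - px)^2 + (ay + t * vy - py)^2)
}

#' Distance to a line network
#'
#' Minimum Euclidean distance from each survey to a set of polylines (e.g. a
#' road network), the `road_prox` covariate's raw distance.
#'
#' @param x,y survey coordinates.
#' @param network a list of polylines, each a 2-column matrix of vertices, or
#'   a single such matrix.
#' @return Numeric vector of minimum distances (metres).
#' @export
distance_to_network <- function(x, y, network) {
  if (is.matrix(network)) network <- list(network)
  if (!length(network)) stop("empty network")
  segs <- do.call(rbind, lapply(network, function(m) {
    if (nrow(m) < 2) stop("polyline with fewer than 2 vertices")
    cbind(m[-nrow(m), 1], m[-nrow(m), 2], m[-1, 1], m[-1, 2])
  }))
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  vapply(seq_len(n), function(i)
    min(point_segment_distance(x[i], y[i],
                               segs[, 1], segs[, 2], segs[, 3], segs[, 4])),
    0)
}

#' Population sum within a radius (HPD)
#'
#' Sum of the density-raster cells whose centres fall within `radius` of each
#' survey.
#'
#' @param density matrix of population counts per cell.
#' @param x,y survey coordinates.
#' @param radius metres (default 10 km).
#' @param cell_size,origin grid geometry.
#' @return Numeric vector of sums. Errors when no cell centre is covered.
#' @export
population_within_radius <- function(density, x, y, radius = 10000,
                                     cell_size = 1000, origin = c(0, 0)) {
  d <- dim(density)
  cx <- origin[1] + (rep(seq_len(d[2]), each = d[1]) - 0.5) * cell_size
  cy <- origin[2] + (rep(seq_len(d[1]), times = d[2]) - 0.5) * cell_size
  dens <- as.vector(density)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  vapply(seq_len(n), function(i) {
    inside <- (cx - x[i])^2 + (cy - y[i])^2 <= radius^2
    if (!any(inside)) stop("no raster cell centre within the disc")
    sum(dens[inside])
  }, 0)
}
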