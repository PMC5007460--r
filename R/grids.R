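#' Gridded climate layers
#'
#' A `climate_grid` holds yearly values of one climate variable (annual mean
#' temperature in degrees C, or annual precipitation in mm) on a regular grid
#' of square cells in a projected coordinate system. Values are stored as a
#' three-dimensional array `[row, col, year]`; rows index y (northing), columns
#' index x (easting). Cell (1, 1) has its lower-left corner at `origin`.
#'
#' @param values numeric array `ny x nx x n_years` (a matrix is promoted to a
#'   single-year array).
#' @param years integer vector of calendar years, one per layer.
#' @param cell_size cell edge length in metres.
#' @param origin numeric length-2, projected x/y of the grid's lower-left corner.
#' @param varname variable name, e.g. `"temperature"` or `"precipitation"`.
#'
#' @return An object of class `climate_grid`.
#' @export
climate_grid <- function(values, years, cell_size = 1000, origin = c(0, 0),
                         varname = "temperature") {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3L, dim(values)[3] == length(years),
            cell_size > 0, length(origin) == 2L)
  if (dim(values)[1] < 2 || dim(values)[2] < 2)
    stop("grid dimensions must be at least 2 x 2")
  structure(
    list(values = values, years = as.integer(years), cell_size = cell_size,
         origin = as.numeric(origin), varname = varname),
    class = "climate_grid"
  )
}

#' @export
print.climate_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("climate_grid: %s, %d x %d cells of %g m, years %d-%d\n",
              x$varname, d[1], d[2], x$cell_size,
              min(x$years), max(x$years)))
  invisible(x)
}

#' @export
dim.climate_grid <- function(x) dim(x$values)

# Row/col of the cell containing projected point(s); errors outside the extent.
cell_index <- function(grid, x, y) {
  col <- floor((x - grid$origin[1]) / grid$cell_size) + 1L
  row <- floor((y - grid$origin[2]) / grid$cell_size) + 1L
  d <- dim(grid$values)
  bad <- col < 1L | col > d[2] | row < 1L | row > d[1]
  if (any(bad))
    stop(sum(bad), " point(s) outside the grid extent")
  cbind(row = row, col = col)
}

#' Extract grid values at points
#'
#' Reads the layer(s) of the given year(s) at the cells containing the points.
#'
#' @param grid a [climate_grid].
#' @param x,y projected coordinates (recycled to a common length).
#' @param year calendar year(s); `NULL` means the mean across all layers.
#' @return Numeric vector of cell values (or multi-year cell means).
#' @export
grid_extract <- function(grid, x, y, year = NULL) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  idx <- cell_index(grid, x, y)
  if (is.null(year)) {
    flat <- apply(grid$values, c(1, 2), mean)
    out <- flat[idx]
  } else {
    year <- rep_len(as.integer(year), n)
    layer <- match(year, grid$years)
    if (anyNA(layer))
      stop("year(s) not present in grid: ",
           paste(unique(year[is.na(layer)]), collapse = ", "))
    out <- grid$values[cbind(idx, layer)]
  }
  if (anyNA(out)) stop("nodata cell encountered at ", sum(is.na(out)), " point(s)")
  out
}

# Mean layer over a set of years (all by default), as a matrix.
grid_mean <- function(grid, years = grid$years) {
  sel <- match(years, grid$years)
  if (anyNA(sel)) stop("requested years missing from grid")
  apply(grid$values[, , sel, drop = FALSE], c(1, 2), mean)
}

# Projected coordinates of all cell centres, as a 2-column matrix (x, y),
# in row-major order matching as.vector of a layer matrix (column-major: rows
# vary fastest). Returned order matches `as.vector(layer)`.
cell_centres <- function(grid) {
  d <- dim(grid$values)
  rows <- rep(seq_len(d[1]), times = d[2])
  cols <- rep(seq_len(d[2]), each = d[1])
  cbind(x = grid$origin[1] + (cols - 0.5) * grid$cell_size,
        y = grid$origin[2] + (rows - 0.5) * grid$cell_size)
}

#' Write / read a climate grid as plain-text CSV
#'
#' One row per cell-year (`row`, `col`, `year`, `value`) with grid metadata in
#' `# key: value` header comments, so grids round-trip through version control
#' friendly text files.
#'
#' @param grid a [climate_grid].
#' @param path file path.
#' @return `write_grid_csv` returns `path` invisibly; `read_grid_csv` returns a
#'   [climate_grid].
#' @export
write_grid_csv <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- dim(grid$values)
  writeLines(c(
    sprintf("# varname: %s", grid$varname),
    sprintf("# cell_size: %.10g", grid$cell_size),
    sprintf("# origin: %.10g %.10g", grid$origin[1], grid$origin[2]),
    sprintf("# dim: %d %d", d[1], d[2])
  ), con)
  df <- data.frame(
    row = rep(seq_len(d[1]), times = d[2] * d[3]),
    col = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    year = rep(grid$years, each = d[1] * d[2]),
    value = as.vector(grid$values)
  )
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  meta <- function(key) sub(sprintf("^# %s: ", key), "",
                            grep(sprintf("^# %s:", key), hdr, value = TRUE))
  df <- utils::read.csv(path, comment.char = "#")
  d <- as.integer(strsplit(meta("dim"), " ")[[1]])
  years <- sort(unique(df$year))
  vals <- array(NA_real_, c(d[1], d[2], length(years)))
  vals[cbind(df$row, df$col, match(df$year, years))] <- df$value
  climate_grid(vals, years,
               cell_size = as.numeric(meta("cell_size")),
               origin = as.numeric(strsplit(meta("origin"), " ")[[1]]),
               varname = meta("varname"))
}
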