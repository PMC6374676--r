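#' Regular single-band raster grid
#'
#' Minimal container for the gridded fields used throughout the package:
#' terrain elevation, temperature climatologies and daily temperature layers.
#' Cells are square, the grid is row-major with row 1 at the southern edge,
#' and all coordinates refer to cell centers.
#'
#' @param values numeric matrix (`nrow` = northing index, `ncol` = easting
#'   index); all values must be finite.
#' @param res cell size in meters (side of the square cell).
#' @param xmin,ymin coordinates (m) of the lower-left corner of the grid.
#'
#' @return An object of class `grid_raster`: a list with elements `values`,
#'   `res`, `xmin`, `ymin`.
#' @export
grid_raster <- function(values, res, xmin = 0, ymin = 0) {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("grid values must be finite numbers")
  if (!is.numeric(res) || length(res) != 1L || res <= 0)
    stop("'res' must be a single positive number")
  structure(list(values = values, res = res, xmin = xmin, ymin = ymin),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("<grid_raster> %d x %d cells, res %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$res, x$xmin, x$ymin))
  cat(sprintf("  values: [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

# cell-center coordinates, vectorised over the whole grid (column-major,
# matching as.vector(values))
grid_centers <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  list(easting  = g$xmin + (rep(seq_len(nc), each = nr) - 0.5) * g$res,
       northing = g$ymin + (rep(seq_len(nr), times = nc) - 0.5) * g$res)
}

#' @export
as.data.frame.grid_raster <- function(x, ...) {
  ctr <- grid_centers(x)
  data.frame(easting = ctr$easting, northing = ctr$northing,
             value = as.vector(x$values))
}

# index of the cell containing point (x, y); NA outside the grid
grid_cell_index <- function(g, x, y) {
  col <- floor((x - g$xmin) / g$res) + 1L
  row <- floor((y - g$ymin) / g$res) + 1L
  bad <- col < 1L | col > ncol(g$values) | row < 1L | row > nrow(g$values)
  idx <- row + (col - 1L) * nrow(g$values)
  idx[bad] <- NA_integer_
  idx
}

# value of the cell containing each point (nearest-cell lookup)
grid_lookup <- function(g, x, y) {
  idx <- grid_cell_index(g, x, y)
  if (anyNA(idx)) stop("point outside grid extent")
  as.vector(g$values)[idx]
}

# block-aggregate a grid by an integer factor (mean of fine cells);
# trailing rows/cols that do not fill a block are dropped
grid_aggregate <- function(g, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  nr <- (nrow(g$values) %/% factor) * factor
  nc <- (ncol(g$values) %/% factor) * factor
  v <- g$values[seq_len(nr), seq_len(nc), drop = FALSE]
  rowg <- (seq_len(nr) - 1L) %/% factor
  colg <- (seq_len(nc) - 1L) %/% factor
  agg <- tapply(as.vector(v),
                list(rep(rowg, times = nc), rep(colg, each = nr)),
                mean)
  grid_raster(matrix(agg, nrow = nr %/% factor), res = g$res * factor,
              xmin = g$xmin, ymin = g$ymin)
}

#' Generate a synthetic mountain landscape
#'
#' Builds a reproducible elevation grid used as the terrain for simulated
#' point-count surveys. Three terrain models are available: a constant
#' elevation, an inclined plane (elevation linear in easting/northing), and a
#' "ridge" model (a plane spanning the requested elevational range plus
#' seeded smooth sinusoidal relief).
#'
#' @param nx,ny number of cells in easting / northing direction.
#' @param res cell size (m).
#' @param model one of `"ridge"`, `"planar"`, `"constant"`.
#' @param elev_range numeric length-2, target range of elevations (m asl) the
#'   terrain should span (ignored by `"constant"`).
#' @param base constant elevation for `model = "constant"`.
#' @param relief amplitude (m) of the sinusoidal relief added by the ridge
#'   model.
#' @param seed integer seed; identical seeds give identical grids.
#'
#' @return A [grid_raster] of elevations (m asl). For the planar model the
#'   plane coefficients are attached as attribute `"plane"`
#'   (`c(intercept, d_easting, d_northing)`, units m and m/m).
#' @export
generate_landscape <- function(nx = 60, ny = 60, res = 500,
                               model = c("ridge", "planar", "constant"),
                               elev_range = c(600, 2700), base = 1500,
                               relief = 150, seed = 1) {
  model <- match.arg(model)
  if (nx < 1 || ny < 1) stop("grid extent must be positive")
  if (res <= 0) stop("'res' must be positive")
  if (model != "constant" && elev_range[1] >= elev_range[2])
    stop("'elev_range' must be increasing")
  xs <- (rep(seq_len(nx), each = ny) - 0.5) * res
  ys <- (rep(seq_len(ny), times = nx) - 0.5) * res
  width <- nx * res; height <- ny * res
  if (model == "constant") {
    v <- matrix(base, ny, nx)
    return(grid_raster(v, res))
  }
  lo <- elev_range[1]; hi <- elev_range[2]
  # plane rising along the diagonal
  dx <- (hi - lo) / (width + height)
  dy <- dx
  plane <- lo + dx * xs + dy * ys
  if (model == "planar") {
    g <- grid_raster(matrix(plane, ny, nx), res)
    attr(g, "plane") <- c(intercept = lo, d_easting = dx, d_northing = dy)
    return(g)
  }
  # ridge: plane + seeded low-frequency relief, clamped to the target range
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ph <- runif(4, 0, 2 * pi)
  amp <- relief * runif(4, 0.5, 1)
  z <- plane +
    amp[1] * sin(2 * pi * xs / width  + ph[1]) +
    amp[2] * sin(4 * pi * xs / width  + ph[2]) +
    amp[3] * sin(2 * pi * ys / height + ph[3]) +
    amp[4] * sin(4 * pi * ys / height + ph[4])
  z <- pmin(pmax(z, lo), hi)
  grid_raster(matrix(z, ny, nx), res)
}
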