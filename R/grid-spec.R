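#' Regular geographic grid geometry
#'
#' A `grid_spec` describes a regular latitude/longitude raster by its
#' north-west corner, pixel size and pixel counts. Pixel `(r, c)` (1-based,
#' row 1 at the north edge) covers the half-open box
#' `[west + (c-1)*dx, west + c*dx)` in longitude and
#' `(north - r*dy, north - (r-1)*dy]` in latitude, so boxes tile the domain
#' without overlap and every point falls in at most one pixel. Pixel centers
#' sit at `west + (c - 0.5)*dx`, `north - (r - 0.5)*dy`.
#'
#' @param west western edge of the domain (degrees longitude)
#' @param north northern edge of the domain (degrees latitude)
#' @param dx,dy pixel size in degrees; both must be positive. `dy` defaults
#'   to `dx` (square pixels).
#' @param nrows,ncols positive integer pixel counts
#' @return an object of class `grid_spec`
#' @examples
#' coarse <- grid_spec(west = -90.5, north = 39, dx = 0.125, nrows = 8, ncols = 8)
#' fine <- refine_grid(coarse, 12)
#' @export
grid_spec <- function(west, north, dx, dy = dx, nrows, ncols) {
  stopifnot(is.numeric(west), is.numeric(north), length(west) == 1L,
            length(north) == 1L, is.finite(west), is.finite(north))
  if (!is.numeric(dx) || !is.numeric(dy) || dx <= 0 || dy <= 0)
    stop("pixel sizes dx and dy must be positive", call. = FALSE)
  nrows <- as.integer(nrows); ncols <- as.integer(ncols)
  if (is.na(nrows) || is.na(ncols) || nrows < 1L || ncols < 1L)
    stop("nrows and ncols must be positive integers", call. = FALSE)
  structure(list(west = as.numeric(west), north = as.numeric(north),
                 dx = as.numeric(dx), dy = as.numeric(dy),
                 nrows = nrows, ncols = ncols),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels, %.6g x %.6g deg\n",
              x$nrows, x$ncols, x$dx, x$dy))
  cat(sprintf("  west %.6f  east %.6f  south %.6f  north %.6f\n",
              x$west, x$west + x$ncols * x$dx,
              x$north - x$nrows * x$dy, x$north))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d @ (%.6g, %.6g)", x$nrows, x$ncols, x$dx, x$dy)
}

same_grid <- function(a, b, tol = 1e-9) {
  a$nrows == b$nrows && a$ncols == b$ncols &&
    abs(a$west - b$west) < tol && abs(a$north - b$north) < tol &&
    abs(a$dx - b$dx) < tol && abs(a$dy - b$dy) < tol
}

#' Pixel center coordinates
#'
#' @param spec a [grid_spec()]
#' @return `x_centers` gives the `ncols` longitudes of pixel-column centers;
#'   `y_centers` the `nrows` latitudes of pixel-row centers (north to south).
#' @export
x_centers <- function(spec) spec$west + (seq_len(spec$ncols) - 0.5) * spec$dx

#' @rdname x_centers
#' @export
y_centers <- function(spec) spec$north - (seq_len(spec$nrows) - 0.5) * spec$dy

#' Subdivide a grid into an exactly nested finer grid
#'
#' @param spec a [grid_spec()]
#' @param factor integer subdivision factor per axis (e.g. 12 turns a 1/8
#'   degree grid into a ~1 km grid)
#' @return a `grid_spec` with the same extent and `factor^2` times the pixels
#' @export
refine_grid <- function(spec, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  grid_spec(spec$west, spec$north, spec$dx / factor, spec$dy / factor,
            spec$nrows * factor, spec$ncols * factor)
}

#' Locate points on a grid
#'
#' Maps coordinates to the 1-based row/column of the pixel whose half-open
#' box contains them (west and north edges of each box included, east and
#' south excluded). Points outside the domain get `NA` indices.
#'
#' @param spec a [grid_spec()]
#' @param x,y numeric vectors of longitudes and latitudes (recycled to a
#'   common length)
#' @return a list with integer vectors `row` and `col` (`NA` outside the
#'   domain) and logical `inside`
#' @export
locate_points <- function(spec, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  col <- floor((x - spec$west) / spec$dx) + 1
  row <- floor((spec$north - y) / spec$dy) + 1
  inside <- is.finite(row) & is.finite(col) &
    row >= 1 & row <= spec$nrows & col >= 1 & col <= spec$ncols
  row[!inside] <- NA_integer_; col[!inside] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col), inside = inside)
}
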