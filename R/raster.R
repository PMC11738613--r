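#' Gridded population raster
#'
#' A minimal single-band raster container for per-cell population counts,
#' mirroring the ESRI ASCII grid model: a regular grid anchored at its
#' lower-left corner with square cells of edge `cellsize` metres. Row 1 of
#' `values` is the northernmost row (the on-disk convention).
#'
#' @param values numeric matrix of per-cell population (persons, >= 0);
#'   `NA` marks missing cells.
#' @param xll,yll coordinates of the lower-left corner of the grid (m).
#' @param cellsize cell edge length (m).
#' @return an object of class `pop_raster`.
#' @export
pop_raster <- function(values, xll = 0, yll = 0, cellsize = 100) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("values must be a numeric matrix")
  }
  if (cellsize <= 0) stopf("cellsize must be > 0")
  if (any(values < 0, na.rm = TRUE)) stopf("negative population in raster")
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize),
    class = "pop_raster"
  )
}

#' @export
print.pop_raster <- function(x, ...) {
  cat(sprintf(
    "<pop_raster> %d x %d cells of %g m, origin (%g, %g), total %.1f persons\n",
    nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll,
    sum(x$values, na.rm = TRUE)
  ))
  invisible(x)
}

#' Cell-center coordinates and populations of a raster
#'
#' Returns one row per cell with the geometric center of the cell and its
#' population. Missing cells are reported with population `NA`.
#'
#' @param raster a [pop_raster()].
#' @return data.frame with columns `x`, `y`, `population`, `row`, `col`.
#' @export
raster_cell_centers <- function(raster) {
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  col <- rep(seq_len(nc), each = nr)
  row <- rep(seq_len(nr), times = nc)
  data.frame(
    x = raster$xll + (col - 0.5) * raster$cellsize,
    y = raster$yll + (nr - row + 0.5) * raster$cellsize,
    population = as.vector(v),
    row = row, col = col
  )
}

#' Total raster population
#' @param raster a [pop_raster()].
#' @param na.rm drop missing cells (default TRUE).
#' @return total persons.
#' @export
raster_total <- function(raster, na.rm = TRUE) {
  sum(raster$values, na.rm = na.rm)
}
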