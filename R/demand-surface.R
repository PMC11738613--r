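#' Correct a population raster to census totals
#'
#' Per administrative unit, a linear correction factor
#' `census_pop / sum(raster cells in unit)` is computed and every raster
#' cell in the unit is multiplied by it, so that post-correction unit sums
#' equal the census exactly. Raster cells are assigned to units by their
#' center point, so each cell is counted exactly once.
#'
#' Units with a zero raster sum but positive census population get the
#' census spread uniformly over their cells (with a warning); cells whose
#' center falls in no unit are left unchanged, counted, and warned about.
#'
#' @param raster a [pop_raster()].
#' @param units an [admin_units()] table.
#' @return the corrected [pop_raster()], with attribute
#'   `"correction_factors"`: data.frame `unit_id`, `raster_sum`,
#'   `census_pop`, `factor`.
#' @export
correct_raster <- function(raster, units) {
  cc <- raster_cell_centers(raster)
  pop <- cc$population
  pop[is.na(pop)] <- 0
  assign <- rep(NA_integer_, nrow(cc))
  for (u in seq_len(nrow(units))) {
    todo <- is.na(assign)
    if (!any(todo)) break
    hit <- point_in_polygon(cc$x[todo], cc$y[todo], units$geometry[[u]])
    assign[which(todo)[hit]] <- u
  }
  n_orphan <- sum(is.na(assign))
  if (n_orphan > 0) {
    warnf("%d raster cell(s) fall in no admin unit; left unchanged", n_orphan)
  }
  out <- pop
  factors <- data.frame(
    unit_id = units$unit_id,
    raster_sum = NA_real_, census_pop = units$census_pop, factor = NA_real_,
    stringsAsFactors = FALSE
  )
  for (u in seq_len(nrow(units))) {
    idx <- which(assign == u)
    s <- sum(pop[idx])
    factors$raster_sum[u] <- s
    if (s > 0) {
      f <- units$census_pop[u] / s
      factors$factor[u] <- f
      out[idx] <- pop[idx] * f
    } else if (units$census_pop[u] > 0) {
      if (length(idx) == 0) {
        warnf("unit %s has census %g but no raster cells; population lost",
              units$unit_id[u], units$census_pop[u])
      } else {
        warnf("unit %s has zero raster population; census %g spread uniformly over %d cells",
              units$unit_id[u], units$census_pop[u], length(idx))
        out[idx] <- units$census_pop[u] / length(idx)
      }
    } else {
      factors$factor[u] <- 1
    }
  }
  v <- raster$values
  # cc rows are in as.vector(values) order
  v[] <- out
  res <- pop_raster(v, xll = raster$xll, yll = raster$yll,
                    cellsize = raster$cellsize)
  attr(res, "correction_factors") <- factors
  res
}

#' Build a square fishnet over an extent
#'
#' Axis-aligned square cells of edge `cell_edge` tiling the extent from its
#' lower-left corner. Partial cells at the upper/right boundary are kept;
#' the centroid is always the geometric center of the nominal full square.
#'
#' @param extent numeric `c(xmin, ymin, xmax, ymax)` in metres.
#' @param cell_edge cell edge in metres (default 2000).
#' @return data.frame `cell_id`, `xmin`, `ymin`, `xmax`, `ymax`, `cx`, `cy`.
#' @export
build_fishnet <- function(extent, cell_edge = 2000) {
  extent <- as_extent(extent)
  if (cell_edge <= 0) stopf("cell_edge must be > 0")
  nx <- ceiling((extent["xmax"] - extent["xmin"]) / cell_edge)
  ny <- ceiling((extent["ymax"] - extent["ymin"]) / cell_edge)
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  xmin <- extent["xmin"] + ix * cell_edge
  ymin <- extent["ymin"] + iy * cell_edge
  data.frame(
    cell_id = seq_len(nx * ny),
    xmin = xmin, ymin = ymin,
    xmax = xmin + cell_edge, ymax = ymin + cell_edge,
    cx = xmin + cell_edge / 2, cy = ymin + cell_edge / 2,
    row.names = NULL
  )
}

#' Population-weighted demand points from a fishnet
#'
#' Each fishnet cell's population is the sum of corrected raster cells whose
#' centers fall inside it (a partition, so total population is conserved);
#' the cell centroid stands in for the population center of mass and carries
#' that population as demand. Zero-population cells are retained by default
#' (they contribute nothing to catchment sums) and can be dropped.
#'
#' @param cells a [build_fishnet()] result.
#' @param raster the corrected [pop_raster()].
#' @param drop_empty drop cells with zero population (default FALSE).
#' @return data.frame `point_id`, `x`, `y`, `population`.
#' @export
make_demand_points <- function(cells, raster, drop_empty = FALSE) {
  cc <- raster_cell_centers(raster)
  pop <- cc$population
  pop[is.na(pop)] <- 0
  edge <- cells$xmax[1] - cells$xmin[1]
  x0 <- min(cells$xmin); y0 <- min(cells$ymin)
  nx <- length(unique(cells$xmin))
  ix <- floor((cc$x - x0) / edge)
  iy <- floor((cc$y - y0) / edge)
  cell_of <- ix + nx * iy + 1L
  inside <- ix >= 0 & iy >= 0 & cell_of >= 1 & cell_of <= nrow(cells) &
    ix < nx
  sums <- rep(0, nrow(cells))
  agg <- tapply(pop[inside], cell_of[inside], sum)
  sums[as.integer(names(agg))] <- agg
  out <- data.frame(
    point_id = cells$cell_id,
    x = cells$cx, y = cells$cy,
    population = sums
  )
  if (drop_empty) out <- out[out$population > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
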