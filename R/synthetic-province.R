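#' Specification for a synthetic province
#'
#' Defines the stated world of the toy study area: a rectangular planar
#' extent (metres, no geodesy), a multi-class road lattice, a heterogeneous
#' ~100 m population raster whose per-unit sums deliberately disagree with
#' the "census", rectangular admin units, and facilities with supply fields
#' and antivenom-type stocking flags.
#'
#' Defaults mirror the motivating provincial survey where it states values:
#' 25 facilities, four antivenom types with stocking frequencies 21/25,
#' 14/25, 11/25, 11/25, 100 m raster cells, a 2 km demand fishnet (the
#' 50 km x 40 km default extent yields 500 fishnet cells).
#'
#' @param seed integer random seed.
#' @param extent `c(xmin, ymin, xmax, ymax)` in metres.
#' @param n_admin_units number of rectangular admin units.
#' @param raster_resolution raster cell edge (m); must divide
#'   `fishnet_edge`.
#' @param road_lattice_spacing distance between lattice lines (m).
#' @param n_facilities number of facilities (>= 1).
#' @param antivenom_types type labels (default the four monovalent types).
#' @param census_distortion range of the multiplicative factor applied per
#'   admin unit so raster sums differ from census totals; `c(1, 1)` makes
#'   them agree.
#' @param fishnet_edge demand-cell edge (m, default 2000).
#' @return object of class `province_spec`.
#' @export
province_spec <- function(seed = 1,
                          extent = c(0, 0, 50000, 40000),
                          n_admin_units = 6,
                          raster_resolution = 100,
                          road_lattice_spacing = 5000,
                          n_facilities = 25,
                          antivenom_types = c("hyalys", "naja",
                                              "bungarus", "acutus"),
                          census_distortion = c(0.8, 1.25),
                          fishnet_edge = 2000) {
  extent <- as_extent(extent)
  if (n_facilities < 1) stopf("n_facilities must be >= 1")
  if (n_admin_units < 1) stopf("n_admin_units must be >= 1")
  if (raster_resolution <= 0) stopf("raster_resolution must be > 0")
  if (fishnet_edge %% raster_resolution != 0) {
    stopf("raster_resolution (%g) must divide the fishnet edge (%g)",
          raster_resolution, fishnet_edge)
  }
  if (extent_area(extent) < 100 * fishnet_edge^2) {
    stopf("extent must cover at least 100 fishnet cells")
  }
  if (length(census_distortion) != 2 ||
      census_distortion[1] > census_distortion[2] ||
      census_distortion[1] <= 0) {
    stopf("census_distortion must be a positive range c(lo, hi)")
  }
  structure(
    list(seed = as.integer(seed), extent = extent,
         n_admin_units = as.integer(n_admin_units),
         raster_resolution = raster_resolution,
         road_lattice_spacing = road_lattice_spacing,
         n_facilities = as.integer(n_facilities),
         antivenom_types = antivenom_types,
         census_distortion = census_distortion,
         fishnet_edge = fishnet_edge),
    class = "province_spec"
  )
}

lattice_class <- function(i, horizontal) {
  # deterministic class pattern exercising three distinct speeds
  if (i %% 4 == 0) "expressway" else if (horizontal && i %% 2 == 1) "rural"
  else "arterial"
}

# Lattice road layer: segments between adjacent lattice nodes, so every
# intersection is a shared endpoint (one graph node) and the grid is
# connected by construction.
make_lattice_roads <- function(extent, spacing) {
  xs <- seq(extent["xmin"], extent["xmax"], by = spacing)
  ys <- seq(extent["ymin"], extent["ymax"], by = spacing)
  seg_id <- character(0); seg_cls <- character(0); geom <- list()
  k <- 0L
  for (j in seq_along(ys)) {       # horizontal lines
    cls <- lattice_class(j - 1, horizontal = TRUE)
    for (i in seq_len(length(xs) - 1)) {
      k <- k + 1L
      seg_id[k] <- sprintf("H%02d_%02d", j, i)
      seg_cls[k] <- cls
      geom[[k]] <- rbind(c(xs[i], ys[j]), c(xs[i + 1], ys[j]))
    }
  }
  for (i in seq_along(xs)) {       # vertical lines
    cls <- lattice_class(i - 1, horizontal = FALSE)
    for (j in seq_len(length(ys) - 1)) {
      k <- k + 1L
      seg_id[k] <- sprintf("V%02d_%02d", i, j)
      seg_cls[k] <- cls
      geom[[k]] <- rbind(c(xs[i], ys[j]), c(xs[i], ys[j + 1]))
    }
  }
  road_layer(seg_id, seg_cls, geom)
}

# n rectangular units in a rows x cols grid (largest divisor split).
make_admin_grid <- function(extent, n) {
  rows <- max(which(seq_len(floor(sqrt(n))) %in%
                      Filter(function(d) n %% d == 0, seq_len(n))))
  cols <- n / rows
  w <- (extent["xmax"] - extent["xmin"]) / cols
  h <- (extent["ymax"] - extent["ymin"]) / rows
  ids <- character(n); geom <- vector("list", n)
  k <- 0L
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      k <- k + 1L
      x0 <- extent["xmin"] + (c - 1) * w
      y0 <- extent["ymin"] + (r - 1) * h
      ids[k] <- sprintf("U%02d", k)
      geom[[k]] <- rbind(c(x0, y0), c(x0 + w, y0),
                         c(x0 + w, y0 + h), c(x0, y0 + h))
    }
  }
  list(ids = ids, geom = geom)
}

#' Generate a synthetic province bundle
#'
#' Deterministic for a fixed seed. Roads form a connected lattice with at
#' least three distinct classes; per-cell population is lognormal (heavy
#' tails, like real settlement grids) and integer-rounded; each admin
#' unit's census total is its raster sum times a recorded distortion factor
#' drawn from `census_distortion`; facilities sit on road nodes, carry
#' positive beds and technicians, and every antivenom type is stocked by at
#' least one facility (facility 1 stocks all four).
#'
#' @param spec a [province_spec()].
#' @return object of class `province_bundle`: list with `roads`, `raster`,
#'   `admin_units`, `facilities`, `extent`, `fishnet_edge`, and the
#'   recorded `distortion` table (`unit_id`, `factor`).
#' @export
generate_province <- function(spec = province_spec()) {
  if (!inherits(spec, "province_spec")) stopf("spec must be a province_spec")
  set.seed(spec$seed)
  extent <- spec$extent

  roads <- make_lattice_roads(extent, spec$road_lattice_spacing)

  res <- spec$raster_resolution
  nc <- as.integer(round((extent["xmax"] - extent["xmin"]) / res))
  nr <- as.integer(round((extent["ymax"] - extent["ymin"]) / res))
  # lognormal settlement field, ~5 persons per 100 m cell on average
  vals <- round(stats::rlnorm(nr * nc, meanlog = log(5) - 0.5, sdlog = 1))
  raster <- pop_raster(matrix(vals, nrow = nr, ncol = nc),
                       xll = extent["xmin"], yll = extent["ymin"],
                       cellsize = res)

  ag <- make_admin_grid(extent, spec$n_admin_units)
  cc <- raster_cell_centers(raster)
  factors <- stats::runif(spec$n_admin_units,
                          spec$census_distortion[1],
                          spec$census_distortion[2])
  census <- numeric(spec$n_admin_units)
  for (u in seq_len(spec$n_admin_units)) {
    inside <- point_in_polygon(cc$x, cc$y, ag$geom[[u]])
    census[u] <- sum(cc$population[inside]) * factors[u]
  }
  units <- admin_units(ag$ids, census, ag$geom)

  xs <- seq(extent["xmin"], extent["xmax"], by = spec$road_lattice_spacing)
  ys <- seq(extent["ymin"], extent["ymax"], by = spec$road_lattice_spacing)
  nodes <- expand.grid(x = xs, y = ys)
  pick <- sample(nrow(nodes), spec$n_facilities,
                 replace = spec$n_facilities > nrow(nodes))
  beds <- pmax(1, round(stats::rlnorm(spec$n_facilities, log(200), 0.7)))
  tech <- pmax(1, round(beds * stats::runif(spec$n_facilities, 1.0, 1.6)))
  # stocking probabilities follow the survey's per-type hospital shares
  p_stock <- c(hyalys = 21, naja = 14, bungarus = 11, acutus = 11) / 25
  flags <- sapply(p_stock, function(p)
    as.integer(stats::runif(spec$n_facilities) < p))
  flags <- matrix(flags, nrow = spec$n_facilities,
                  dimnames = list(NULL, names(p_stock)))
  flags[1, ] <- 1L  # guarantees every type stocked and all_types non-empty
  fac <- data.frame(
    facility_id = sprintf("F%02d", seq_len(spec$n_facilities)),
    x = nodes$x[pick], y = nodes$y[pick],
    beds = beds, technicians = tech,
    stringsAsFactors = FALSE
  )
  fac <- cbind(fac, as.data.frame(flags))
  fac <- validate_facilities(fac)

  structure(
    list(roads = roads, raster = raster, admin_units = units,
         facilities = fac, extent = extent,
         fishnet_edge = spec$fishnet_edge,
         distortion = data.frame(unit_id = ag$ids, factor = factors,
                                 stringsAsFactors = FALSE)),
    class = "province_bundle"
  )
}

#' @export
print.province_bundle <- function(x, ...) {
  cat(sprintf(
    "<province_bundle> %d road segments, %d admin units, %d facilities, %.0f persons\n",
    nrow(x$roads), nrow(x$admin_units), nrow(x$facilities),
    raster_total(x$raster)
  ))
  invisible(x)
}

#' Hand-computable micro-scenario
#'
#' A fixed bundle whose 2SFCA solution is checkable by hand: one facility
#' (10 beds, 10 technicians, all types) at the west end of a single 22 km
#' arterial road; two populated demand cells — one whose centroid coincides
#' with the facility node (network distance 0) and one 20 km along the road
#' — with 100 persons each; all other cells empty. With the default 40 km
#' distance catchment: G(20) = 0.7013666, R = 10 / (100 + 100 G) =
#' 0.05877628, A(0 km) = R, A(20 km) = G R = 0.04122372, and
#' sum(D_i A_i) = 10 = total supply.
#'
#' @return a `province_bundle` (extent 22 km x 2 km, fishnet edge 2 km).
#' @export
known_answer_scenario <- function() {
  extent <- as_extent(c(0, 0, 22000, 2000))
  # one straight arterial with a vertex at every fishnet centroid x
  xs <- seq(1000, 21000, by = 2000)
  roads <- road_layer("R1", "arterial", list(cbind(xs, 1000)))
  res <- 100
  nc <- 220L; nr <- 20L
  v <- matrix(0, nrow = nr, ncol = nc)
  # cell centers: col c covers x in ((c-1)*100, c*100]; centroid x=1000 is
  # the center of col 10 at row with y=1050 -> row nr - 10 = 10
  v[10, 10] <- 100    # (x, y) = (950, 1050), inside fishnet cell 1
  v[10, 210] <- 100   # (x, y) = (20950, 1050), inside fishnet cell 11
  raster <- pop_raster(v, xll = 0, yll = 0, cellsize = res)
  units <- admin_units("U01", sum(v), list(rbind(
    c(0, 0), c(22000, 0), c(22000, 2000), c(0, 2000)
  )))
  fac <- validate_facilities(data.frame(
    facility_id = "F01", x = 1000, y = 1000,
    beds = 10, technicians = 10,
    hyalys = 1, naja = 1, bungarus = 1, acutus = 1,
    stringsAsFactors = FALSE
  ))
  structure(
    list(roads = roads, raster = raster, admin_units = units,
         facilities = fac, extent = extent, fishnet_edge = 2000,
         distortion = data.frame(unit_id = "U01", factor = 1,
                                 stringsAsFactors = FALSE)),
    class = "province_bundle"
  )
}
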