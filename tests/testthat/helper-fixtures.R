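# Shared fixtures and independent oracles, all built in code.

# A three-segment toy road layer: two arterials sharing a node plus a
# pedestrian spur.
tiny_roads <- function() {
  road_layer(
    c("a", "b", "c"),
    c("arterial", "arterial", "pedestrian"),
    list(
      rbind(c(0, 0), c(1000, 0)),
      rbind(c(1000, 0), c(2000, 0)),
      rbind(c(1000, 0), c(1000, 500))
    )
  )
}

# Independent all-pairs shortest-path oracle (Floyd-Warshall) on a
# travel_network's minute weights; returns the full node x node matrix.
fw_minutes <- function(network) {
  g <- network$graph
  n <- igraph::vcount(g)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$minutes
  for (e in seq_len(nrow(el))) {
    i <- el[e, 1]; j <- el[e, 2]
    D[i, j] <- min(D[i, j], w[e])
    D[j, i] <- min(D[j, i], w[e])
  }
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  rownames(D) <- colnames(D) <- igraph::V(g)$name
  D
}

# Random connected road layer: a random tree over n random points plus
# extra chords, with classes cycling through three speeds.
random_road_layer <- function(seed, n_nodes = 12, n_extra = 6) {
  set.seed(seed)
  pts <- cbind(runif(n_nodes, 0, 20000), runif(n_nodes, 0, 20000))
  from <- integer(0); to <- integer(0)
  for (i in 2:n_nodes) {             # random tree: connect i to earlier node
    from <- c(from, sample(i - 1, 1)); to <- c(to, i)
  }
  for (k in seq_len(n_extra)) {
    e <- sample(n_nodes, 2)
    from <- c(from, e[1]); to <- c(to, e[2])
  }
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  cls <- rep(c("expressway", "arterial", "rural"), length.out = length(from))
  road_layer(
    sprintf("s%02d", seq_along(from)), cls,
    lapply(seq_along(from), function(i) rbind(pts[from[i], ], pts[to[i], ]))
  )
}

# Construct an od_matrix object directly from cost matrices (km defaults to
# minutes so either cost basis works in unit tests).
manual_od <- function(minutes, km = minutes,
                      point_ids = rownames(minutes),
                      facility_ids = colnames(minutes)) {
  dimnames(minutes) <- dimnames(km) <- list(point_ids, facility_ids)
  structure(list(minutes = minutes, km = km), class = "od_matrix")
}

# A facility table emulating the survey's stocking pattern exactly:
# 25 hospitals; 21 hyalys, 14 naja, 11 bungarus, 11 acutus, 5 all-types.
survey_pattern_facilities <- function() {
  hy <- bu <- na <- ac <- rep(0L, 25)
  hy[1:21] <- 1L
  na[c(1:5, 6:10, 22:25)] <- 1L
  bu[c(1:5, 11:16)] <- 1L
  ac[c(1:5, 17:22)] <- 1L
  data.frame(
    facility_id = sprintf("F%02d", 1:25),
    x = seq(0, by = 1000, length.out = 25), y = 0,
    beds = 100L, technicians = 120L,
    hyalys = hy, naja = na, bungarus = bu, acutus = ac,
    stringsAsFactors = FALSE
  )
}

# Small province used across tests (fast: 100 x 100 raster, 100 cells).
small_spec <- function(...) {
  args <- utils::modifyList(
    list(seed = 7, extent = c(0, 0, 20000, 20000), n_admin_units = 4,
         raster_resolution = 200, road_lattice_spacing = 5000,
         n_facilities = 5),
    list(...)
  )
  do.call(province_spec, args)
}

# Independent zonal sum: population inside a polygon by brute-force scan
# over every raster cell center.
zonal_sum <- function(raster, poly) {
  cc <- raster_cell_centers(raster)
  pop <- cc$population
  pop[is.na(pop)] <- 0
  sum(pop[point_in_polygon_oracle(cc$x, cc$y, poly)])
}

# Re-derivation of even-odd ray casting, kept separate from the package's
# implementation (same classic algorithm, written against the closed ring).
point_in_polygon_oracle <- function(px, py, poly) {
  if (!all(poly[1, ] == poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    inside <- FALSE
    for (e in seq_len(nrow(poly) - 1)) {
      x1 <- poly[e, 1]; y1 <- poly[e, 2]
      x2 <- poly[e + 1, 1]; y2 <- poly[e + 1, 2]
      if ((y1 > y) != (y2 > y)) {
        xc <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
        if (x < xc) inside <- !inside
      }
    }
    inside
  }, logical(1))
}
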