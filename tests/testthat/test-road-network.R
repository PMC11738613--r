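test_that("edge travel times follow the class speed table", {
  r <- road_layer(
    c("a", "p"), c("arterial", "pedestrian"),
    list(rbind(c(0, 0), c(1000, 0)),        # 1 km at 60 km/h -> 1 min
         rbind(c(0, 100), c(5000, 100)))    # 5 km at 5 km/h -> 60 min
  )
  net <- build_graph(r)
  e <- igraph::as_data_frame(net$graph, what = "edges")
  expect_equal(sort(e$minutes), c(1, 60))
  expect_equal(e$minutes, e$km / (speed_table()[e$road_class] / 60),
               ignore_attr = TRUE)
})

test_that("speed table validates overrides and requires positive speeds", {
  expect_equal(unname(speed_table()[c("highway", "rural", "pedestrian")]),
               c(100, 30, 5))
  expect_equal(unname(speed_table(arterial = 50)["arterial"]), 50)
  expect_error(speed_table(tramline = 30), "unknown road class")
  expect_error(speed_table(rural = 0), "> 0")
})

test_that("segments sharing an endpoint merge into one node", {
  net <- build_graph(tiny_roads())
  expect_equal(nrow(net$nodes), 4)
  deg <- igraph::degree(net$graph)
  shared <- net$nodes$node[net$nodes$x == 1000 & net$nodes$y == 0]
  expect_equal(unname(deg[as.character(shared)]), 3)
})

test_that("zero-length pieces are dropped with a warning", {
  r <- road_layer(
    c("ok", "zero"), c("arterial", "arterial"),
    list(rbind(c(0, 0), c(1000, 0)), rbind(c(5, 5), c(5, 5)))
  )
  expect_warning(net <- build_graph(r), "zero-length")
  expect_equal(igraph::ecount(net$graph), 1)
})

test_that("snapping picks the nearest node, ties to the lower node id", {
  net <- build_graph(tiny_roads())   # nodes at (0,0),(1000,0),(2000,0),(1000,500)
  s <- snap_points(data.frame(x = 1000, y = 0), net)
  expect_equal(s$snap_m, 0)
  expect_equal(net$nodes$x[s$node], 1000)
  # equidistant between (0,0) and (1000,0): the lower node id wins
  s <- snap_points(data.frame(x = 500, y = 0), net)
  expect_equal(s$node, min(
    net$nodes$node[(net$nodes$x == 0 | net$nodes$x == 1000) &
                     net$nodes$y == 0]
  ))
  # beyond max_snap_m -> flagged unreachable
  s <- snap_points(data.frame(x = 1000, y = 90000), net, max_snap_m = 5000)
  expect_false(s$reachable)
})

test_that("snapping equals an exhaustive nearest-node scan", {
  net <- build_graph(random_road_layer(31, n_nodes = 15))
  set.seed(99)
  pts <- data.frame(x = runif(100, -1000, 21000), y = runif(100, -1000, 21000))
  s <- snap_points(pts, net, max_snap_m = Inf)
  for (i in seq_len(nrow(pts))) {
    d <- sqrt((net$nodes$x - pts$x[i])^2 + (net$nodes$y - pts$y[i])^2)
    expect_equal(s$snap_m[i], min(d))
  }
})

test_that("OD costs: identity, and shortest path beats the direct edge", {
  # triangle: A-B and B-C at 1 min each, A-C direct at 3 min
  r <- road_layer(
    c("ab", "bc", "ac"), c("arterial", "arterial", "rural"),
    list(rbind(c(0, 0), c(1000, 0)),
         rbind(c(1000, 0), c(1000, 1000)),
         rbind(c(0, 0), c(1000, 1000)))
  )
  net <- build_graph(r, speed_table(arterial = 60, rural = 60 * sqrt(2) / 3))
  demand <- data.frame(point_id = "d", x = 0, y = 0)
  fac <- data.frame(facility_id = c("self", "far"),
                    x = c(0, 1000), y = c(0, 1000))
  od <- od_cost_matrix(net, demand, fac)
  expect_equal(od$minutes["d", "self"], 0)
  expect_equal(od$km["d", "self"], 0)
  expect_equal(od$minutes["d", "far"], 2)   # 1+1 min, not the 3 min chord
  expect_equal(od$km["d", "far"], 2)        # km along the time-optimal path
})

test_that("OD times equal the Floyd-Warshall oracle on small graphs", {
  for (seed in c(12, 77, 301)) {
    layer <- random_road_layer(seed, n_nodes = 12, n_extra = 6)
    net <- build_graph(layer)
    D <- fw_minutes(net)
    demand <- data.frame(point_id = net$nodes$node,
                         x = net$nodes$x, y = net$nodes$y)
    fac_idx <- seq_len(3)
    fac <- data.frame(facility_id = sprintf("f%d", fac_idx),
                      x = net$nodes$x[fac_idx], y = net$nodes$y[fac_idx])
    od <- od_cost_matrix(net, demand, fac)
    expect_equal(unname(od$minutes),
                 unname(D[, as.character(fac_idx), drop = FALSE]),
                 tolerance = 1e-9)
  }
})

test_that("shortest-path metric: triangle inequality over facilities", {
  layer <- random_road_layer(55, n_nodes = 20, n_extra = 10)
  net <- build_graph(layer)
  D <- fw_minutes(net)
  n <- nrow(D)
  for (i in sample(n, 5)) {
    for (j in sample(n, 4)) {
      for (k in sample(n, 4)) {
        expect_lte(D[i, k], D[i, j] + D[j, k] + 1e-9)
      }
    }
  }
})

test_that("raising a class speed never increases OD times; doubling halves them", {
  layer <- random_road_layer(8, n_nodes = 14, n_extra = 7)
  demand <- data.frame(point_id = 1:5,
                       x = seq(0, 20000, length.out = 5), y = 5000)
  fac <- data.frame(facility_id = c("f1", "f2"),
                    x = c(1000, 18000), y = c(1000, 18000))
  base <- od_cost_matrix(build_graph(layer), demand, fac)
  faster <- od_cost_matrix(build_graph(layer, speed_table(rural = 90)),
                           demand, fac)
  expect_true(all(faster$minutes <= base$minutes + 1e-9))
  doubled <- od_cost_matrix(
    build_graph(layer, speed_table(
      highway = 200, expressway = 160, arterial = 120, feeder = 40,
      other = 40, internal = 40, rural = 60, bicycle = 30, pedestrian = 10
    )),
    demand, fac
  )
  expect_equal(doubled$minutes, base$minutes / 2, tolerance = 1e-12)
  expect_equal(doubled$km, base$km)   # same optimal paths, same distance
})

test_that("nearest_facility: argmin, ties, subsets, and errors", {
  m <- rbind(p1 = c(17.2, 9.4, 31.0))
  od <- manual_od(m, facility_ids = c("1", "2", "3"))
  nf <- nearest_facility(od)
  expect_equal(nf$facility_id, "2")
  expect_equal(nf$minutes, 9.4)

  # tie -> lower facility id (numeric ordering of ids)
  od <- manual_od(rbind(p1 = c(5, 5, 7)), facility_ids = c("10", "2", "3"))
  expect_equal(nearest_facility(od)$facility_id, "2")

  # singleton subset is nearest everywhere it is reachable
  od <- manual_od(rbind(p1 = c(3, 1), p2 = c(8, 2)),
                  facility_ids = c("a", "b"))
  nf <- nearest_facility(od, "a")
  expect_equal(nf$facility_id, c("a", "a"))
  expect_error(nearest_facility(od, character(0)), "empty")
  expect_error(nearest_facility(od, "zz"), "unknown")

  # unreachable rows are flagged
  od <- manual_od(rbind(p1 = c(Inf, Inf)), facility_ids = c("a", "b"))
  expect_false(nearest_facility(od)$reachable)
})

test_that("nearest facility over a flag subset matches a brute-force scan", {
  b <- generate_province(small_spec(seed = 21, n_facilities = 8))
  net <- build_graph(b$roads)
  cells <- build_fishnet(b$extent, b$fishnet_edge)
  demand <- make_demand_points(cells, b$raster)
  od <- od_cost_matrix(net, demand, b$facilities)
  sub <- b$facilities$facility_id[b$facilities$hyalys == 1]
  nf <- nearest_facility(od, sub)
  brute <- apply(od$minutes[, sub, drop = FALSE], 1, min)
  expect_equal(nf$minutes, unname(brute))
})
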