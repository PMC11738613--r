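#' Road-class travel-speed table
#'
#' Canonical nine-class vocabulary with the provincial peak-hour design
#' speeds (km/h): highway 100, expressway 80, arterial 60, feeder 20,
#' other 20, internal 20, rural 30, bicycle 15, pedestrian 5.
#'
#' @param ... named overrides, e.g. `arterial = 50`.
#' @return named numeric vector of speeds (km/h) over all nine classes.
#' @export
speed_table <- function(...) {
  sp <- default_speeds()
  over <- list(...)
  if (length(over) > 0) {
    bad <- setdiff(names(over), names(sp))
    if (length(bad) > 0) stopf("unknown road class(es): %s",
                               paste(bad, collapse = ", "))
    sp[names(over)] <- as.numeric(unlist(over))
  }
  if (any(sp <= 0)) stopf("all speeds must be > 0")
  sp
}

default_speeds <- function() {
  c(highway = 100, expressway = 80, arterial = 60, feeder = 20,
    other = 20, internal = 20, rural = 30, bicycle = 15, pedestrian = 5)
}

node_key <- function(x, y) sprintf("%.6f_%.6f", x, y)

#' Build a routable travel-time network from a road layer
#'
#' Nodes are created at every segment vertex; coordinates equal within
#' 1e-6 m are merged into one node, so segments sharing endpoints connect.
#' Each inter-vertex edge carries its Euclidean length (m), its road class,
#' and a travel time of `length_km / speed_kmh * 60` minutes. Edges are
#' undirected (the model has no one-way streets). Zero-length pieces are
#' dropped with a warning.
#'
#' @param roads a [road_layer()].
#' @param speeds a [speed_table()].
#' @return object of class `travel_network`: list with the `igraph` graph
#'   and a `nodes` data.frame (`node`, `x`, `y`).
#' @export
build_graph <- function(roads, speeds = speed_table()) {
  miss <- setdiff(unique(roads$road_class), names(speeds))
  if (length(miss) > 0) stopf("no speed for road class(es): %s",
                              paste(miss, collapse = ", "))
  from_x <- c(); from_y <- c(); to_x <- c(); to_y <- c()
  len <- c(); cls <- c()
  n_zero <- 0L
  for (i in seq_len(nrow(roads))) {
    g <- roads$geometry[[i]]
    d <- sqrt(rowSums(diff(g)^2))
    keep <- d > 0
    n_zero <- n_zero + sum(!keep)
    if (!any(keep)) next
    idx <- which(keep)
    from_x <- c(from_x, g[idx, 1]); from_y <- c(from_y, g[idx, 2])
    to_x <- c(to_x, g[idx + 1, 1]); to_y <- c(to_y, g[idx + 1, 2])
    len <- c(len, d[idx])
    cls <- c(cls, rep(roads$road_class[i], length(idx)))
  }
  if (n_zero > 0) warnf("%d zero-length road piece(s) dropped", n_zero)
  if (length(len) == 0) stopf("road layer has no usable segments")
  fk <- node_key(from_x, from_y)
  tk <- node_key(to_x, to_y)
  keys <- unique(c(fk, tk))
  nodes <- data.frame(
    node = seq_along(keys),
    x = c(from_x, to_x)[match(keys, c(fk, tk))],
    y = c(from_y, to_y)[match(keys, c(fk, tk))]
  )
  km <- len / 1000
  minutes <- km / unname(speeds[cls]) * 60
  edges <- data.frame(
    from = match(fk, keys), to = match(tk, keys),
    km = km, minutes = minutes, road_class = cls
  )
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes$node, x = nodes$x, y = nodes$y)
  )
  structure(list(graph = g, nodes = nodes), class = "travel_network")
}

#' @export
print.travel_network <- function(x, ...) {
  cat(sprintf("<travel_network> %d nodes, %d edges\n",
              nrow(x$nodes), igraph::ecount(x$graph)))
  invisible(x)
}

#' Snap points to their nearest network node
#'
#' Each point is assigned the nearest node by planar distance; ties go to the
#' lower node id. Points farther than `max_snap_m` are flagged unreachable.
#' Off-network access time from the point to its node is not added to travel
#' costs (the model is network-only).
#'
#' @param points data.frame with `x`, `y` (and optionally an id column).
#' @param network a [build_graph()] result.
#' @param max_snap_m maximum snap distance in metres (default 5000).
#' @return data.frame `node`, `snap_m`, `reachable`, one row per point.
#' @export
snap_points <- function(points, network, max_snap_m = 5000) {
  nx <- network$nodes$x; ny <- network$nodes$y
  n <- nrow(points)
  node <- integer(n); snap <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (nx - points$x[i])^2 + (ny - points$y[i])^2
    j <- which.min(d2)  # first minimum = lowest node id
    node[i] <- network$nodes$node[j]
    snap[i] <- sqrt(d2[j])
  }
  data.frame(node = node, snap_m = snap, reachable = snap <= max_snap_m)
}

#' Origin-destination travel-cost matrix
#'
#' Shortest paths by travel-time weight (Dijkstra) from every demand point
#' to every facility; the network distance reported is measured along the
#' same time-optimal path. Unreachable pairs (disconnected, or snapped
#' beyond the snap limit) are `Inf`.
#'
#' @param network a [build_graph()] result.
#' @param demand demand points data.frame with `point_id`, `x`, `y`.
#' @param facilities facility data.frame with `facility_id`, `x`, `y`.
#' @param max_snap_m forwarded to [snap_points()].
#' @return object of class `od_matrix`: list of two matrices `minutes` and
#'   `km` (rows = demand points, cols = facilities), plus the snap tables.
#' @export
od_cost_matrix <- function(network, demand, facilities, max_snap_m = 5000) {
  dsnap <- snap_points(demand, network, max_snap_m)
  fsnap <- snap_points(facilities, network, max_snap_m)
  g <- network$graph
  w_min <- igraph::E(g)$minutes
  w_km <- igraph::E(g)$km
  vnames <- igraph::V(g)$name
  d_idx <- match(as.character(dsnap$node), vnames)
  f_idx <- match(as.character(fsnap$node), vnames)

  ud <- unique(d_idx)
  minutes_u <- igraph::distances(g, v = ud, to = f_idx, weights = w_min,
                                 algorithm = "dijkstra")
  km_u <- matrix(Inf, nrow = length(ud), ncol = length(f_idx))
  for (r in seq_along(ud)) {
    sp <- igraph::shortest_paths(g, from = ud[r], to = f_idx,
                                 weights = w_min, output = "epath")
    for (cidx in seq_along(f_idx)) {
      ep <- sp$epath[[cidx]]
      if (length(ep) > 0 || is.finite(minutes_u[r, cidx])) {
        km_u[r, cidx] <- sum(w_km[ep])
      }
    }
  }
  rowmap <- match(d_idx, ud)
  minutes <- minutes_u[rowmap, , drop = FALSE]
  km <- km_u[rowmap, , drop = FALSE]
  minutes[!dsnap$reachable, ] <- Inf
  km[!dsnap$reachable, ] <- Inf
  minutes[, !fsnap$reachable] <- Inf
  km[, !fsnap$reachable] <- Inf
  dimnames(minutes) <- dimnames(km) <-
    list(as.character(demand$point_id), as.character(facilities$facility_id))
  structure(
    list(minutes = minutes, km = km,
         demand_snap = dsnap, facility_snap = fsnap),
    class = "od_matrix"
  )
}

#' @export
print.od_matrix <- function(x, ...) {
  cat(sprintf("<od_matrix> %d demand points x %d facilities (%d unreachable pairs)\n",
              nrow(x$minutes), ncol(x$minutes), sum(!is.finite(x$minutes))))
  invisible(x)
}

#' Long-form export of an OD matrix
#' @param x an `od_matrix`.
#' @param row.names,optional,... standard [as.data.frame()] arguments (unused).
#' @return data.frame `point_id`, `facility_id`, `minutes`, `km`
#'   (`NA` = unreachable).
#' @export
as.data.frame.od_matrix <- function(x, row.names = NULL, optional = FALSE, ...) {
  pts <- rownames(x$minutes); fac <- colnames(x$minutes)
  out <- data.frame(
    point_id = rep(pts, times = length(fac)),
    facility_id = rep(fac, each = length(pts)),
    minutes = as.vector(x$minutes),
    km = as.vector(x$km),
    stringsAsFactors = FALSE
  )
  out$minutes[!is.finite(out$minutes)] <- NA_real_
  out$km[!is.finite(out$km)] <- NA_real_
  out
}

#' Nearest facility per demand point
#'
#' Minimum-travel-time facility within an optional facility subset; ties
#' break to the lower facility id. Points with no reachable facility in the
#' subset come back with `reachable = FALSE`.
#'
#' @param od an [od_cost_matrix()] result.
#' @param facility_subset character vector of facility ids (default: all).
#' @return data.frame `point_id`, `facility_id`, `minutes`, `km`,
#'   `reachable`.
#' @export
nearest_facility <- function(od, facility_subset = NULL) {
  fac <- colnames(od$minutes)
  if (is.null(facility_subset)) facility_subset <- fac
  facility_subset <- as.character(facility_subset)
  if (length(facility_subset) == 0) stopf("empty facility subset")
  miss <- setdiff(facility_subset, fac)
  if (length(miss) > 0) stopf("unknown facility id(s): %s",
                              paste(miss, collapse = ", "))
  # order columns by facility id so which.min's first-match rule implements
  # the lower-id tie-break; numeric-looking ids compare numerically
  num <- suppressWarnings(as.numeric(facility_subset))
  ord <- if (anyNA(num)) order(facility_subset) else order(num)
  sub <- facility_subset[ord]
  m <- od$minutes[, sub, drop = FALSE]
  k <- od$km[, sub, drop = FALSE]
  n <- nrow(m)
  out <- data.frame(
    point_id = rownames(m),
    facility_id = NA_character_, minutes = NA_real_, km = NA_real_,
    reachable = FALSE, stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    j <- which.min(m[i, ])
    if (length(j) == 1 && is.finite(m[i, j])) {
      out$facility_id[i] <- sub[j]
      out$minutes[i] <- m[i, j]
      out$km[i] <- k[i, j]
      out$reachable[i] <- TRUE
    }
  }
  out
}
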