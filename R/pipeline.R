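#' Run the full accessibility pipeline on a province bundle
#'
#' Census-corrects the raster, builds the demand fishnet and points, builds
#' the travel-time graph, computes the OD cost matrix, the per-type
#' travel-time band reports, and the Gaussian 2SFCA scores for beds and
#' health technicians.
#'
#' @param bundle a `province_bundle` (from [generate_province()],
#'   [known_answer_scenario()] or [read_province()]).
#' @param params a [decay_params()].
#' @param scheme a [band_scheme()].
#' @param speeds a [speed_table()].
#' @param fishnet_edge demand-cell edge (m); defaults to the bundle's value
#'   or 2000.
#' @param max_snap_m snap limit forwarded to [od_cost_matrix()].
#' @param drop_empty drop zero-population demand cells (default FALSE).
#' @param extent study extent; defaults to the bundle's.
#' @return list with `points` (per-point table: coordinates, population,
#'   nearest facility over all facilities, minutes, band, `A_beds`,
#'   `A_tech`), `bands` (all-facility band summary), `per_type` (the
#'   [per_type_report()] list), `scores`, `ratios`, `od`, `demand`,
#'   `network`, `corrected_raster`, and generated-vs-routed counts.
#' @export
run_pipeline <- function(bundle,
                         params = decay_params(),
                         scheme = band_scheme(),
                         speeds = speed_table(),
                         fishnet_edge = NULL,
                         max_snap_m = 5000,
                         drop_empty = FALSE,
                         extent = NULL) {
  extent <- as_extent(extent %||% bundle$extent)
  fishnet_edge <- fishnet_edge %||% bundle$fishnet_edge %||% 2000

  corrected <- correct_raster(bundle$raster, bundle$admin_units)
  cells <- build_fishnet(extent, fishnet_edge)
  demand <- make_demand_points(cells, corrected, drop_empty = drop_empty)

  network <- build_graph(bundle$roads, speeds)
  od <- od_cost_matrix(network, demand, bundle$facilities,
                       max_snap_m = max_snap_m)

  reports <- per_type_report(bundle$facilities, demand, od, scheme)
  scores <- run_2sfca(bundle$facilities, demand, od, params)

  nf <- reports$any$nearest
  points <- data.frame(
    point_id = demand$point_id,
    x = demand$x, y = demand$y,
    population = demand$population,
    nearest_facility_id = nf$facility_id,
    travel_min = nf$minutes,
    band = as.character(classify_bands(nf$minutes, scheme)),
    A_beds = scores$A_beds,
    A_tech = scores$A_tech,
    stringsAsFactors = FALSE
  )
  list(
    points = points,
    bands = reports$any$summary,
    per_type = reports,
    scores = scores,
    ratios = attr(scores, "ratios"),
    od = od,
    demand = demand,
    network = network,
    corrected_raster = corrected,
    n_generated = nrow(demand),
    n_routed = reports$any$n_routed,
    n_unrouted = reports$any$n_unrouted
  )
}
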