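#' Classified road layer
#'
#' A set of polyline road segments in one planar metric coordinate system.
#' Stored as a data.frame with a list-column `geometry` of n x 2 coordinate
#' matrices (metres) plus `segment_id` and `road_class`.
#'
#' @param segment_id character or integer identifiers (unique).
#' @param road_class character vector of canonical road-class labels
#'   (see [speed_table()]).
#' @param geometry list of numeric matrices, each with >= 2 rows of (x, y).
#' @return object of class `road_layer` (a data.frame).
#' @export
road_layer <- function(segment_id, road_class, geometry) {
  if (length(segment_id) == 0) stopf("empty road layer")
  if (anyDuplicated(segment_id)) stopf("duplicate segment_id")
  ok <- vapply(geometry, function(g) is.matrix(g) && nrow(g) >= 2, logical(1))
  if (!all(ok)) stopf("every segment needs a >= 2-vertex coordinate matrix")
  df <- data.frame(
    segment_id = as.character(segment_id),
    road_class = as.character(road_class),
    stringsAsFactors = FALSE
  )
  df$geometry <- geometry
  class(df) <- c("road_layer", class(df))
  df
}

#' @export
print.road_layer <- function(x, ...) {
  cat(sprintf(
    "<road_layer> %d segments, %d classes (%s)\n",
    nrow(x), length(unique(x$road_class)),
    paste(sort(unique(x$road_class)), collapse = ", ")
  ))
  invisible(x)
}

segment_length <- function(g) {
  sum(sqrt(rowSums(diff(g)^2)))
}

# ---- GeoJSON ---------------------------------------------------------------

read_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stopf("%s: expected a GeoJSON FeatureCollection", path)
  }
  gj
}

coords_to_matrix <- function(coords) {
  do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
}

#' Read a classified road network from GeoJSON
#'
#' Expects a FeatureCollection of `LineString` features carrying a road-class
#' property. Class labels are validated against the canonical nine-class
#' vocabulary; source-specific codes can be translated via `class_map`.
#' Unrecognised classes are a hard error (silently dropping or defaulting
#' them would bias travel times), reported with their counts.
#'
#' @param path GeoJSON file. Shapefile input is not supported in this build;
#'   convert to GeoJSON first.
#' @param class_attr name of the feature property holding the class
#'   (default `"road_class"`).
#' @param class_map optional named character vector translating source codes
#'   to canonical labels, e.g. `c("motorway" = "expressway")`.
#' @return a [road_layer()].
#' @export
read_roads <- function(path, class_attr = "road_class", class_map = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (grepl("\\.shp$", path, ignore.case = TRUE)) {
    stopf("Shapefile input is not supported; convert %s to GeoJSON", path)
  }
  gj <- read_geojson(path)
  feats <- gj$features
  if (length(feats) == 0) stopf("%s: empty road layer", path)
  ids <- character(length(feats))
  cls <- character(length(feats))
  geom <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    if (!identical(f$geometry$type, "LineString")) {
      stopf("feature %d: geometry must be LineString, got %s",
            i, f$geometry$type %||% "NULL")
    }
    cl <- f$properties[[class_attr]]
    if (is.null(cl)) {
      stopf("feature %d is missing the road-class attribute '%s'",
            i, class_attr)
    }
    ids[i] <- as.character(f$properties$segment_id %||% i)
    cls[i] <- as.character(cl)
    geom[[i]] <- coords_to_matrix(f$geometry$coordinates)
  }
  if (!is.null(class_map)) {
    mapped <- !is.na(match(cls, names(class_map)))
    cls[mapped] <- unname(class_map[cls[mapped]])
  }
  known <- names(default_speeds())
  bad <- setdiff(unique(cls), known)
  if (length(bad) > 0) {
    counts <- table(cls[cls %in% bad])
    stopf(
      "unrecognised road class(es) with no mapping: %s",
      paste(sprintf("'%s' (%d segments)", names(counts), as.integer(counts)),
            collapse = ", ")
    )
  }
  road_layer(ids, cls, geom)
}

#' Write a road layer to GeoJSON
#' @param roads a [road_layer()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_roads <- function(roads, path) {
  feats <- lapply(seq_len(nrow(roads)), function(i) {
    g <- roads$geometry[[i]]
    list(
      type = "Feature",
      properties = list(
        segment_id = roads$segment_id[i],
        road_class = roads$road_class[i]
      ),
      geometry = list(
        type = "LineString",
        coordinates = lapply(seq_len(nrow(g)), function(r) c(g[r, 1], g[r, 2]))
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- Facilities ------------------------------------------------------------

#' Read the facility (hospital) table
#'
#' CSV columns: `facility_id,x,y,beds,technicians,hyalys,naja,bungarus,acutus`
#' with 0/1 stocking flags for the four antivenom types. A derived logical
#' `all_types` column marks facilities stocking all four. Per-type stocking
#' counts are attached as attribute `"type_counts"` (also available via
#' [facility_type_counts()]).
#'
#' @param path CSV file.
#' @return data.frame of facilities with derived `all_types`.
#' @export
read_facilities <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  fac <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_facilities(fac)
}

validate_facilities <- function(fac) {
  need <- c("facility_id", "x", "y", "beds", "technicians",
            "hyalys", "naja", "bungarus", "acutus")
  miss <- setdiff(need, names(fac))
  if (length(miss) > 0) {
    stopf("facility table missing column(s): %s", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(fac$facility_id)) {
    stopf("duplicate facility_id: %s",
          paste(unique(fac$facility_id[duplicated(fac$facility_id)]),
                collapse = ", "))
  }
  if (any(fac$beds < 0) || any(fac$technicians < 0)) {
    stopf("negative beds or technicians in facility table")
  }
  flags <- c("hyalys", "naja", "bungarus", "acutus")
  for (fl in flags) {
    if (!all(fac[[fl]] %in% c(0, 1))) stopf("flag column '%s' must be 0/1", fl)
  }
  fac$all_types <- rowSums(fac[flags]) == length(flags)
  attr(fac, "type_counts") <- facility_type_counts(fac)
  fac
}

#' Per-antivenom-type facility counts
#' @param facilities facility data.frame (see [read_facilities()]).
#' @return named integer vector over the four types plus `all_types`.
#' @export
facility_type_counts <- function(facilities) {
  flags <- c("hyalys", "naja", "bungarus", "acutus")
  n <- vapply(flags, function(fl) sum(facilities[[fl]] == 1), integer(1))
  c(n, all_types = sum(rowSums(facilities[flags]) == length(flags)))
}

#' Write the facility table to CSV
#' @param facilities facility data.frame.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_facilities <- function(facilities, path) {
  cols <- c("facility_id", "x", "y", "beds", "technicians",
            "hyalys", "naja", "bungarus", "acutus")
  utils::write.csv(facilities[cols], path, row.names = FALSE)
  invisible(path)
}

# ---- Admin units -----------------------------------------------------------

#' Read administrative units (polygons + census totals)
#'
#' @param geojson_path FeatureCollection of Polygon features with a
#'   `unit_id` property.
#' @param census_csv CSV with columns `unit_id,census_pop`.
#' @return data.frame with `unit_id`, `census_pop` and list-column `geometry`
#'   (ring vertex matrices), class `admin_units`.
#' @export
read_admin_units <- function(geojson_path, census_csv) {
  gj <- read_geojson(geojson_path)
  feats <- gj$features
  if (length(feats) == 0) stopf("empty admin-unit layer")
  ids <- character(length(feats))
  geom <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    if (!identical(f$geometry$type, "Polygon")) {
      stopf("admin feature %d: expected Polygon", i)
    }
    ids[i] <- as.character(f$properties$unit_id %||% i)
    geom[[i]] <- coords_to_matrix(f$geometry$coordinates[[1]])
  }
  census <- utils::read.csv(census_csv, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "census_pop") %in% names(census))) {
    stopf("census CSV needs columns unit_id,census_pop")
  }
  m <- match(ids, as.character(census$unit_id))
  if (anyNA(m)) {
    stopf("census totals missing for unit(s): %s",
          paste(ids[is.na(m)], collapse = ", "))
  }
  admin_units(ids, census$census_pop[m], geom)
}

#' Construct an admin-unit table
#' @param unit_id identifiers.
#' @param census_pop census population totals (persons, >= 0).
#' @param geometry list of polygon ring matrices.
#' @return `admin_units` data.frame.
#' @export
admin_units <- function(unit_id, census_pop, geometry) {
  if (any(census_pop < 0)) stopf("negative census population")
  df <- data.frame(
    unit_id = as.character(unit_id),
    census_pop = as.numeric(census_pop),
    stringsAsFactors = FALSE
  )
  df$geometry <- geometry
  class(df) <- c("admin_units", class(df))
  df
}

#' Write admin units to GeoJSON + census CSV
#' @param units `admin_units` data.frame.
#' @param geojson_path,census_csv output files.
#' @return paths, invisibly.
#' @export
write_admin_units <- function(units, geojson_path, census_csv) {
  feats <- lapply(seq_len(nrow(units)), function(i) {
    g <- units$geometry[[i]]
    if (!all(g[1, ] == g[nrow(g), ])) g <- rbind(g, g[1, ])
    list(
      type = "Feature",
      properties = list(unit_id = units$unit_id[i]),
      geometry = list(
        type = "Polygon",
        coordinates = list(
          lapply(seq_len(nrow(g)), function(r) c(g[r, 1], g[r, 2]))
        )
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       geojson_path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(
    data.frame(unit_id = units$unit_id, census_pop = units$census_pop),
    census_csv, row.names = FALSE
  )
  invisible(c(geojson_path, census_csv))
}

# ---- Raster (ESRI ASCII grid) ---------------------------------------------

#' Read a population raster from an ESRI ASCII grid
#'
#' Plain-text single-band raster (`.asc`): a 6-line header
#' (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value) followed by rows
#' north to south. NODATA cells are treated as population 0; their count is
#' reported with a message.
#'
#' @param path `.asc` file.
#' @return a [pop_raster()].
#' @export
read_pop_raster <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) {
    stopf("%s: expected %d values, found %d", path, nr * nc, length(vals))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- hdr$nodata_value %||% -9999
  n_missing <- sum(m == nodata)
  if (n_missing > 0) {
    message(sprintf("%d NODATA cells treated as population 0", n_missing))
    m[m == nodata] <- 0
  }
  pop_raster(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
             cellsize = hdr$cellsize)
}

#' Write a population raster as an ESRI ASCII grid
#' @param raster a [pop_raster()].
#' @param path output `.asc` file.
#' @param nodata value encoding missing cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_pop_raster <- function(raster, path, nodata = -9999) {
  v <- raster$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", raster$xll),
    sprintf("yllcorner %.10g", raster$yll),
    sprintf("cellsize %.10g", raster$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  rows <- apply(v, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# ---- Bundle round-trip and pipeline outputs -------------------------------

#' Write a province bundle to a directory
#'
#' Emits `roads.geojson`, `population.asc`, `admin_units.geojson`,
#' `census.csv`, `facilities.csv`.
#'
#' @param bundle a `province_bundle` (see [generate_province()]).
#' @param dir output directory (created if needed).
#' @return named character vector of paths, invisibly.
#' @export
write_province <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(
    roads = file.path(dir, "roads.geojson"),
    raster = file.path(dir, "population.asc"),
    admin = file.path(dir, "admin_units.geojson"),
    census = file.path(dir, "census.csv"),
    facilities = file.path(dir, "facilities.csv")
  )
  write_roads(bundle$roads, p["roads"])
  write_pop_raster(bundle$raster, p["raster"])
  write_admin_units(bundle$admin_units, p["admin"], p["census"])
  write_facilities(bundle$facilities, p["facilities"])
  invisible(p)
}

#' Read a province bundle from a directory written by [write_province()]
#' @param dir directory containing the five layer files.
#' @return a `province_bundle` list (without generator metadata).
#' @export
read_province <- function(dir) {
  bundle <- list(
    roads = read_roads(file.path(dir, "roads.geojson")),
    raster = read_pop_raster(file.path(dir, "population.asc")),
    admin_units = read_admin_units(file.path(dir, "admin_units.geojson"),
                                   file.path(dir, "census.csv")),
    facilities = read_facilities(file.path(dir, "facilities.csv"))
  )
  class(bundle) <- "province_bundle"
  bundle
}

#' Write pipeline results to disk
#'
#' Writes (a) the per-demand-point table as CSV, (b) the travel-time band
#' summary CSV, (c) the demand points with scores as GeoJSON, and returns a
#' manifest of files with row counts.
#'
#' @param results list with components `points` (per-point data.frame with
#'   columns point_id, x, y, population, nearest_facility_id, travel_min,
#'   band, A_beds, A_tech) and `bands` (band summary data.frame); e.g. from
#'   [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return data.frame manifest: `file`, `rows`.
#' @export
write_outputs <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0) {
    stopf("output directory not writable: %s", out_dir)
  }
  pts <- results$points
  bands <- results$bands
  pt_cols <- c("point_id", "x", "y", "population", "nearest_facility_id",
               "travel_min", "band", "A_beds", "A_tech")
  if (is.null(pts) || nrow(pts) == 0) {
    pts <- as.data.frame(setNames(rep(list(logical(0)), length(pt_cols)),
                                  pt_cols))
  }
  f_pts <- file.path(out_dir, "demand_points.csv")
  utils::write.csv(pts[intersect(pt_cols, names(pts))], f_pts,
                   row.names = FALSE)
  f_bands <- file.path(out_dir, "band_summary.csv")
  if (is.null(bands)) bands <- empty_band_summary()
  utils::write.csv(bands, f_bands, row.names = FALSE)
  f_gj <- file.path(out_dir, "demand_points.geojson")
  feats <- lapply(seq_len(nrow(pts)), function(i) {
    props <- as.list(pts[i, setdiff(names(pts), c("x", "y"))])
    list(
      type = "Feature",
      properties = props,
      geometry = list(type = "Point", coordinates = c(pts$x[i], pts$y[i]))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       f_gj, auto_unbox = TRUE, digits = NA)
  data.frame(
    file = c(f_pts, f_bands, f_gj),
    rows = c(nrow(pts), nrow(bands), length(feats)),
    stringsAsFactors = FALSE
  )
}
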