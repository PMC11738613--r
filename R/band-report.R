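#' Travel-time band scheme
#'
#' The five reporting intervals in minutes — `[0,30]`, `(30,60]`, `(60,90]`,
#' `(90,120]`, `(120,Inf)` — plus the nominal per-cell area used for band
#' areas (4 km² for the default 2 km fishnet).
#'
#' @param breaks increasing numeric vector of interior boundaries
#'   (default `c(30, 60, 90, 120)`).
#' @param cell_area_km2 nominal area of one demand cell (default 4).
#' @return object of class `band_scheme` with `breaks`, `labels`,
#'   `cell_area_km2`.
#' @export
band_scheme <- function(breaks = c(30, 60, 90, 120), cell_area_km2 = 4) {
  if (is.unsorted(breaks, strictly = TRUE) || any(breaks <= 0)) {
    stopf("breaks must be positive and strictly increasing")
  }
  lab <- c(
    sprintf("<=%g", breaks[1]),
    if (length(breaks) > 1) {
      sprintf("%g<m<=%g", breaks[-length(breaks)], breaks[-1])
    },
    sprintf(">%g", breaks[length(breaks)])
  )
  structure(list(breaks = breaks, labels = lab,
                 cell_area_km2 = cell_area_km2),
            class = "band_scheme")
}

#' Classify nearest-facility times into travel-time bands
#'
#' Half-open on the left: exactly 30.0 min falls in the first band,
#' 30.000001 in the second. Non-finite times (unreachable points) come back
#' as `NA` and are excluded from summaries.
#'
#' @param minutes numeric vector of nearest-facility travel times.
#' @param scheme a [band_scheme()].
#' @return factor of band labels (levels in band order), `NA` = unreachable.
#' @export
classify_bands <- function(minutes, scheme = band_scheme()) {
  if (any(minutes < 0, na.rm = TRUE)) stopf("negative travel time")
  m <- minutes
  m[!is.finite(m)] <- NA
  cut(m, breaks = c(0, scheme$breaks, Inf), labels = scheme$labels,
      include.lowest = TRUE, right = TRUE)
}

empty_band_summary <- function(scheme = band_scheme()) {
  data.frame(
    band = scheme$labels, n_points = 0L, proportion_pct = 0,
    area_km2 = 0, population_persons = 0, population_1e4 = 0,
    stringsAsFactors = FALSE
  )
}

#' Band summary table (counts, proportions, areas, populations)
#'
#' One row per band: point count, percentage of routed points (1 decimal,
#' half-up), nominal area `n * cell_area` km², and band population in
#' persons plus the 10^4-person display unit used in provincial reporting
#' tables (their "thousands" header is a mislabel — cross-checking the
#' headline ">1 h" figures shows the unit is 10^4 persons).
#'
#' @param bands factor from [classify_bands()] (`NA` = unrouted, excluded).
#' @param populations demand populations aligned with `bands`.
#' @param scheme a [band_scheme()].
#' @param n_total denominator for proportions (default: number of routed
#'   points).
#' @return data.frame `band`, `n_points`, `proportion_pct`, `area_km2`,
#'   `population_persons`, `population_1e4`.
#' @export
summarize_bands <- function(bands, populations, scheme = band_scheme(),
                            n_total = NULL) {
  ok <- !is.na(bands)
  n_total <- n_total %||% sum(ok)
  if (n_total == 0) stopf("no routed demand points to summarise")
  n <- as.integer(table(bands[ok]))
  pop <- as.numeric(tapply(populations[ok], bands[ok], sum, default = 0))
  data.frame(
    band = scheme$labels,
    n_points = n,
    proportion_pct = round_half_up(100 * n / n_total, 1),
    area_km2 = n * scheme$cell_area_km2,
    population_persons = pop,
    population_1e4 = round_half_up(pop / 1e4, 1),
    stringsAsFactors = FALSE
  )
}

#' Population beyond a travel-time threshold
#'
#' Sums band populations for every band strictly above the threshold, which
#' must be one of the scheme's band boundaries (the one-hour roll-up sums
#' the 60–90, 90–120 and >120 bands).
#'
#' @param rows a [summarize_bands()] table for one facility subset.
#' @param threshold minutes; must coincide with a band boundary
#'   (default 60).
#' @param scheme the [band_scheme()] that produced `rows`.
#' @return persons (from `population_persons`).
#' @export
over_threshold_population <- function(rows, threshold = 60,
                                      scheme = band_scheme()) {
  idx <- match(threshold, scheme$breaks)
  if (is.na(idx)) {
    stopf("threshold %g min is not a band boundary (%s)",
          threshold, paste(scheme$breaks, collapse = ", "))
  }
  sum(rows$population_persons[(idx + 1):nrow(rows)])
}

#' Per-antivenom-type travel-time band report
#'
#' For each antivenom type with at least one stocking facility — and for the
#' facilities stocking all four types — computes the nearest stocked
#' facility per demand point, classifies into bands, and summarises. Empty
#' subsets are skipped with a warning.
#'
#' @param facilities facility data.frame with the four 0/1 type flags.
#' @param demand demand points data.frame.
#' @param od an [od_cost_matrix()] result.
#' @param scheme a [band_scheme()].
#' @param types flag columns to report on (default the four types).
#' @param include_all_facilities also report the pooled all-facility subset
#'   (default TRUE, labelled `"any"`).
#' @return named list, one element per subset, each a list with
#'   `facility_ids`, `nearest` (per-point table), `summary` (band table),
#'   `n_routed`, `n_unrouted`.
#' @export
per_type_report <- function(facilities, demand, od, scheme = band_scheme(),
                            types = c("hyalys", "naja", "bungarus", "acutus"),
                            include_all_facilities = TRUE) {
  fac_ids <- as.character(facilities$facility_id)
  subsets <- list()
  if (include_all_facilities) subsets$any <- fac_ids
  for (t in types) {
    subsets[[t]] <- fac_ids[facilities[[t]] == 1]
  }
  subsets$all_types <- fac_ids[rowSums(facilities[types]) == length(types)]
  out <- list()
  for (nm in names(subsets)) {
    ids <- subsets[[nm]]
    if (length(ids) == 0) {
      warnf("no facility stocks '%s'; subset skipped", nm)
      next
    }
    nf <- nearest_facility(od, ids)
    bands <- classify_bands(nf$minutes, scheme)
    out[[nm]] <- list(
      facility_ids = ids,
      nearest = nf,
      summary = summarize_bands(bands, demand$population, scheme),
      n_routed = sum(!is.na(bands)),
      n_unrouted = sum(is.na(bands))
    )
  }
  out
}
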