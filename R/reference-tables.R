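#' Published travel-time band statistics for antivenom-stocked hospitals
#'
#' The reported band counts and band populations from the 2024 provincial
#' snakebite-antivenom accessibility survey of Hainan Island, China (25
#' stocked hospitals, 2 km demand grid, five travel-time bands): one row
#' per facility subset — all stocked hospitals pooled (`any`), each of the
#' four antivenom types, and the hospitals stocking all four (`all_types`).
#' Band populations are in the survey table's display unit of 10^4 persons
#' (its "thousands" header is a mislabel; the headline ">1 h" population
#' figures confirm the 10^4 scale). These printed values are inputs for the
#' worked-example report arithmetic; the package never fits to them.
#'
#' @return data.frame with columns `subset`, `n_facilities`, the five band
#'   counts `n_le30`, `n_30_60`, `n_60_90`, `n_90_120`, `n_gt120`, the
#'   routed total `n_total`, and the five band populations (10^4 persons)
#'   `pop_le30` ... `pop_gt120`.
#' @export
reference_band_table <- function() {
  data.frame(
    subset = c("any", "hyalys", "naja", "bungarus", "acutus", "all_types"),
    n_facilities = c(25L, 21L, 14L, 11L, 11L, 5L),
    n_le30   = c(4055L, 3855L, 2118L, 1799L, 1695L, 805L),
    n_30_60  = c(4106L, 4159L, 3971L, 3683L, 4045L, 2491L),
    n_60_90  = c(498L, 645L, 2153L, 2510L, 2521L, 2898L),
    n_90_120 = c(48L, 49L, 444L, 654L, 415L, 1794L),
    n_gt120  = c(0L, 0L, 21L, 61L, 31L, 719L),
    n_total  = c(8707L, 8708L, 8707L, 8707L, 8707L, 8707L),
    pop_le30   = c(370.4, 345.3, 231.8, 217.8, 224.1, 142.2),
    pop_30_60  = c(407.7, 409.9, 377.6, 315.8, 349.9, 226.4),
    pop_60_90  = c(58.7, 81.2, 209.0, 251.7, 245.0, 278.3),
    pop_90_120 = c(3.8, 4.4, 21.6, 51.7, 18.1, 146.2),
    pop_gt120  = c(0, 0, 0.7, 3.7, 3.5, 47.6),
    stringsAsFactors = FALSE
  )
}

#' Band summary from published counts and populations
#'
#' Rebuilds a [summarize_bands()]-shaped table from one row of
#' [reference_band_table()], converting the 10^4-person display unit back
#' to persons, so the report operations (proportions, areas, over-threshold
#' roll-ups) can be run on the published figures.
#'
#' @param subset one of `"any"`, `"hyalys"`, `"naja"`, `"bungarus"`,
#'   `"acutus"`, `"all_types"`.
#' @param scheme a [band_scheme()].
#' @return list with `summary` (band table) and `n_total` (routed points).
#' @export
reference_band_summary <- function(subset = "any", scheme = band_scheme()) {
  tab <- reference_band_table()
  row <- tab[tab$subset == subset, ]
  if (nrow(row) != 1) stopf("unknown subset '%s'", subset)
  n <- as.integer(row[paste0("n_", c("le30", "30_60", "60_90",
                                     "90_120", "gt120"))])
  pop4 <- as.numeric(row[paste0("pop_", c("le30", "30_60", "60_90",
                                          "90_120", "gt120"))])
  list(
    summary = data.frame(
      band = scheme$labels,
      n_points = n,
      proportion_pct = round_half_up(100 * n / row$n_total, 1),
      area_km2 = n * scheme$cell_area_km2,
      population_persons = pop4 * 1e4,
      population_1e4 = pop4,
      stringsAsFactors = FALSE
    ),
    n_total = row$n_total
  )
}
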