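#' Catchment / decay parameters
#'
#' The catchment threshold d0 and the cost basis it is measured on. The
#' default is a 40 km network-distance radius (antivenom provisioning needs
#' cold-chain-capable hospitals, hence a generous driving catchment); a
#' travel-time basis in minutes is supported as an alternative
#' parameterisation of the same threshold.
#'
#' @param d0 catchment threshold, > 0; kilometres when
#'   `cost_basis = "distance"`, minutes when `cost_basis = "time"`.
#' @param cost_basis `"distance"` (network km, default) or `"time"`.
#' @return object of class `decay_params`.
#' @export
decay_params <- function(d0 = 40, cost_basis = c("distance", "time")) {
  if (!is.numeric(d0) || length(d0) != 1 || d0 <= 0) stopf("d0 must be > 0")
  cost_basis <- match.arg(cost_basis)
  structure(list(d0 = d0, cost_basis = cost_basis), class = "decay_params")
}

#' Gaussian distance-decay kernel
#'
#' The truncated, renormalised Gaussian used by Gaussian 2SFCA:
#' \deqn{G(d) = \frac{e^{-\frac12 (d/d_0)^2} - e^{-\frac12}}{1 - e^{-\frac12}}, \quad d < d_0}
#' and \eqn{G(d) = 0} for \eqn{d \ge d_0}. It declines smoothly from 1 at
#' `d = 0` to exactly 0 at the catchment threshold, so including or
#' excluding the boundary itself changes nothing.
#'
#' @param d non-negative cost(s) in the unit of `params$d0`.
#' @param params a [decay_params()].
#' @return weight(s) in `[0, 1]`.
#' @export
gaussian_decay <- function(d, params = decay_params()) {
  if (any(d < 0, na.rm = TRUE)) stopf("negative travel cost")
  d0 <- params$d0
  w <- (exp(-0.5 * (d / d0)^2) - exp(-0.5)) / (1 - exp(-0.5))
  w[!is.finite(d) | d >= d0] <- 0
  w
}

od_cost <- function(od, params) {
  switch(params$cost_basis, distance = od$km, time = od$minutes)
}

#' Step 1: facility supply-to-weighted-demand ratios
#'
#' For each facility j, demand points within the catchment (cost `<= d0`)
#' are weighted by the Gaussian kernel and summed; the ratio is
#' \deqn{R_j = S_j / \sum_{k: d_{jk} \le d_0} G(d_{jk}) D_k.}
#' Facilities whose catchment holds no (weighted) demand have no one to
#' allocate their supply to: they are flagged and their R set to 0.
#'
#' @param facilities facility data.frame (needs `facility_id` and the
#'   supply column).
#' @param demand demand points data.frame (`point_id`, `population`).
#' @param od an [od_cost_matrix()] result covering all pairs.
#' @param params a [decay_params()].
#' @param supply_field name of the supply column, e.g. `"beds"` or
#'   `"technicians"`.
#' @return data.frame `facility_id`, `supply`, `catchment_weighted_demand`,
#'   `R`, `empty_catchment`.
#' @export
supply_demand_ratios <- function(facilities, demand, od,
                                 params = decay_params(),
                                 supply_field = "beds") {
  if (!supply_field %in% names(facilities)) {
    stopf("unknown supply field '%s'", supply_field)
  }
  cost <- od_cost(od, params)
  fac_ids <- as.character(facilities$facility_id)
  stopifnot(all(fac_ids %in% colnames(cost)))
  cost <- cost[as.character(demand$point_id), fac_ids, drop = FALSE]
  W <- gaussian_decay(cost, params)          # n_demand x n_fac
  wd <- as.vector(crossprod(W, demand$population))
  S <- as.numeric(facilities[[supply_field]])
  empty <- wd == 0
  R <- ifelse(empty, 0, S / wd)
  if (any(empty)) {
    warnf("%d facility(ies) with empty catchment; R set to 0", sum(empty))
  }
  data.frame(
    facility_id = fac_ids, supply = S,
    catchment_weighted_demand = wd, R = R, empty_catchment = empty,
    stringsAsFactors = FALSE
  )
}

#' Step 2: accessibility score per demand point
#'
#' Each demand point sums the distance-weighted ratios of the facilities in
#' its catchment: \deqn{A_i = \sum_{j: d_{ij} \le d_0} G(d_{ij}) R_j.}
#' Larger A means better access; units are supply units (beds or
#' technicians) per person, with `per_1000 = 1000 * A` for reporting.
#' Facility-to-demand and demand-to-facility costs coincide on the
#' undirected network, so the same OD matrix serves both steps.
#'
#' @param ratios a [supply_demand_ratios()] result (same `params`).
#' @param demand demand points data.frame.
#' @param od the same [od_cost_matrix()] result.
#' @param params the same [decay_params()].
#' @return data.frame `point_id`, `A`, `per_1000`.
#' @export
accessibility_scores <- function(ratios, demand, od,
                                 params = decay_params()) {
  cost <- od_cost(od, params)
  cost <- cost[as.character(demand$point_id),
               as.character(ratios$facility_id), drop = FALSE]
  W <- gaussian_decay(cost, params)
  R <- ifelse(ratios$empty_catchment, 0, ratios$R)
  A <- as.vector(W %*% R)
  data.frame(point_id = demand$point_id, A = A, per_1000 = 1000 * A)
}

#' Gaussian two-step floating catchment area, both supply measures
#'
#' Runs [supply_demand_ratios()] + [accessibility_scores()] once per supply
#' field (beds and health technicians by default) and merges the results.
#'
#' @param facilities facility data.frame.
#' @param demand demand points data.frame.
#' @param od an [od_cost_matrix()] result.
#' @param params a [decay_params()].
#' @param supply_fields supply columns to evaluate.
#' @return data.frame with `point_id` and, per field `f`, columns `A_<f>`
#'   and `A_<f>_per_1000`; the per-field ratio tables are attached as
#'   attribute `"ratios"` (named list).
#' @export
run_2sfca <- function(facilities, demand, od, params = decay_params(),
                      supply_fields = c("beds", "technicians")) {
  out <- data.frame(point_id = demand$point_id)
  all_ratios <- list()
  for (f in supply_fields) {
    r <- supply_demand_ratios(facilities, demand, od, params, f)
    a <- accessibility_scores(r, demand, od, params)
    short <- if (f == "technicians") "tech" else f
    out[[paste0("A_", short)]] <- a$A
    out[[paste0("A_", short, "_per_1000")]] <- a$per_1000
    all_ratios[[f]] <- r
  }
  attr(out, "ratios") <- all_ratios
  out
}
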