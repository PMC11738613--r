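# Closed-form oracle for the truncated, renormalised Gaussian kernel.
kernel_oracle <- function(d, d0) {
  ifelse(d >= d0, 0,
         (exp(-0.5 * (d / d0)^2) - exp(-0.5)) / (1 - exp(-0.5)))
}

test_that("kernel bounds and frozen reference value", {
  p <- decay_params(d0 = 40)
  expect_equal(gaussian_decay(0, p), 1)
  expect_equal(gaussian_decay(40, p), 0)
  expect_equal(gaussian_decay(1000, p), 0)
  # independent closed-form evaluation, frozen to 10 digits
  expect_equal(gaussian_decay(20, p), 0.7013665732, tolerance = 1e-9)
  expect_error(gaussian_decay(-1, p), "negative")
  expect_error(decay_params(d0 = 0), "> 0")
})

test_that("kernel is strictly decreasing on [0, d0) and matches the oracle", {
  p <- decay_params(d0 = 40)
  d <- seq(0, 39.9, by = 0.1)
  g <- gaussian_decay(d, p)
  expect_true(all(diff(g) < 0))
  expect_true(all(g >= 0 & g <= 1))
  expect_equal(g, kernel_oracle(d, 40), tolerance = 1e-12)
  # continuity at the support boundary: G(d -> d0-) -> 0
  expect_lt(gaussian_decay(39.9999, p), 1e-4)
})

test_that("supply-demand ratios: unit ratio, fixture value, empty catchment", {
  demand <- data.frame(point_id = c("k1", "k2"), population = c(100, 100))
  fac <- data.frame(facility_id = "j1", beds = 10, technicians = 10)
  od <- manual_od(cbind(j1 = c(k1 = 0, k2 = 20)))
  p <- decay_params(d0 = 40, cost_basis = "distance")
  r <- supply_demand_ratios(fac, demand, od, p, "beds")
  expect_equal(r$catchment_weighted_demand, 100 + 100 * 0.7013665732,
               tolerance = 1e-9)
  expect_equal(r$R, 0.05877628, tolerance = 1e-7)

  # co-located demand D = S -> R = 1
  demand1 <- data.frame(point_id = "k1", population = 10)
  od1 <- manual_od(cbind(j1 = c(k1 = 0)))
  expect_equal(supply_demand_ratios(fac, demand1, od1, p, "beds")$R, 1)

  # all demand beyond d0 -> flagged, R = 0
  od2 <- manual_od(cbind(j1 = c(k1 = 45, k2 = 60)))
  expect_warning(r2 <- supply_demand_ratios(fac, demand, od2, p, "beds"),
                 "empty catchment")
  expect_true(r2$empty_catchment)
  expect_equal(r2$R, 0)

  expect_error(supply_demand_ratios(fac, demand, od, p, "ambulances"),
               "unknown supply field")
})

test_that("fixture accessibility scores match the hand evaluation", {
  res <- run_pipeline(known_answer_scenario())
  live <- res$points[res$points$population > 0, ]
  expect_equal(live$A_beds, c(0.05877628, 0.04122372), tolerance = 1e-7)
  expect_equal(live$A_tech, live$A_beds)   # identical supply fields
  # spec-quoted approximations agree at coarser precision
  expect_equal(live$A_beds[1], 0.058776, tolerance = 1e-4)
  expect_equal(live$A_beds[2], 0.041226, tolerance = 1e-3)
})

test_that("a demand point with no facility inside d0 scores zero", {
  demand <- data.frame(point_id = c("near", "far"), population = c(50, 50))
  fac <- data.frame(facility_id = "j1", beds = 5)
  od <- manual_od(cbind(j1 = c(near = 10, far = 55)))
  p <- decay_params(d0 = 40)
  r <- supply_demand_ratios(fac, demand, od, p, "beds")
  a <- accessibility_scores(r, demand, od, p)
  expect_gt(a$A[1], 0)
  expect_equal(a$A[2], 0)
})

test_that("conservation: sum(D_i A_i) = sum(S_j) over non-empty catchments", {
  p <- decay_params(d0 = 40)
  for (seed in 1:8) {
    set.seed(seed)
    nd <- sample(5:30, 1); nf <- sample(2:6, 1)
    demand <- data.frame(point_id = sprintf("k%02d", seq_len(nd)),
                         population = rpois(nd, 200))
    fac <- data.frame(facility_id = sprintf("j%d", seq_len(nf)),
                      beds = sample(10:500, nf))
    cost <- matrix(runif(nd * nf, 0, 70), nd, nf,
                   dimnames = list(demand$point_id, fac$facility_id))
    od <- manual_od(cost)
    r <- suppressWarnings(supply_demand_ratios(fac, demand, od, p, "beds"))
    a <- accessibility_scores(r, demand, od, p)
    expect_equal(sum(demand$population * a$A),
                 sum(fac$beds[!r$empty_catchment]),
                 tolerance = 1e-9)
  }
})

test_that("A is homogeneous of degree 1 in supply; zero supply gives zero A", {
  b <- known_answer_scenario()
  res <- run_pipeline(b)
  b2 <- b
  b2$facilities$beds <- b2$facilities$beds * 2
  res2 <- run_pipeline(b2)
  expect_equal(res2$scores$A_beds, res$scores$A_beds * 2, tolerance = 1e-12)
  expect_equal(res2$scores$A_tech, res$scores$A_tech)
  b3 <- b
  b3$facilities$beds <- 0
  res3 <- suppressWarnings(run_pipeline(b3))
  expect_equal(res3$scores$A_beds, rep(0, nrow(res3$scores)))
  expect_equal(res3$scores$A_tech, res$scores$A_tech)
})

test_that("time basis uses minutes against a minute threshold", {
  demand <- data.frame(point_id = c("k1", "k2"), population = c(100, 100))
  fac <- data.frame(facility_id = "j1", beds = 10)
  minutes <- cbind(j1 = c(k1 = 0, k2 = 7.5))
  km <- cbind(j1 = c(k1 = 0, k2 = 10))
  od <- manual_od(minutes, km)
  p <- decay_params(d0 = 15, cost_basis = "time")
  r <- supply_demand_ratios(fac, demand, od, p, "beds")
  # 7.5 min on a 15-min threshold sits at the same relative depth as
  # 20 km on 40 km, so the weight is identical
  expect_equal(r$catchment_weighted_demand, 100 + 100 * 0.7013665732,
               tolerance = 1e-9)
})

test_that("shrinking d0 never grows a facility catchment", {
  set.seed(42)
  cost <- matrix(runif(200, 0, 80), 40, 5,
                 dimnames = list(sprintf("k%02d", 1:40), sprintf("j%d", 1:5)))
  for (d0s in list(c(60, 40), c(40, 20), c(20, 10))) {
    big <- colSums(cost <= d0s[1])
    small <- colSums(cost <= d0s[2])
    w_big <- gaussian_decay(cost, decay_params(d0 = d0s[1]))
    w_small <- gaussian_decay(cost, decay_params(d0 = d0s[2]))
    expect_true(all(small <= big))
    expect_true(all(colSums(w_small > 0) <= colSums(w_big > 0)))
  }
})

test_that("seed-7 province conservation holds for both supply fields", {
  b <- generate_province(province_spec(seed = 7))
  res <- run_pipeline(b)
  expect_equal(nrow(res$demand), 500)
  for (f in c("beds", "technicians")) {
    r <- res$ratios[[f]]
    short <- if (f == "technicians") "A_tech" else "A_beds"
    expect_equal(
      sum(res$demand$population * res$scores[[short]]),
      sum(b$facilities[[f]][!r$empty_catchment]),
      tolerance = 1e-9
    )
  }
})
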