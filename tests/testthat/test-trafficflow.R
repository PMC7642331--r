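classes <- default_vehicle_classes()
h0 <- default_scenarios()$H0

test_that("arrival sampling has exponential-headway statistics", {
  expect_length(sample_arrivals(0, 600), 0)
  a <- sample_arrivals(3600, 600, seed = 1)
  expect_true(all(diff(a) > 0) && all(a >= 0 & a <= 600))
  # Poisson count: 600 expected, within 3 standard deviations
  expect_lt(abs(length(a) - 600), 3 * sqrt(600))
  expect_identical(a, sample_arrivals(3600, 600, seed = 1))
})

test_that("free-speed draws are truncated normals around the class mean", {
  cl0 <- vehicle_class("x", 4, 1.8, 72, 0)
  expect_equal(sample_free_speed(cl0, 5, seed = 1), rep(20, 5))
  v <- sample_free_speed(classes$car, 10000, seed = 2)
  expect_true(all(v > 0))
  expect_lt(abs(mean(v) * 3.6 - 80) / 80, 0.01)
})

test_that("harmonic mean speed is the space-mean speed", {
  expect_equal(harmonic_mean_speed(c(10, 10, 10)), 10)
  expect_equal(harmonic_mean_speed(c(20, 5)), 8)
  set.seed(4)
  v <- runif(100, 5, 30)
  expect_lte(harmonic_mean_speed(v), mean(v))
  expect_error(harmonic_mean_speed(numeric(0)), "empty")
  expect_error(harmonic_mean_speed(c(10, -1)), "positive")
})

test_that("an empty road reproduces free-flow speeds exactly", {
  # single class, zero speed variance, far-apart vehicles: no interactions
  cl <- list(car = vehicle_class("car", 4, 1.8, 72, 0))
  sc <- traffic_scenario("only", c(car = 1))
  cfg <- sim_config(duration_s = 600, replicates = 2, seed = 3)
  fr <- simulate_flow(10, sc, cl, cfg)
  expect_gt(fr$n_vehicles_observed, 0)
  expect_equal(fr$harmonic_mean_speed_ms, 20, tolerance = 1e-6)
})

test_that("zero volume yields an empty, flagged result", {
  fr <- simulate_flow(0, h0, classes, sim_config(replicates = 1, seed = 1))
  expect_true(fr$empty)
  expect_equal(fr$n_vehicles_observed, 0)
  expect_true(is.na(fr$harmonic_mean_speed_ms))
})

test_that("the simulation is deterministic under a fixed seed", {
  cfg <- sim_config(duration_s = 300, replicates = 2, seed = 11)
  f1 <- simulate_flow(800, h0, classes, cfg)
  f2 <- simulate_flow(800, h0, classes, cfg)
  expect_identical(f1$speeds, f2$speeds)
  expect_identical(f1$per_class_free_speed_ms, f2$per_class_free_speed_ms)
})

test_that("congested single-lane flow runs without gap violations and slows down", {
  cfg <- sim_config(duration_s = 400, replicates = 2, seed = 7)
  slow <- simulate_flow(2200, h0, classes, cfg)   # internal gap assertion active
  fast <- simulate_flow(150, h0, classes, cfg)
  expect_lt(slow$harmonic_mean_speed_ms, fast$harmonic_mean_speed_ms)
})

test_that("a car-only stream outruns a MAV-only stream", {
  cfg <- sim_config(duration_s = 400, replicates = 3, seed = 5)
  sc <- default_scenarios()
  f_car <- simulate_flow(1000, sc$H1, classes, cfg)
  f_mav <- simulate_flow(1000, sc$H3, classes, cfg)
  expect_gt(f_car$harmonic_mean_speed_ms, f_mav$harmonic_mean_speed_ms)
})

test_that("two lanes per direction carry congested volumes faster than one", {
  cfg1 <- sim_config(duration_s = 400, replicates = 2, seed = 8, lanes = 1)
  cfg2 <- sim_config(duration_s = 400, replicates = 2, seed = 8, lanes = 2)
  f1 <- simulate_flow(2000, h0, classes, cfg1)
  f2 <- simulate_flow(2000, h0, classes, cfg2)
  expect_gt(f2$harmonic_mean_speed_ms, f1$harmonic_mean_speed_ms)
})

test_that("low-density mixed flow matches the class-weighted free-flow harmonic mean", {
  # enough pooled vehicles (~400) that the 2% band has power
  cfg <- sim_config(duration_s = 600, replicates = 60, seed = 13)
  fr <- simulate_flow(50, h0, classes, cfg)
  expect_lt(abs(fr$harmonic_mean_speed_ms -
                  analytic_freeflow_harmonic(classes, h0)) /
              analytic_freeflow_harmonic(classes, h0), 0.02)
})

test_that("speed-flow curves are tabulated with per-class free speeds", {
  cfg <- sim_config(duration_s = 300, replicates = 2, seed = 21)
  cur <- flow_speed_curve(c(300, 1200), h0, classes, cfg)
  expect_s3_class(cur, "flow_curve")
  expect_equal(nrow(cur), 2)
  expect_true(all(c("harmonic_speed_ms", "car_speed_ms", "mav_speed_ms",
                    "bus_truck_speed_ms", "n_observed") %in% names(cur)))
  # in mixed flow the heavy class has the lowest and cars the highest free speed
  expect_true(all(cur$mav_speed_ms < cur$bus_truck_speed_ms))
  expect_true(all(cur$car_speed_ms > cur$bus_truck_speed_ms))
  one <- flow_speed_curve(500, h0, classes, cfg)
  expect_equal(nrow(one), 1)
  expect_error(flow_speed_curve(c(500, 100), h0, classes, cfg), "ascending")
  expect_error(simulate_flow(100, traffic_scenario("bad", c(tractor = 1)),
                             classes, cfg), "unknown vehicle class")
})
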