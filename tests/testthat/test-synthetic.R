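test_that("generated hourly traffic conserves the daily total with an evening peak", {
  spec <- traffic_profile_spec(seed = 1)
  v <- gen_hourly_traffic(spec)
  expect_length(v, 24)
  expect_true(all(v >= 0) && all(v == round(v)))
  expect_equal(sum(v), 5883)
  expect_true((which.max(v) - 1) %in% 18:20)
  expect_identical(v, gen_hourly_traffic(spec))
  expect_error(traffic_profile_spec(daily_total = -5), "> 0")
  expect_error(traffic_profile_spec(peaks = list(list(centre_h = 9))), "peak")
})

test_that("hourly shares converge to the specified profile shape", {
  spec <- traffic_profile_spec(daily_total = 1e5, seed = 2)
  v <- gen_hourly_traffic(spec)
  h <- 0:23
  w <- rep(spec$baseline_weight, 24)
  for (p in spec$peaks) {
    d <- pmin(abs(h - p$centre_h) %% 24, 24 - abs(h - p$centre_h) %% 24)
    w <- w + p$weight * exp(-0.5 * (d / p$spread_h)^2)
  }
  gof <- chisq.test(v, p = w / sum(w))
  expect_gt(gof$p.value, 0.01)
})

test_that("capture generation respects counts, mixtures and exclusions", {
  spec <- activity_spec("chital", list(list(mu_h = 19, kappa = 4, weight = 1)),
                        n_captures = 802, seed = 3)
  rec <- gen_capture_records(spec)
  expect_equal(nrow(rec), 802)
  expect_true(all(rec$species == "chital"))
  hrs <- capture_hours(rec)
  expect_lt(abs(vonmises_mle(hrs)$mu_h - 19), 0.5)   # within 30 minutes
  # deterministic under the spec's seed
  expect_identical(rec, gen_capture_records(spec))
  # empty request
  expect_equal(nrow(gen_capture_records(
    activity_spec("x", list(list(mu_h = 1, kappa = 1, weight = 1)), 0))), 0)
  # excluded hours never appear
  noct <- activity_spec("gaur", list(list(mu_h = 21, kappa = 2, weight = 1)),
                        500, exclude_hours = 9:20, seed = 4)
  hrs_n <- capture_hours(gen_capture_records(noct))
  expect_false(any(floor(hrs_n) %in% 9:20))
  expect_error(activity_spec("x", list(list(mu_h = 1, kappa = 1, weight = 0.5)),
                             10), "sum to 1")
})

test_that("the default study fixture matches its declared composition", {
  fx <- default_study_fixture(seed = 7)
  expect_equal(vapply(fx$captures, nrow, 0L),
               c(chital = 802L, gaur = 34L, sambar = 21L, wild_pig = 79L))
  expect_equal(sum(fx$hourly_traffic), 5883)
  expect_equal(fx$scenarios$H0$proportions,
               c(car = 0.61, bus_truck = 0.13, mav = 0.26))
  expect_equal(nrow(fx$species), 6)
})

test_that("a written fixture round-trips through every reader", {
  fx <- default_study_fixture(seed = 8)
  dir <- withr::local_tempdir()
  write_fixture(fx, dir)
  sp <- read_species_table(file.path(dir, "species.csv"))
  expect_equal(as.data.frame(sp), as.data.frame(fx$species))
  cl <- read_vehicle_classes(file.path(dir, "vehicle_classes.csv"))
  expect_equal(cl$mav$free_speed_mean_kmh, fx$classes$mav$free_speed_mean_kmh)
  tv <- read_hourly_traffic(file.path(dir, "hourly_traffic.csv"))
  expect_equal(tv, as.numeric(fx$hourly_traffic))
  caps <- read_capture_records(file.path(dir, "captures.csv"))
  expect_equal(nrow(caps), sum(vapply(fx$captures, nrow, 0L)))
  expect_s3_class(caps$timestamp, "POSIXct")
  # and the readers validate
  expect_error(read_hourly_traffic(file.path(dir, "species.csv")), "hour")
})
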