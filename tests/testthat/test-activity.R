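test_that("hourly detection probability counts independent captures per camera-day", {
  # 48 captures spread 2 per hour at distinct stations: every rate = 2/24
  ts <- as.POSIXct("2017-07-01 00:15:00", tz = "UTC") +
    rep(0:23, each = 2) * 3600 + rep(c(0, 1200), 24)
  rec <- data.frame(station_id = rep(c("A", "B"), 24), species = "chital",
                    timestamp = ts)
  prof <- hourly_detection_prob(rec, effort_camera_days = 24)
  expect_s3_class(prof, "activity_profile")
  expect_equal(prof$hourly_rate, rep(2 / 24, 24))
  expect_error(hourly_detection_prob(rec, 0), "> 0")
})

test_that("captures within the independence window collapse to one event", {
  base <- as.POSIXct("2017-07-01 06:00:00", tz = "UTC")
  rec <- data.frame(station_id = "A", species = "sambar",
                    timestamp = base + c(0, 600, 3600))  # 0, 10 min, 60 min
  prof <- hourly_detection_prob(rec, 10)
  expect_equal(prof$n_independent, 2)
  # same times at two stations stay independent
  rec2 <- data.frame(station_id = c("A", "B"), species = "sambar",
                     timestamp = base + c(0, 600))
  expect_equal(hourly_detection_prob(rec2, 10)$n_independent, 2)
  # filter disabled keeps everything
  expect_equal(hourly_detection_prob(rec, 10, independence_min = 0)$n_independent, 3)
})

test_that("no captures give an all-zero profile", {
  empty <- data.frame(station_id = character(0), species = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"))
  prof <- hourly_detection_prob(empty, 10)
  expect_equal(prof$hourly_rate, rep(0, 24))
})

test_that("circular kernel density is a proper density on the 24-h circle", {
  d <- circular_density(rvonmises_hours(300, 13, 2, seed = 1))
  expect_equal(trapz_24(d$density), 1, tolerance = 1e-6)
  # point mass smoothed: mode at the data
  d12 <- circular_density(rep(12, 25))
  expect_equal(d12$grid$x[which.max(d12$grid$y)], 12, tolerance = 0.25)
  expect_equal(trapz_24(d12$density), 1, tolerance = 1e-6)
  # near-uniform sample: flat within 20%
  du <- circular_density(seq(0.05, 23.95, length.out = 400))
  expect_lt(max(abs(du$grid$y - 1 / 24)) / (1 / 24), 0.2)
  expect_error(circular_density(5), "at least 2")
})

test_that("overlap coefficient behaves at the extremes", {
  a <- rvonmises_hours(200, 7, 2, seed = 2)
  self <- overlap_dhat1(a, a, n_boot = 0)
  expect_gt(self$dhat1, 0.98)
  night <- rvonmises_hours(150, 2, 40, seed = 3)
  noon <- rvonmises_hours(150, 14, 40, seed = 4)
  expect_lt(overlap_dhat1(night, noon, n_boot = 0)$dhat1, 0.05)
})

test_that("overlap estimates track the true overlap of known von Mises pairs", {
  pairs <- list(c(7, 2, 19, 2), c(6, 1, 10, 3), c(0, 4, 3, 1))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    a <- rvonmises_hours(800, p[1], p[2], seed = 50 + i)
    b <- rvonmises_hours(800, p[3], p[4], seed = 60 + i)
    truth <- true_vm_overlap(p[1], p[2], p[3], p[4])
    expect_lt(abs(overlap_dhat1(a, b, n_boot = 0)$dhat1 - truth), 0.05)
  }
})

test_that("overlap is symmetric, bounded and rotation invariant", {
  a <- rvonmises_hours(120, 5, 1.5, seed = 6)
  b <- rvonmises_hours(90, 15, 2.5, seed = 7)
  d_ab <- overlap_dhat1(a, b, n_boot = 0)$dhat1
  d_ba <- overlap_dhat1(b, a, n_boot = 0)$dhat1
  expect_equal(d_ab, d_ba, tolerance = 1e-12)
  expect_gte(d_ab, 0); expect_lte(d_ab, 1)
  rot <- overlap_dhat1((a + 5) %% 24, (b + 5) %% 24, n_boot = 0)$dhat1
  expect_equal(rot, d_ab, tolerance = 0.01)
  ci <- overlap_dhat1(a, b, n_boot = 199, seed = 8)
  expect_true(ci$ci_low <= ci$dhat1 + 0.02 && ci$ci_high >= ci$dhat1 - 0.02)
})

test_that("traffic activity is a normalised piecewise-constant density", {
  td <- traffic_activity_density(rep(100, 24))
  expect_equal(td$share, rep(1 / 24, 24))
  expect_equal(trapz_24(td$density, n_grid = 24 * 50), 1, tolerance = 1e-9)
  single <- traffic_activity_density(c(50, rep(0, 23)))
  expect_equal(single$share[1], 1)
  expect_error(traffic_activity_density(rep(0, 24)), "zero")
  expect_error(traffic_activity_density(rep(10, 23)), "24")
})

test_that("hourly risk is the product of collision probability and activity", {
  rate <- c(rep(0, 6), rep(0.5, 12), rep(0, 6))
  prof <- structure(list(species = "x", hourly_rate = rate,
                         effort_camera_days = 10, n_raw = 60L,
                         n_independent = 60L), class = "activity_profile")
  ph <- seq(0.1, 0.5, length.out = 24)
  rp <- avc_risk_profile(prof, ph)
  expect_equal(rp$risk, ph * rate)
  expect_true(all(rp$risk[rate == 0] == 0))
  # linearity in activity
  prof2 <- prof; prof2$hourly_rate <- 2 * rate
  expect_equal(avc_risk_profile(prof2, ph)$risk, 2 * rp$risk)
  expect_error(avc_risk_profile(prof, ph[-1]), "24")
})

test_that("von Mises fit recovers generating parameters at moderate sample size", {
  x <- rvonmises_hours(500, 19, 4, seed = 9)
  fit <- vonmises_mle(x)
  expect_lt(abs(fit$mu_h - 19), 0.5)            # within 30 minutes
  expect_lt(abs(fit$kappa - 4) / 4, 0.2)        # within 20%
})
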