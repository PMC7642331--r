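car <- effective_vehicle(length_m = 4.0, width_m = 1.8, speed_ms = 16.667)

test_that("group length scales body length by mean group size", {
  sp <- default_species()
  gl <- group_length(sp)
  expect_equal(gl[sp$name == "chital"], 8.15 * 1.55)   # 12.6325
  expect_equal(gl[sp$name == "gaur"], 4.75 * 3.3)      # 15.675
  # solitary species: identity
  expect_equal(gl[sp$name == "tiger"], sp$body_length_m[sp$name == "tiger"])
})

test_that("coincidence time matches hand arithmetic and its limits", {
  chital <- one_species("chital", 65, 1.55, 0.6, grp = 8.15, va = 2.91)
  T_s <- coincidence_time(chital, car)
  expect_equal(T_s, (1.8 + 12.6325) / 2.91 + (4.0 + 0.6) / 16.667,
               tolerance = 1e-12)
  expect_equal(T_s, 5.2356, tolerance = 1e-4)
  # infinitely fast traffic leaves only the animal-clearance term
  fast <- effective_vehicle(4.0, 1.8, 1e12)
  expect_equal(coincidence_time(chital, fast), (1.8 + 12.6325) / 2.91,
               tolerance = 1e-9)
})

test_that("crossing success follows the Poisson-headway form", {
  expect_equal(p_success(5.236, 0), 1)
  expect_equal(p_hit(5.236, 0), 0)
  # lambda * T = ln 2 gives a coin flip
  expect_equal(p_success(log(2), 3600), 0.5)
  expect_equal(p_success(5.236, 245), exp(-245 / 3600 * 5.236))
  expect_equal(p_success(5.236, 245), 0.700, tolerance = 1e-3)
  expect_error(p_success(-1, 100), "> 0")
  expect_error(p_success(5, -10), ">= 0")
})

test_that("collision probability complements success and is monotone in its drivers", {
  set.seed(3)
  T_s <- runif(50, 0.2, 20); vol <- runif(50, 0, 3000)
  expect_equal(p_hit(T_s, vol) + p_success(T_s, vol), rep(1, 50),
               tolerance = 1e-12)
  base <- one_species("b", 100, 2, 0.5, grp = 2, va = 2.5)
  veh <- effective_vehicle(7, 2.1, 18)
  ph0 <- p_hit(coincidence_time(base, veh), 500)
  # increasing group size, vehicle length raise P_h
  bigger_grp <- one_species("b", 100, 2, 0.5, grp = 4, va = 2.5)
  expect_gt(p_hit(coincidence_time(bigger_grp, veh), 500), ph0)
  longer_veh <- effective_vehicle(14, 2.1, 18)
  expect_gt(p_hit(coincidence_time(base, longer_veh), 500), ph0)
  # faster animal or faster traffic lower P_h; more traffic raises it
  faster_animal <- one_species("b", 100, 2, 0.5, grp = 2, va = 3.5)
  expect_lt(p_hit(coincidence_time(faster_animal, veh), 500), ph0)
  faster_veh <- effective_vehicle(7, 2.1, 25)
  expect_lt(p_hit(coincidence_time(base, faster_veh), 500), ph0)
  expect_gt(p_hit(coincidence_time(base, veh), 800), ph0)
})

test_that("collision probability matches the Poisson-arrival Monte-Carlo oracle", {
  T_s <- 5
  vol <- 400
  n <- 4e4
  frac <- mc_collision_fraction(T_s, vol, n_trials = n, seed = 9)
  p <- p_hit(T_s, vol)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("threshold volume inverts the half-collision condition", {
  expect_equal(threshold_volume(log(2)), 3600)
  expect_equal(threshold_volume(5.236), 476.6, tolerance = 1e-3)
  set.seed(5)
  T_s <- runif(20, 0.3, 25)
  expect_equal(p_hit(T_s, threshold_volume(T_s)), rep(0.5, 20),
               tolerance = 1e-9)
  expect_error(threshold_volume(0), "> 0")
})

test_that("exposure scales with road width and collision probability", {
  chital <- one_species("chital", 65, 1.55, 0.6, grp = 8.15, va = 2.91)
  two <- road_geometry(2); four <- road_geometry(4)
  expect_equal(exposure_seconds(chital, two, 0), 0)
  expect_equal(exposure_seconds(chital, two, 0.5), 7 / 2.91 * 0.5,
               tolerance = 1e-12)
  # doubling lanes doubles exposure at equal P_h
  expect_equal(exposure_seconds(chital, four, 0.37) /
                 exposure_seconds(chital, two, 0.37), 2)
  expect_error(exposure_seconds(chital, two, 1.2), "\\[0, 1\\]")
})

test_that("daily profile averages 24 hourly collision probabilities", {
  sp <- default_species()
  chital <- sp[sp$name == "chital", ]
  veh <- fleet_effective_vehicle(default_vehicle_classes(),
                                 default_scenarios()$H0)
  const <- daily_avc_profile(chital, rep(245, 24), veh)
  expect_equal(const$sd, 0)
  expect_equal(length(unique(const$p_hit)), 1)
  vols <- gen_hourly_traffic(traffic_profile_spec(seed = 42))
  prof <- daily_avc_profile(chital, vols, veh)
  expect_equal(prof$mean, mean(prof$p_hit))
  expect_error(daily_avc_profile(chital, rep(100, 23), veh), "24")
  # volume-weighted option emphasises busy hours
  w <- daily_avc_profile(chital, vols, veh, weighting = "volume")
  expect_gt(w$mean, prof$mean)
})

test_that("species ordering of daily collision probability is trait-driven", {
  sp <- default_species()
  veh <- fleet_effective_vehicle(default_vehicle_classes(),
                                 default_scenarios()$H0)
  vols <- gen_hourly_traffic(traffic_profile_spec(seed = 42))
  means <- vapply(sp$name, function(nm) {
    daily_avc_profile(sp[sp$name == nm, ], vols, veh)$mean
  }, 0)
  expect_equal(names(which.max(means)), "gaur")
  expect_setequal(names(sort(means)[1:2]), c("leopard", "tiger"))
})

test_that("per-class decomposition reduces to the single-class model", {
  sp <- default_species()[1, ]
  classes <- default_vehicle_classes()
  only_car <- traffic_scenario("cars", c(car = 1))
  pa <- p_success_per_class(sp, classes, only_car, 600)
  veh <- effective_vehicle(classes$car$length_m, classes$car$width_m,
                           classes$car$free_speed_mean_kmh / 3.6)
  expect_equal(pa, p_success(coincidence_time(sp, veh), 600), tolerance = 1e-12)
})

test_that("the model object predicts, summarises and simulates consistently", {
  tr <- traversability(default_species())
  pr <- predict(tr, volume_vph = c(100, 245))
  expect_equal(nrow(pr), 12)
  expect_equal(pr$p_hit + pr$p_success, rep(1, 12), tolerance = 1e-12)
  s <- summary(tr)
  expect_equal(s$threshold_vph, 3600 * log(2) / s$T_s)
  sim <- simulate(tr, nsim = 20000, seed = 2, volume_vph = 245)
  ph <- pr$p_hit[pr$volume_vph == 245]
  emp <- colMeans(sim)
  expect_true(all(abs(emp - ph) < 3 * sqrt(ph * (1 - ph) / 20000)))
})
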