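#' Define a vehicle class
#'
#' A class of vehicles in the traffic stream: its dimensions and the normal
#' distribution of its desired (free-flow) speed.
#'
#' @param name class label, e.g. `"car"`, `"bus_truck"`, `"mav"`.
#' @param length_m,width_m vehicle dimensions in m.
#' @param free_speed_mean_kmh,free_speed_sd_kmh desired free-flow speed
#'   distribution, km/h. Draws are truncated below at half the mean.
#' @return a `vehicle_class` list.
#' @export
vehicle_class <- function(name, length_m, width_m,
                          free_speed_mean_kmh, free_speed_sd_kmh) {
  check_number(length_m, "length_m"); check_number(width_m, "width_m")
  check_number(free_speed_mean_kmh, "free_speed_mean_kmh")
  check_number(free_speed_sd_kmh, "free_speed_sd_kmh", positive = FALSE)
  if (free_speed_sd_kmh < 0) stop("free_speed_sd_kmh must be >= 0", call. = FALSE)
  structure(list(name = name, length_m = length_m, width_m = width_m,
                 free_speed_mean_kmh = free_speed_mean_kmh,
                 free_speed_sd_kmh = free_speed_sd_kmh),
            class = "vehicle_class")
}

#' Default vehicle fleet: car, bus/truck and multi-axle vehicle
#'
#' Dimensions and desired-speed distributions for the three classes that make
#' up highway traffic in the study system: car (light vehicles and LCVs
#' merged), bus/truck, and MAV (multi-axle and oversize vehicles merged).
#' Values are the package's stand-in driving parameters; all are
#' configurable via [vehicle_class()].
#'
#' @return named list of three `vehicle_class` objects.
#' @export
default_vehicle_classes <- function() {
  list(
    car = vehicle_class("car", 4.0, 1.8, 80, 10),
    bus_truck = vehicle_class("bus_truck", 10.3, 2.5, 65, 8),
    mav = vehicle_class("mav", 14.0, 2.6, 55, 6)
  )
}

#' Read a vehicle class table from CSV
#'
#' Columns: `class`, `length_m`, `width_m`, `free_speed_mean_kmh`,
#' `free_speed_sd_kmh`.
#'
#' @param path path to a CSV file.
#' @return named list of `vehicle_class` objects.
#' @export
read_vehicle_classes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("class", "length_m", "width_m", "free_speed_mean_kmh",
                "free_speed_sd_kmh")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("vehicle table '%s': missing column(s) %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    vehicle_class(df$class[i], df$length_m[i], df$width_m[i],
                  df$free_speed_mean_kmh[i], df$free_speed_sd_kmh[i])
  })
  names(out) <- df$class
  out
}

#' Define a traffic heterogeneity scenario
#'
#' A scenario is a mix of vehicle classes: the proportion of each class in
#' the traffic stream.
#'
#' @param label scenario label, e.g. `"H0"`.
#' @param proportions named numeric vector of class proportions; must be
#'   non-negative and sum to 1.
#' @return a `traffic_scenario` list.
#' @export
traffic_scenario <- function(label, proportions) {
  if (is.null(names(proportions)) || any(names(proportions) == "")) {
    stop("proportions must be a named vector (class -> fraction)", call. = FALSE)
  }
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9) {
    stop(sprintf("scenario '%s': proportions must be >= 0 and sum to 1", label),
         call. = FALSE)
  }
  structure(list(label = label, proportions = proportions),
            class = "traffic_scenario")
}

#' Default heterogeneity scenarios H0-H9
#'
#' H0 is the observed present-day mix on the study highway (61% car, 13%
#' bus/truck, 26% MAV); H1-H3 are the homogeneous single-class scenarios
#' (H3 = all MAV); H4-H9 span light- to heavy-dominated mixes. Light-vehicle
#' scenarios: H0, H1, H4, H7; heavy-vehicle scenarios: H3, H5, H6.
#'
#' @return named list of `traffic_scenario` objects.
#' @export
default_scenarios <- function() {
  mk <- function(lab, p) traffic_scenario(lab, c(car = p[1], bus_truck = p[2], mav = p[3]))
  list(
    H0 = mk("H0", c(0.61, 0.13, 0.26)),
    H1 = mk("H1", c(1, 0, 0)),
    H2 = mk("H2", c(0, 1, 0)),
    H3 = mk("H3", c(0, 0, 1)),
    H4 = mk("H4", c(0.80, 0.10, 0.10)),
    H5 = mk("H5", c(0.10, 0.20, 0.70)),
    H6 = mk("H6", c(0.10, 0.70, 0.20)),
    H7 = mk("H7", c(0.70, 0.20, 0.10)),
    H8 = mk("H8", c(0.34, 0.33, 0.33)),
    H9 = mk("H9", c(0.50, 0.25, 0.25))
  )
}

#' Effective (fleet-level) vehicle for the collision model
#'
#' @param length_m,width_m effective vehicle length \eqn{L_c} and width
#'   \eqn{W_c} in m.
#' @param speed_ms effective flow speed \eqn{V_c} in m/s.
#' @return an `effective_vehicle` list.
#' @export
effective_vehicle <- function(length_m, width_m, speed_ms) {
  check_number(length_m, "length_m"); check_number(width_m, "width_m")
  check_number(speed_ms, "speed_ms")
  structure(list(length_m = length_m, width_m = width_m, speed_ms = speed_ms),
            class = "effective_vehicle")
}

#' Fleet-level effective vehicle from a scenario mix
#'
#' Dimensions are proportion-weighted class means; the speed is either
#' supplied (typically a simulated harmonic mean flow speed from
#' [simulate_flow()]) or defaults to the proportion-weighted harmonic mean
#' of the class free-flow speed means.
#'
#' @param classes named list of [vehicle_class()] objects.
#' @param scenario a [traffic_scenario()] (or named proportion vector).
#' @param speed_ms optional effective flow speed in m/s.
#' @return an `effective_vehicle`.
#' @examples
#' fleet_effective_vehicle(default_vehicle_classes(), default_scenarios()$H0)
#' @export
fleet_effective_vehicle <- function(classes, scenario, speed_ms = NULL) {
  p <- if (inherits(scenario, "traffic_scenario")) scenario$proportions else scenario
  missing_cls <- setdiff(names(p)[p > 0], names(classes))
  if (length(missing_cls)) {
    stop(sprintf("scenario uses unknown vehicle class(es): %s",
                 paste(missing_cls, collapse = ", ")), call. = FALSE)
  }
  p <- p[p > 0]
  cls <- classes[names(p)]
  L <- sum(p * vapply(cls, `[[`, 0, "length_m"))
  W <- sum(p * vapply(cls, `[[`, 0, "width_m"))
  if (is.null(speed_ms)) {
    mu_ms <- vapply(cls, `[[`, 0, "free_speed_mean_kmh") / 3.6
    speed_ms <- 1 / sum(p / mu_ms)
  }
  effective_vehicle(L, W, speed_ms)
}

#' Road geometry
#'
#' @param lane_count total number of lanes (1-8).
#' @param lane_width_m lane width in m (default 3.5).
#' @param divided logical; whether the road has a median.
#' @return a `road_geometry` list; `$width_m` is the full crossing width.
#' @export
road_geometry <- function(lane_count, lane_width_m = 3.5, divided = lane_count >= 4) {
  if (!lane_count %in% 1:8) stop("lane_count must be an integer in 1..8", call. = FALSE)
  check_number(lane_width_m, "lane_width_m")
  structure(list(lane_count = lane_count, lane_width_m = lane_width_m,
                 divided = divided, width_m = lane_count * lane_width_m),
            class = "road_geometry")
}
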