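#' Effective crossing length of an animal group
#'
#' Group-living species cross roads in single file; collective collision risk
#' is captured by scaling body length by mean group size, treating the group
#' as one contiguous object.
#'
#' @param species a [species_traits()] table (one or more rows).
#' @return numeric vector of group lengths in m.
#' @examples
#' group_length(default_species())
#' @export
group_length <- function(species) {
  stopifnot(inherits(species, "species_traits"))
  species$mean_group_size * species$body_length_m
}

#' Animal-vehicle coincidence time
#'
#' The time window `T` (seconds) during which an animal crossing the road and
#' an arriving vehicle are in conflict: the time the animal (group) needs to
#' clear the vehicle's swept width plus the time the vehicle needs to clear
#' the animal's width,
#' \deqn{T = \frac{W_c + L_{group}}{V_a} + \frac{L_c + W_a}{V_c}.}
#'
#' @param species a [species_traits()] table.
#' @param vehicle an [effective_vehicle()].
#' @return numeric vector of coincidence times in seconds, one per species.
#' @export
coincidence_time <- function(species, vehicle) {
  stopifnot(inherits(species, "species_traits"),
            inherits(vehicle, "effective_vehicle"))
  check_number(species$traverse_speed_ms, "traverse_speed_ms")
  check_number(vehicle$speed_ms, "vehicle speed_ms")
  (vehicle$width_m + group_length(species)) / species$traverse_speed_ms +
    (vehicle$length_m + species$body_width_m) / vehicle$speed_ms
}

#' Probability of successful crossing
#'
#' With vehicle headways following a Poisson process at rate
#' \eqn{\lambda} (vehicles per second), a crossing succeeds when no vehicle
#' arrives during the coincidence window: \eqn{P_a = e^{-\lambda T}}. The
#' model is "blind": neither driver braking nor animal evasion.
#'
#' @param T_s coincidence time in seconds (> 0).
#' @param volume_vph hourly traffic volume (>= 0); converted internally to a
#'   per-second rate.
#' @return probability in \[0, 1\]. Vectorised over both arguments.
#' @export
p_success <- function(T_s, volume_vph) {
  check_number(T_s, "T_s")
  if (!is.numeric(volume_vph) || anyNA(volume_vph) || any(volume_vph < 0)) {
    stop("'volume_vph' must be numeric and >= 0", call. = FALSE)
  }
  exp(-(volume_vph / 3600) * T_s)
}

#' Probability of animal-vehicle collision (probability of hit)
#'
#' The complement of [p_success()]: \eqn{P_h = 1 - e^{-\lambda T}}.
#'
#' @inheritParams p_success
#' @return probability in \[0, 1\].
#' @export
p_hit <- function(T_s, volume_vph) {
  1 - p_success(T_s, volume_vph)
}

#' Per-class decomposition of crossing success
#'
#' Alternative to the fleet-level effective vehicle: each class k arrives as
#' an independent Poisson stream at rate \eqn{\lambda_k} with its own
#' coincidence time, and \eqn{P_a = \prod_k e^{-\lambda_k T_k}}. Reduces to
#' [p_success()] when only one class is present.
#'
#' @param species a single-row [species_traits()] table.
#' @param classes named list of [vehicle_class()] objects.
#' @param scenario a [traffic_scenario()] (or named proportions).
#' @param volume_vph total hourly volume split across classes by proportion.
#' @param speeds_ms optional named per-class speeds in m/s; defaults to the
#'   class free-flow speed means.
#' @return probability of successful crossing.
#' @export
p_success_per_class <- function(species, classes, scenario, volume_vph,
                                speeds_ms = NULL) {
  stopifnot(inherits(species, "species_traits"), nrow(species) == 1)
  p <- if (inherits(scenario, "traffic_scenario")) scenario$proportions else scenario
  p <- p[p > 0]
  if (is.null(speeds_ms)) {
    speeds_ms <- vapply(classes[names(p)], `[[`, 0, "free_speed_mean_kmh") / 3.6
  }
  log_pa <- 0
  for (k in names(p)) {
    veh <- effective_vehicle(classes[[k]]$length_m, classes[[k]]$width_m,
                             speeds_ms[[k]])
    Tk <- coincidence_time(species, veh)
    log_pa <- log_pa - (p[[k]] * volume_vph / 3600) * Tk
  }
  unname(exp(log_pa))
}

#' Threshold (barrier) traffic volume
#'
#' The hourly volume at which collision and successful crossing are equally
#' likely (\eqn{P_h = 0.5}): \eqn{3600 \ln 2 / T}. Above it the road acts as
#' a partial barrier and most crossing attempts fail.
#'
#' @param T_s coincidence time in seconds (> 0). Vectorised.
#' @return threshold volume in vehicles/hour.
#' @export
threshold_volume <- function(T_s) {
  check_number(T_s, "T_s")
  3600 * log(2) / T_s
}

#' Collision exposure while crossing
#'
#' Seconds of an attempted crossing spent at risk of collision: the time to
#' traverse the full road width at the species' crossing speed, weighted by
#' the collision probability at the prevailing volume.
#'
#' @param species a [species_traits()] table.
#' @param road a [road_geometry()].
#' @param p_hit_value collision probability in \[0, 1\] (vectorised).
#' @return exposure in seconds.
#' @export
exposure_seconds <- function(species, road, p_hit_value) {
  stopifnot(inherits(species, "species_traits"), inherits(road, "road_geometry"))
  if (any(p_hit_value < 0 | p_hit_value > 1, na.rm = TRUE)) {
    stop("'p_hit_value' must lie in [0, 1]", call. = FALSE)
  }
  crossing_duration <- road$width_m / species$traverse_speed_ms
  crossing_duration * p_hit_value
}

#' Daily collision-probability profile
#'
#' Hourly collision probabilities over a 24-hour traffic-volume profile,
#' with the unweighted mean and standard deviation of the 24 hourly values
#' (optionally a volume-weighted mean).
#'
#' @param species a single-row [species_traits()] table.
#' @param hourly_volumes numeric vector of 24 non-negative hourly volumes
#'   (hours 0-23).
#' @param vehicle an [effective_vehicle()], a list of 24 of them (one per
#'   hour), or a function `function(volume_vph)` returning one (e.g. built
#'   from a simulated speed-flow curve).
#' @param weighting `"unweighted"` (default) or `"volume"` for the summary
#'   mean.
#' @return a list with `hour`, `volume_vph`, `p_hit` (length 24), `mean`,
#'   `sd`, of class `daily_profile`.
#' @export
daily_avc_profile <- function(species, hourly_volumes, vehicle,
                              weighting = c("unweighted", "volume")) {
  stopifnot(inherits(species, "species_traits"), nrow(species) == 1)
  weighting <- match.arg(weighting)
  if (length(hourly_volumes) != 24 || any(hourly_volumes < 0)) {
    stop("'hourly_volumes' must be 24 non-negative values", call. = FALSE)
  }
  veh_at <- hourly_vehicle_fun(vehicle)
  ph <- vapply(seq_len(24), function(h) {
    v <- veh_at(h, hourly_volumes[h])
    p_hit(coincidence_time(species, v), hourly_volumes[h])
  }, 0)
  mu <- if (weighting == "volume" && sum(hourly_volumes) > 0) {
    sum(ph * hourly_volumes) / sum(hourly_volumes)
  } else {
    mean(ph)
  }
  structure(list(species = species$name, hour = 0:23,
                 volume_vph = hourly_volumes, p_hit = ph,
                 mean = mu, sd = sd(ph), weighting = weighting),
            class = "daily_profile")
}

hourly_vehicle_fun <- function(vehicle) {
  if (inherits(vehicle, "effective_vehicle")) {
    function(h, vol) vehicle
  } else if (is.function(vehicle)) {
    function(h, vol) vehicle(vol)
  } else if (is.list(vehicle) && length(vehicle) == 24) {
    function(h, vol) vehicle[[h]]
  } else {
    stop("'vehicle' must be an effective_vehicle, a list of 24, or a function(volume)",
         call. = FALSE)
  }
}

#' @export
print.daily_profile <- function(x, ...) {
  cat(sprintf("Daily AVC profile for %s: mean P_h = %.3f +/- %.3f (%s)\n",
              x$species, x$mean, x$sd, x$weighting))
  invisible(x)
}
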