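#' Traversability model for a species set on a road
#'
#' Binds species traits, a vehicle fleet mix and road geometry into a single
#' model object. The model treats vehicle headways as a Poisson process, so
#' for each species the collision probability at hourly volume \eqn{v} is
#' \eqn{P_h = 1 - e^{-(v/3600)\,T}} with `T` the coincidence time. Methods:
#' [predict.traversability()] evaluates \eqn{P_h}, crossing success and
#' exposure over traffic volumes; `summary()` reports coincidence times and
#' threshold (barrier) volumes; `plot()` draws the \eqn{P_h}-volume curves;
#' `simulate()` draws crossing outcomes from the fitted Poisson-arrival
#' process.
#'
#' @param species a [species_traits()] table.
#' @param classes named list of [vehicle_class()] objects.
#' @param scenario a [traffic_scenario()]; defaults to the present-day mix H0.
#' @param road a [road_geometry()]; default 2-lane, 3.5 m lanes.
#' @param speed a flow-speed source for the effective vehicle speed
#'   \eqn{V_c}: `NULL` (free-flow harmonic mean of the class speed means), a
#'   single speed in m/s, a `flow_curve` from [flow_speed_curve()]
#'   (interpolated by volume), or a `function(volume_vph)` returning m/s.
#' @return an object of class `traversability`.
#' @examples
#' tr <- traversability(default_species())
#' predict(tr, volume_vph = c(100, 245, 1000))
#' summary(tr)
#' @export
traversability <- function(species, classes = default_vehicle_classes(),
                           scenario = default_scenarios()$H0,
                           road = road_geometry(2), speed = NULL) {
  stopifnot(inherits(species, "species_traits"), inherits(road, "road_geometry"))
  speed_fun <- make_speed_fun(speed, classes, scenario)
  obj <- structure(list(species = species, classes = classes,
                        scenario = scenario, road = road,
                        speed_fun = speed_fun, call = match.call()),
                   class = "traversability")
  obj
}

make_speed_fun <- function(speed, classes, scenario) {
  free <- fleet_effective_vehicle(classes, scenario)$speed_ms
  if (is.null(speed)) {
    function(vol) free
  } else if (inherits(speed, "flow_curve")) {
    ok <- is.finite(speed$harmonic_speed_ms)
    if (sum(ok) < 2) stop("flow curve has fewer than 2 usable volumes", call. = FALSE)
    f <- approxfun(speed$volume_vph[ok], speed$harmonic_speed_ms[ok], rule = 2)
    function(vol) f(vol)
  } else if (is.function(speed)) {
    speed
  } else if (is.numeric(speed) && length(speed) == 1) {
    function(vol) speed
  } else {
    stop("'speed' must be NULL, a number, a flow_curve or a function", call. = FALSE)
  }
}

vehicle_at_volume <- function(object, volume_vph) {
  fleet_effective_vehicle(object$classes, object$scenario,
                          speed_ms = object$speed_fun(volume_vph))
}

#' Predict collision probabilities over traffic volumes
#'
#' @param object a [traversability()] model.
#' @param volume_vph numeric vector of hourly traffic volumes.
#' @param ... unused.
#' @return a long data frame: `species`, `volume_vph`, `T_s`, `p_success`,
#'   `p_hit`, `exposure_s`.
#' @export
predict.traversability <- function(object, volume_vph = seq(100, 2400, by = 100),
                                   ...) {
  out <- do.call(rbind, lapply(volume_vph, function(v) {
    veh <- vehicle_at_volume(object, v)
    T_s <- coincidence_time(object$species, veh)
    ph <- p_hit(T_s, v)
    data.frame(species = object$species$name, volume_vph = v, T_s = T_s,
               p_success = 1 - ph, p_hit = ph,
               exposure_s = exposure_seconds(object$species, object$road, ph),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.traversability <- function(x, ...) {
  cat("Traversability model\n")
  cat(sprintf("  species: %s\n", paste(x$species$name, collapse = ", ")))
  cat(sprintf("  scenario: %s (%s)\n", x$scenario$label,
              paste(sprintf("%s %.0f%%", names(x$scenario$proportions),
                            100 * x$scenario$proportions), collapse = ", ")))
  cat(sprintf("  road: %d x %.1f m lanes (%.1f m crossing width)\n",
              x$road$lane_count, x$road$lane_width_m, x$road$width_m))
  invisible(x)
}

#' Summarise a traversability model
#'
#' Coincidence time, collision probability at a reference volume, and the
#' threshold (barrier) volume for each species.
#'
#' @param object a [traversability()] model.
#' @param ref_volume_vph reference hourly volume (default 245, a typical
#'   protected-area highway load).
#' @param ... unused.
#' @return a `summary.traversability` data frame.
#' @export
summary.traversability <- function(object, ref_volume_vph = 245, ...) {
  veh <- vehicle_at_volume(object, ref_volume_vph)
  T_s <- coincidence_time(object$species, veh)
  out <- data.frame(
    species = object$species$name,
    group_length_m = group_length(object$species),
    T_s = T_s,
    p_hit_ref = p_hit(T_s, ref_volume_vph),
    threshold_vph = threshold_volume(T_s),
    stringsAsFactors = FALSE
  )
  attr(out, "ref_volume_vph") <- ref_volume_vph
  class(out) <- c("summary.traversability", "data.frame")
  out
}

#' @export
print.summary.traversability <- function(x, ...) {
  cat(sprintf("Traversability summary (reference volume %g veh/h)\n",
              attr(x, "ref_volume_vph")))
  y <- as.data.frame(x)
  y$group_length_m <- round(y$group_length_m, 2)
  y$T_s <- round(y$T_s, 2)
  y$p_hit_ref <- round(y$p_hit_ref, 3)
  y$threshold_vph <- round(y$threshold_vph)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Plot collision-probability curves against traffic volume
#'
#' @param x a [traversability()] model.
#' @param volume_vph volume grid for the x-axis.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the predicted data frame.
#' @export
plot.traversability <- function(x, volume_vph = seq(100, 2400, by = 50), ...) {
  pr <- predict(x, volume_vph)
  wide <- do.call(cbind, lapply(split(pr$p_hit, pr$species), identity))
  matplot(volume_vph, wide[, unique(pr$species), drop = FALSE], type = "l",
          lty = 1, xlab = "traffic volume (veh/h)",
          ylab = expression(P[h]), ylim = c(0, 1), ...)
  legend("bottomright", legend = unique(pr$species), lty = 1,
         col = seq_along(unique(pr$species)), bty = "n", cex = 0.8)
  invisible(pr)
}

#' Simulate crossing outcomes from the fitted Poisson-arrival process
#'
#' Draws, for each species, `nsim` independent crossing attempts at the
#' given volume: the number of vehicle arrivals during the coincidence
#' window is Poisson(\eqn{\lambda T}) and the attempt fails when at least
#' one vehicle arrives.
#'
#' @param object a [traversability()] model.
#' @param nsim number of crossing attempts per species.
#' @param seed optional RNG seed.
#' @param volume_vph hourly traffic volume.
#' @param ... unused.
#' @return a logical matrix (`nsim` rows, one column per species): `TRUE`
#'   when the attempt ends in a collision.
#' @export
simulate.traversability <- function(object, nsim = 1000, seed = NULL,
                                    volume_vph = 245, ...) {
  veh <- vehicle_at_volume(object, volume_vph)
  T_s <- coincidence_time(object$species, veh)
  lam <- volume_vph / 3600
  with_seed(seed, {
    hits <- vapply(T_s, function(Ti) stats::rpois(nsim, lam * Ti) > 0,
                   logical(nsim))
    if (!is.matrix(hits)) hits <- matrix(hits, nrow = nsim)
    colnames(hits) <- object$species$name
    hits
  })
}
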