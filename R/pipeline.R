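#' Tabulate species speeds
#'
#' Computes allometric maximum running speeds and traversing speeds for a
#' species table, with both full-precision and display (truncated to 2
#' decimals) columns.
#'
#' @param species a [species_traits()] table or path to a species CSV.
#' @param out_csv optional path; when given the table is written as a
#'   headered CSV.
#' @return data frame: `name`, `mass_kg`, `vmax_ms`, `traverse_speed_ms`,
#'   `vmax_ms_display`, `traverse_speed_ms_display`.
#' @export
run_speeds <- function(species, out_csv = NULL) {
  if (is.character(species)) species <- read_species_table(species)
  stopifnot(inherits(species, "species_traits"))
  out <- data.frame(
    name = species$name, mass_kg = species$mass_kg,
    vmax_ms = species$vmax_ms, traverse_speed_ms = species$traverse_speed_ms,
    vmax_ms_display = trunc_dec(species$vmax_ms, 2),
    traverse_speed_ms_display = trunc_dec(species$traverse_speed_ms, 2),
    stringsAsFactors = FALSE
  )
  if (!is.null(out_csv)) write_output_csv(out, out_csv)
  out
}

#' Collision risk over volumes, scenarios and lane types
#'
#' Runs the collision model for every species x scenario x road
#' combination over a volume grid: collision probability, threshold
#' (barrier) volume, and crossing exposure. Flow speeds come either from
#' the free-flow fleet mix (`sim` = `NULL`) or from the traffic
#' microsimulation (a [sim_config()]; its `lanes` field is overridden per
#' road: 1 lane per direction for roads up to 3 lanes, 2 above).
#'
#' @param species a [species_traits()] table.
#' @param classes named list of [vehicle_class()] objects.
#' @param scenarios list of [traffic_scenario()] objects.
#' @param roads list of [road_geometry()] objects.
#' @param volumes hourly-volume grid.
#' @param sim `NULL` for free-flow speeds, or a [sim_config()] to simulate
#'   a speed-flow curve per scenario and road.
#' @param out_csv optional output CSV path.
#' @return long data frame: `species`, `scenario`, `lanes`, `volume_vph`,
#'   `T_s`, `p_success`, `p_hit`, `exposure_s`, `threshold_vph`.
#' @export
run_risk <- function(species, classes = default_vehicle_classes(),
                     scenarios = default_scenarios()["H0"],
                     roads = list(road_geometry(2), road_geometry(4)),
                     volumes = seq(100, 2400, by = 100), sim = NULL,
                     out_csv = NULL) {
  stopifnot(inherits(species, "species_traits"))
  if (any(volumes < 0 | volumes > 10000)) {
    stop("volume grid must lie within [0, 10000] veh/h", call. = FALSE)
  }
  rows <- list()
  for (sc in scenarios) {
    for (road in roads) {
      speed <- NULL
      if (!is.null(sim)) {
        cfg <- sim
        cfg$lanes <- if (road$lane_count > 3) 2L else 1L
        speed <- flow_speed_curve(sort(unique(volumes)), sc, classes, cfg)
      }
      tr <- traversability(species, classes, sc, road, speed = speed)
      pr <- predict(tr, volumes)
      pr$scenario <- sc$label
      pr$lanes <- road$lane_count
      pr$threshold_vph <- threshold_volume(pr$T_s)
      rows[[length(rows) + 1L]] <- pr
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("species", "scenario", "lanes", "volume_vph", "T_s",
                 "p_success", "p_hit", "exposure_s", "threshold_vph")]
  rownames(out) <- NULL
  if (!is.null(out_csv)) write_output_csv(out, out_csv, seed = sim$seed)
  out
}

#' Activity-weighted hourly collision risk per species
#'
#' Binds the hourly traffic profile, per-hour collision probabilities and
#' camera-trap activity into the hourly risk table for each species present
#' in the capture records, plus the activity-traffic overlap coefficient
#' Dhat1. Species in `species` without capture records are skipped with a
#' warning.
#'
#' @param captures capture-record data frame (`station_id`, `species`,
#'   `timestamp`) or named list of per-species data frames.
#' @param effort_camera_days sampling effort in camera-days.
#' @param hourly_volumes 24 hourly traffic volumes.
#' @param species a [species_traits()] table.
#' @param classes,scenario fleet definition for the collision model.
#' @param road a [road_geometry()].
#' @param speed flow-speed source, as in [traversability()].
#' @param n_boot bootstrap resamples for the overlap CIs.
#' @param seed optional RNG seed for the bootstrap.
#' @param out_csv optional output CSV path for the risk table.
#' @return list with `risk` (long data frame: `species`, `hour`,
#'   `volume_vph`, `p_hit`, `activity_rate`, `risk`) and `overlap` (data
#'   frame: `species`, `dhat1`, `ci_low`, `ci_high`).
#' @export
run_activity_risk <- function(captures, effort_camera_days, hourly_volumes,
                              species = default_species(),
                              classes = default_vehicle_classes(),
                              scenario = default_scenarios()$H0,
                              road = road_geometry(2), speed = NULL,
                              n_boot = 999, seed = NULL, out_csv = NULL) {
  stopifnot(inherits(species, "species_traits"))
  if (is.list(captures) && !is.data.frame(captures)) {
    captures <- do.call(rbind, captures)
  }
  profiles <- hourly_detection_prob(captures, effort_camera_days)
  if (inherits(profiles, "activity_profile")) {
    profiles <- setNames(list(profiles), profiles$species)
  }
  missing_sp <- setdiff(species$name, names(profiles))
  if (length(missing_sp)) {
    warning(sprintf("no capture records for: %s; skipped",
                    paste(missing_sp, collapse = ", ")))
  }
  traffic_dens <- traffic_activity_density(hourly_volumes)
  risk_rows <- list(); ov_rows <- list()
  for (sp in intersect(species$name, names(profiles))) {
    sp_row <- species[species$name == sp, ]
    prof <- profiles[[sp]]
    daily <- daily_avc_profile(sp_row, hourly_volumes,
                               vehicle_fun_for(classes, scenario, speed))
    rp <- avc_risk_profile(prof, daily$p_hit)
    rp$species <- sp
    rp$volume_vph <- hourly_volumes
    risk_rows[[sp]] <- as.data.frame(rp)[, c("species", "hour", "volume_vph",
                                             "p_hit", "activity_rate", "risk")]
    hrs <- capture_hours(captures[captures$species == sp, , drop = FALSE])
    ov <- overlap_dhat1(hrs, traffic_dens, n_boot = n_boot, seed = seed)
    ov_rows[[sp]] <- data.frame(species = sp, dhat1 = ov$dhat1,
                                ci_low = ov$ci_low, ci_high = ov$ci_high)
  }
  risk <- do.call(rbind, risk_rows); rownames(risk) <- NULL
  overlap <- do.call(rbind, ov_rows); rownames(overlap) <- NULL
  if (!is.null(out_csv)) write_output_csv(risk, out_csv, seed = seed)
  list(risk = risk, overlap = overlap)
}

vehicle_fun_for <- function(classes, scenario, speed) {
  speed_fun <- make_speed_fun(speed, classes, scenario)
  function(vol) fleet_effective_vehicle(classes, scenario, speed_fun(vol))
}

#' Hour-of-day values from capture records
#'
#' @param records capture-record data frame with a `timestamp` column.
#' @return numeric hours in `[0, 24)` (fractional).
#' @export
capture_hours <- function(records) {
  ts <- records$timestamp
  if (!inherits(ts, "POSIXct")) {
    ts <- as.POSIXct(ts, tz = "UTC", tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                    "%Y-%m-%d %H:%M:%S"))
  }
  lt <- as.POSIXlt(ts)
  lt$hour + lt$min / 60 + lt$sec / 3600
}
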