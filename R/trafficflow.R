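#' Traffic simulation configuration
#'
#' Settings for the single-link microsimulation: a 1 km link, 10 time steps
#' per second, 10-minute runs with 20 replicates, and a warm-up period
#' excluded from detector statistics so speeds are measured on a loaded
#' road. The car-following rule is a bounded safe-headway law: a vehicle
#' travels at its desired speed unless the gap to its leader forces
#' `speed <= (gap - min_gap) / reaction_headway`.
#'
#' @param link_length_m simulated link length (m).
#' @param duration_s simulated time per replicate (s).
#' @param replicates number of independent replicates pooled per volume.
#' @param timestep_s simulation resolution (s); must be <= 1.
#' @param lanes lanes per simulated direction: 1 (2-lane road, no
#'   overtaking) or 2 (4-lane divided road, free lane selection).
#' @param warmup_s initial seconds excluded from detector statistics.
#' @param min_gap_m minimum bumper-to-bumper gap (m).
#' @param reaction_headway_s time headway kept behind the leader (s).
#' @param seed RNG seed for reproducibility.
#' @return a `sim_config` list.
#' @export
sim_config <- function(link_length_m = 1000, duration_s = 600, replicates = 20,
                       timestep_s = 0.1, lanes = 1, warmup_s = 120,
                       min_gap_m = 2, reaction_headway_s = 1, seed = NULL) {
  check_number(c(link_length_m, duration_s, replicates, timestep_s,
                 min_gap_m, reaction_headway_s), "sim_config values")
  if (timestep_s > 1) stop("timestep_s must be <= 1 s", call. = FALSE)
  if (!lanes %in% 1:2) stop("lanes must be 1 or 2 (per direction)", call. = FALSE)
  if (warmup_s < 0 || warmup_s >= duration_s) {
    stop("warmup_s must lie in [0, duration_s)", call. = FALSE)
  }
  structure(list(link_length_m = link_length_m, duration_s = duration_s,
                 replicates = as.integer(replicates), timestep_s = timestep_s,
                 lanes = as.integer(lanes), warmup_s = warmup_s,
                 min_gap_m = min_gap_m, reaction_headway_s = reaction_headway_s,
                 seed = seed),
            class = "sim_config")
}

#' Sample vehicle arrival times
#'
#' Headways are negative-exponential (Poisson arrivals): i.i.d. exponential
#' gaps with mean `3600 / volume_vph` seconds.
#'
#' @param volume_vph hourly volume (>= 0); 0 gives no arrivals.
#' @param duration_s length of the arrival window (s).
#' @param seed optional RNG seed.
#' @return increasing vector of arrival times in `[0, duration_s]`.
#' @export
sample_arrivals <- function(volume_vph, duration_s, seed = NULL) {
  if (volume_vph < 0) stop("'volume_vph' must be >= 0", call. = FALSE)
  if (volume_vph == 0) return(numeric(0))
  with_seed(seed, {
    rate <- volume_vph / 3600
    n_guess <- ceiling(duration_s * rate + 6 * sqrt(duration_s * rate) + 10)
    times <- cumsum(rexp(n_guess, rate))
    while (length(times) && times[length(times)] < duration_s) {
      times <- c(times, times[length(times)] + cumsum(rexp(n_guess, rate)))
    }
    times[times <= duration_s]
  })
}

#' Sample desired free-flow speeds for a vehicle class
#'
#' Normal in km/h, truncated below at half the class mean (re-drawn), and
#' returned in m/s.
#'
#' @param cls a [vehicle_class()].
#' @param n number of draws.
#' @param seed optional RNG seed.
#' @return speeds in m/s.
#' @export
sample_free_speed <- function(cls, n = 1, seed = NULL) {
  stopifnot(inherits(cls, "vehicle_class"))
  with_seed(seed, {
    v <- rnorm(n, cls$free_speed_mean_kmh, cls$free_speed_sd_kmh)
    lo <- 0.5 * cls$free_speed_mean_kmh
    while (any(bad <- v < lo)) {
      v[bad] <- rnorm(sum(bad), cls$free_speed_mean_kmh, cls$free_speed_sd_kmh)
    }
    v / 3.6
  })
}

#' Harmonic mean speed
#'
#' The space-mean speed `n / sum(1/v)` over vehicles passing a detector;
#' always at most the arithmetic mean.
#'
#' @param speeds positive speeds (m/s); must be non-empty.
#' @return harmonic mean in m/s.
#' @export
harmonic_mean_speed <- function(speeds) {
  if (length(speeds) == 0) stop("'speeds' is empty", call. = FALSE)
  if (any(!is.finite(speeds) | speeds <= 0)) {
    stop("'speeds' must all be positive and finite", call. = FALSE)
  }
  length(speeds) / sum(1 / speeds)
}

# One replicate of the link simulation. Returns detector records.
run_replicate <- function(volume_vph, scenario, classes, config) {
  arr <- sample_arrivals(volume_vph, config$duration_s)
  n <- length(arr)
  if (n == 0) {
    return(list(speed = numeric(0), class = character(0), desired = numeric(0)))
  }
  p <- scenario$proportions
  unknown <- setdiff(names(p)[p > 0], names(classes))
  if (length(unknown)) {
    stop(sprintf("scenario '%s' uses unknown vehicle class(es): %s",
                 scenario$label, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cls_id <- sample(names(p), n, replace = TRUE, prob = p)
  desired <- numeric(n)
  for (k in unique(cls_id)) {
    desired[cls_id == k] <- sample_free_speed(classes[[k]], sum(cls_id == k))
  }
  len <- vapply(classes[cls_id], `[[`, 0, "length_m")

  dt <- config$timestep_s
  tau <- config$reaction_headway_s
  min_gap <- config$min_gap_m
  det_x <- config$link_length_m / 2
  lanes <- config$lanes

  pos <- rep(NA_real_, n)      # front-bumper position
  spd <- rep(0, n)
  lane <- rep(1L, n)
  state <- rep(0L, n)          # 0 pending, 1 active, 2 finished
  next_pending <- 1L

  det_speed <- numeric(0); det_class <- character(0); det_desired <- numeric(0)

  steps <- ceiling(config$duration_s / dt)
  for (s in seq_len(steps)) {
    t <- s * dt

    # --- entries: admit pending vehicles whose arrival time has come and
    #     whose entry lane has clearance at x = 0
    while (next_pending <= n && arr[next_pending] <= t &&
           state[next_pending] == 0L) {
      i <- next_pending
      rear_gap <- function(l) {
        ids <- which(state == 1L & lane == l)
        if (!length(ids)) return(Inf)
        j <- ids[which.min(pos[ids])]
        pos[j] - len[j]                       # rear of rearmost vehicle
      }
      if (lanes == 2L) {
        g1 <- rear_gap(1L); g2 <- rear_gap(2L)
        tgt <- if (g2 > g1) 2L else 1L
        g <- max(g1, g2)
      } else {
        tgt <- 1L
        g <- rear_gap(1L)
      }
      if (g < min_gap) break                  # blocked; retry next step
      lane[i] <- tgt
      pos[i] <- 0
      spd[i] <- max(0, min(desired[i], (g - min_gap) / tau))
      state[i] <- 1L
      next_pending <- next_pending + 1L
    }

    act <- which(state == 1L)
    if (!length(act)) next

    # --- lane changes (free lane selection on the divided road)
    if (lanes == 2L && length(act) > 1) {
      for (l in 1:2) {
        ids <- act[lane[act] == l]
        if (length(ids) < 1) next
        ord <- ids[order(pos[ids], decreasing = TRUE)]
        if (length(ord) < 2) next
        other <- 3L - l
        oth_ids <- act[lane[act] == other]
        for (r in 2:length(ord)) {            # leaders never need to change
          i <- ord[r]
          ldr <- ord[r - 1]
          if (spd[ldr] >= desired[i] - 2) next
          if (length(oth_ids)) {
            ahead <- oth_ids[pos[oth_ids] > pos[i]]
            behind <- oth_ids[pos[oth_ids] <= pos[i]]
            fore_gap <- if (length(ahead)) {
              j <- ahead[which.min(pos[ahead])]
              (pos[j] - len[j]) - pos[i]
            } else Inf
            aft_gap <- if (length(behind)) {
              j <- behind[which.max(pos[behind])]
              (pos[i] - len[i]) - pos[j]
            } else Inf
            tgt_ldr_spd <- if (length(ahead)) {
              spd[ahead[which.min(pos[ahead])]]
            } else Inf
          } else {
            fore_gap <- Inf; aft_gap <- Inf; tgt_ldr_spd <- Inf
          }
          if (fore_gap >= 1.5 * min_gap && aft_gap >= 1.5 * min_gap &&
              tgt_ldr_spd > spd[ldr] + 0.5) {
            lane[i] <- other
            oth_ids <- act[lane[act] == other]
          }
        }
      }
    }

    # --- car-following speed update and move, lane by lane
    old_pos <- pos
    for (l in seq_len(lanes)) {
      ids <- act[lane[act] == l]
      if (!length(ids)) next
      ord <- ids[order(pos[ids], decreasing = TRUE)]
      gap <- c(Inf, pos[ord[-length(ord)]] - len[ord[-length(ord)]]) -
        c(0, pos[ord[-1]])
      gap[1] <- Inf
      v <- pmin(desired[ord], pmax(0, (gap - min_gap) / tau))
      spd[ord] <- v
      pos[ord] <- pos[ord] + v * dt
      # followers may not close below the minimum gap
      if (length(ord) > 1) {
        new_gap <- (pos[ord[-length(ord)]] - len[ord[-length(ord)]]) -
          pos[ord[-1]]
        if (any(new_gap < min_gap - 1e-9)) {
          stop("internal error: minimum gap violated in simulation", call. = FALSE)
        }
      }
    }

    # --- mid-link detector
    if (t >= config$warmup_s) {
      crossed <- act[old_pos[act] < det_x & pos[act] >= det_x]
      if (length(crossed)) {
        det_speed <- c(det_speed, spd[crossed])
        det_class <- c(det_class, cls_id[crossed])
        det_desired <- c(det_desired, desired[crossed])
      }
    }

    state[act[pos[act] >= config$link_length_m]] <- 2L
  }

  list(speed = det_speed, class = det_class, desired = det_desired)
}

#' Simulate heterogeneous traffic flow on a link
#'
#' Runs the microsimulation at one hourly volume: Poisson arrivals, class
#' mix drawn from the scenario proportions, normal desired speeds, bounded
#' safe-headway car following (no overtaking on the undivided road; free
#' lane selection with 2 lanes per direction), and a mid-link detector
#' recording each vehicle's instantaneous speed. All replicates are pooled.
#'
#' @param volume_vph hourly traffic volume fed to the link.
#' @param scenario a [traffic_scenario()].
#' @param classes named list of [vehicle_class()] objects.
#' @param config a [sim_config()].
#' @return a `flow_result`: `volume_vph`, `harmonic_mean_speed_ms`,
#'   `arithmetic_mean_speed_ms`, `per_class_free_speed_ms`,
#'   `n_vehicles_observed`, and the pooled detector `speeds`. With no
#'   observed vehicles the speed fields are `NA` and `empty` is `TRUE`.
#' @examples
#' cfg <- sim_config(duration_s = 200, replicates = 2, seed = 1)
#' simulate_flow(300, default_scenarios()$H0, default_vehicle_classes(), cfg)
#' @export
simulate_flow <- function(volume_vph, scenario = default_scenarios()$H0,
                          classes = default_vehicle_classes(),
                          config = sim_config()) {
  stopifnot(inherits(scenario, "traffic_scenario"), inherits(config, "sim_config"))
  reps <- with_seed(config$seed, {
    lapply(seq_len(config$replicates), function(r) {
      run_replicate(volume_vph, scenario, classes, config)
    })
  })
  speed <- unlist(lapply(reps, `[[`, "speed"))
  cls <- unlist(lapply(reps, `[[`, "class"))
  des <- unlist(lapply(reps, `[[`, "desired"))
  n_obs <- length(speed)
  per_class <- vapply(names(classes), function(k) {
    if (any(cls == k)) mean(des[cls == k]) else NA_real_
  }, 0)
  structure(list(
    volume_vph = volume_vph,
    scenario = scenario$label,
    harmonic_mean_speed_ms = if (n_obs) harmonic_mean_speed(speed) else NA_real_,
    arithmetic_mean_speed_ms = if (n_obs) mean(speed) else NA_real_,
    per_class_free_speed_ms = per_class,
    n_vehicles_observed = n_obs,
    speeds = speed,
    empty = n_obs == 0
  ), class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("Flow result [%s] at %g veh/h: no vehicles observed\n",
                x$scenario, x$volume_vph))
  } else {
    cat(sprintf("Flow result [%s] at %g veh/h: harmonic speed %.2f m/s (n = %d)\n",
                x$scenario, x$volume_vph, x$harmonic_mean_speed_ms,
                x$n_vehicles_observed))
  }
  invisible(x)
}

#' Speed-flow curve across traffic volumes
#'
#' Runs [simulate_flow()] at each volume and tabulates harmonic mean flow
#' speed and per-class free-flow speeds. The returned `flow_curve` can be
#' passed to [traversability()] as the `speed` source so collision
#' probabilities use volume-dependent flow speeds.
#'
#' @param volumes ascending hourly volumes.
#' @param scenario a [traffic_scenario()].
#' @param classes named list of [vehicle_class()] objects.
#' @param config a [sim_config()]; per-volume seeds are derived from
#'   `config$seed` so the curve is reproducible.
#' @return a `flow_curve` data frame: `scenario`, `volume_vph`,
#'   `harmonic_speed_ms`, one `<class>_speed_ms` column per class,
#'   `n_observed`.
#' @export
flow_speed_curve <- function(volumes, scenario = default_scenarios()$H0,
                             classes = default_vehicle_classes(),
                             config = sim_config()) {
  if (is.unsorted(volumes)) stop("'volumes' must be sorted ascending", call. = FALSE)
  rows <- lapply(seq_along(volumes), function(i) {
    cfg <- config
    if (!is.null(config$seed)) cfg$seed <- config$seed + i - 1L
    fr <- simulate_flow(volumes[i], scenario, classes, cfg)
    row <- data.frame(scenario = scenario$label, volume_vph = volumes[i],
                      harmonic_speed_ms = fr$harmonic_mean_speed_ms,
                      n_observed = fr$n_vehicles_observed,
                      stringsAsFactors = FALSE)
    for (k in names(classes)) {
      row[[paste0(k, "_speed_ms")]] <- fr$per_class_free_speed_ms[[k]]
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("flow_curve", "data.frame")
  out
}
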