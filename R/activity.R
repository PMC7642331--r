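#' @name circular-helpers
#' @title Circular statistics for hour-of-day data
#'
#' @description Hours of day are treated as angles on the 24-h circle
#' (1 h = pi/12 radians). `vonmises_mle()` gives the maximum-likelihood
#' circular mean and concentration of a sample; `rvonmises_hours()` draws
#' from a von Mises distribution on the circle, in hours.
#'
#' @param times_h numeric vector of hour-of-day values in `[0, 24)`.
#' @param n number of draws.
#' @param mu_h circular mean, hours.
#' @param kappa concentration (>= 0); 0 is circular uniform.
#' @param seed optional RNG seed.
NULL

hours_to_rad <- function(h) h * pi / 12
rad_to_hours <- function(th) (th * 12 / pi) %% 24

# Fisher's approximation to the inverse of A(kappa) = I1(k)/I0(k)
a1inv <- function(R) {
  if (R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else if (R < 1) {
    1 / (R^3 - 4 * R^2 + 3 * R)
  } else {
    Inf
  }
}

#' @rdname circular-helpers
#' @return `vonmises_mle()`: a list with `mu_h` (circular mean, hours),
#'   `kappa`, and the mean resultant length `rbar`.
#' @export
vonmises_mle <- function(times_h) {
  if (length(times_h) < 2) stop("need at least 2 observations", call. = FALSE)
  th <- hours_to_rad(times_h)
  C <- mean(cos(th)); S <- mean(sin(th))
  rbar <- sqrt(C^2 + S^2)
  list(mu_h = rad_to_hours(atan2(S, C)), kappa = min(a1inv(rbar), 1e5),
       rbar = rbar)
}

#' @rdname circular-helpers
#' @return `rvonmises_hours()`: `n` hour-of-day draws.
#' @export
rvonmises_hours <- function(n, mu_h, kappa, seed = NULL) {
  with_seed(seed, {
    if (kappa == 0) return(runif(n, 0, 24))
    mu <- hours_to_rad(mu_h)
    # Best & Fisher (1979) rejection sampler
    tau <- 1 + sqrt(1 + 4 * kappa^2)
    rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
    r <- (1 + rho^2) / (2 * rho)
    out <- numeric(n)
    got <- 0L
    while (got < n) {
      m <- n - got
      u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      ccost <- kappa * (r - f)
      ok <- (ccost * (2 - ccost) - u2 > 0) | (log(ccost / u2) + 1 - ccost >= 0)
      if (any(ok)) {
        th <- mu + sign(u3[ok] - 0.5) * acos(f[ok])
        out[got + seq_len(sum(ok))] <- th
        got <- got + sum(ok)
      }
    }
    rad_to_hours(out)
  })
}

# Taylor (2008) plug-in concentration for a von Mises kernel
taylor_bandwidth <- function(times_h) {
  n <- length(times_h)
  k <- vonmises_mle(times_h)$kappa
  k <- min(k, 500)  # degenerate (point-mass) samples
  # I2(2k)/I0(k)^2 with the exp scaling of besselI cancelling exactly
  i0 <- besselI(k, 0, expon.scaled = TRUE)
  ratio <- besselI(2 * k, 2, expon.scaled = TRUE) / i0^2
  max((3 * n * k^2 * ratio / (4 * sqrt(pi)))^(2 / 5), 0.05)
}

#' Circular kernel density of hour-of-day activity
#'
#' Von Mises kernel density on the 24-h circle. The kernel concentration is
#' the Taylor plug-in value computed from the sample's fitted von Mises
#' concentration, divided by `adjust` (larger `adjust` = smoother). The
#' density is expressed per hour and integrates to 1 over one period.
#'
#' @param times_h hour-of-day sample (`n >= 2`), values in `[0, 24)`.
#' @param adjust bandwidth adjustment constant; 1 is the convention used for
#'   small-sample overlap estimation.
#' @param n_grid grid size for the tabulated density.
#' @return a `circular_density`: list with `density` (vectorised function of
#'   hours), `grid` (data frame `x`, `y`), the kernel concentration `nu`,
#'   and the sample size `n`.
#' @examples
#' d <- circular_density(c(rep(6.5, 10), rep(7.5, 10)))
#' integrate(d$density, 0, 24)$value  # 1
#' @export
circular_density <- function(times_h, adjust = 1, n_grid = 512) {
  if (length(times_h) < 2) stop("need at least 2 observations", call. = FALSE)
  if (any(!is.finite(times_h))) stop("non-finite hour values", call. = FALSE)
  times_h <- times_h %% 24
  nu <- taylor_bandwidth(times_h) / adjust
  th_i <- hours_to_rad(times_h)
  log_i0 <- log(besselI(nu, 0, expon.scaled = TRUE)) + nu
  dens <- function(h) {
    th <- hours_to_rad(h)
    vapply(th, function(t0) {
      mean(exp(nu * (cos(t0 - th_i) - 1) + nu - log_i0)) / (2 * pi)
    }, 0) * pi / 12   # radians -> per-hour
  }
  x <- seq(0, 24, length.out = n_grid + 1)[seq_len(n_grid)]
  structure(list(density = dens, grid = data.frame(x = x, y = dens(x)),
                 nu = nu, n = length(times_h)),
            class = "circular_density")
}

#' Traffic activity as a circular density
#'
#' Piecewise-constant density over the 24 hours, proportional to the hourly
#' traffic volumes; integrates to 1 over a day. Used as the "activity
#' pattern" of traffic when computing overlap with animal activity.
#'
#' @param hourly_volumes 24 non-negative volumes (hours 0-23), not all zero.
#' @return a `traffic_density`: list with a vectorised `density` function
#'   (per hour) and the hourly shares.
#' @export
traffic_activity_density <- function(hourly_volumes) {
  if (length(hourly_volumes) != 24 || any(hourly_volumes < 0)) {
    stop("'hourly_volumes' must be 24 non-negative values", call. = FALSE)
  }
  if (sum(hourly_volumes) == 0) stop("all hourly volumes are zero", call. = FALSE)
  share <- hourly_volumes / sum(hourly_volumes)
  dens <- function(h) share[floor(h %% 24) + 1]
  structure(list(density = dens, share = share), class = "traffic_density")
}

# trapezoid integral of min(fa, fb) over one 24-h period on `grid_n` intervals
dhat1_on_grid <- function(fa, fb, grid_n = 128) {
  x <- seq(0, 24, length.out = grid_n + 1)
  m <- pmin(fa(x), fb(x))
  sum((m[-1] + m[-length(m)]) / 2 * diff(x))
}

#' Overlap coefficient Dhat1 between two activity patterns
#'
#' The coefficient of overlapping \eqn{\hat\Delta_1 = \int \min(\hat f,
#' \hat g)} between two circular activity densities, estimated with von
#' Mises kernel densities on a 128-interval grid (trapezoid rule). This is
#' the overlap estimator recommended for small samples. A percentile
#' bootstrap (resampling each hour sample with replacement, bandwidths
#' re-estimated) gives the confidence interval.
#'
#' @param times_a hour-of-day sample for the first pattern (`n >= 2`).
#' @param times_b hour-of-day sample for the second pattern, or a
#'   [traffic_activity_density()] object (held fixed in the bootstrap).
#' @param n_boot bootstrap resamples for the CI (>= 0; 0 skips the CI).
#' @param conf confidence level.
#' @param adjust kernel bandwidth adjustment, see [circular_density()].
#' @param grid_n number of grid intervals for the integral.
#' @param seed optional RNG seed for the bootstrap.
#' @return an `overlap_result`: `dhat1`, `ci_low`, `ci_high`, `n_boot`.
#' @examples
#' a <- rvonmises_hours(100, 7, 2, seed = 1)
#' b <- rvonmises_hours(100, 9, 2, seed = 2)
#' overlap_dhat1(a, b, n_boot = 99, seed = 3)
#' @export
overlap_dhat1 <- function(times_a, times_b, n_boot = 999, conf = 0.95,
                          adjust = 1, grid_n = 128, seed = NULL) {
  if (length(times_a) < 2) stop("'times_a' needs at least 2 observations", call. = FALSE)
  fixed_b <- inherits(times_b, "traffic_density")
  if (!fixed_b && length(times_b) < 2) {
    stop("'times_b' needs at least 2 observations", call. = FALSE)
  }
  est <- function(a, b) {
    fa <- circular_density(a, adjust = adjust)$density
    fb <- if (fixed_b) b$density else circular_density(b, adjust = adjust)$density
    dhat1_on_grid(fa, fb, grid_n)
  }
  d <- est(times_a, times_b)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        a <- sample(times_a, replace = TRUE)
        b <- if (fixed_b) times_b else sample(times_b, replace = TRUE)
        est(a, b)
      }, 0)
    })
    alpha <- (1 - conf) / 2
    ci <- unname(quantile(boots, c(alpha, 1 - alpha)))
  }
  structure(list(dhat1 = d, ci_low = ci[1], ci_high = ci[2], n_boot = n_boot),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  if (x$n_boot > 0) {
    cat(sprintf("Dhat1 = %.3f (%d-resample CI %.3f-%.3f)\n",
                x$dhat1, x$n_boot, x$ci_low, x$ci_high))
  } else {
    cat(sprintf("Dhat1 = %.3f\n", x$dhat1))
  }
  invisible(x)
}

#' Hourly detection probability from camera-trap captures
#'
#' Capture rate per camera-day in each hour of the day, a proxy for animal
#' activity near the road. Captures of the same species at the same station
#' within `independence_min` minutes of the previously retained capture are
#' collapsed to one (independent-event filter).
#'
#' @param records data frame of captures: `station_id`, `species`,
#'   `timestamp` (ISO 8601 text or POSIXct).
#' @param effort_camera_days total sampling effort in camera-days (> 0).
#' @param independence_min independence window in minutes (0 disables).
#' @return an `activity_profile` (list: `species`, `hourly_rate` of length
#'   24, `effort_camera_days`, `n_raw`, `n_independent`); with several
#'   species in `records`, a named list of profiles.
#' @export
hourly_detection_prob <- function(records, effort_camera_days,
                                  independence_min = 30) {
  check_number(effort_camera_days, "effort_camera_days")
  required <- c("station_id", "species", "timestamp")
  if (!all(required %in% names(records))) {
    stop("records need columns station_id, species, timestamp", call. = FALSE)
  }
  ts <- records$timestamp
  if (!inherits(ts, "POSIXct")) {
    ts <- as.POSIXct(ts, tz = "UTC", tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                    "%Y-%m-%d %H:%M:%S"))
  }
  if (anyNA(ts)) stop("unparseable timestamp(s) in capture records", call. = FALSE)
  if (nrow(records) == 0) {
    return(structure(list(species = NA_character_, hourly_rate = rep(0, 24),
                          effort_camera_days = effort_camera_days,
                          n_raw = 0L, n_independent = 0L),
                     class = "activity_profile"))
  }
  sp_all <- unique(records$species)
  one <- function(sp) {
    sel <- records$species == sp
    t_sp <- ts[sel]; st_sp <- records$station_id[sel]
    n_raw <- sum(sel)
    keep <- logical(n_raw)
    for (st in unique(st_sp)) {
      idx <- which(st_sp == st)
      idx <- idx[order(t_sp[idx])]
      last <- -Inf
      for (i in idx) {
        if (as.numeric(t_sp[i]) - last >= independence_min * 60) {
          keep[i] <- TRUE
          last <- as.numeric(t_sp[i])
        }
      }
    }
    hrs <- as.integer(format(t_sp[keep], "%H"))
    rate <- tabulate(hrs + 1, nbins = 24) / effort_camera_days
    structure(list(species = sp, hourly_rate = rate,
                   effort_camera_days = effort_camera_days,
                   n_raw = n_raw, n_independent = sum(keep)),
              class = "activity_profile")
  }
  if (length(sp_all) == 1) one(sp_all) else setNames(lapply(sp_all, one), sp_all)
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("Activity profile for %s: %d captures (%d independent), effort %g camera-days\n",
              x$species, x$n_raw, x$n_independent, x$effort_camera_days))
  cat(sprintf("  peak hour %02d:00, rate %.3f/camera-day\n",
              which.max(x$hourly_rate) - 1, max(x$hourly_rate)))
  invisible(x)
}

#' Activity-weighted hourly collision risk
#'
#' Hourly AVC risk: the collision probability at that hour's traffic volume
#' multiplied by the hourly detection probability (activity near the road).
#' Risk is zero exactly where the species is never detected or traffic is
#' absent.
#'
#' @param activity an `activity_profile` from [hourly_detection_prob()].
#' @param hourly_p_hit 24 hourly collision probabilities (e.g. the `p_hit`
#'   element of [daily_avc_profile()]).
#' @return an `avc_risk_profile` data frame: `hour`, `p_hit`,
#'   `activity_rate`, `risk`.
#' @export
avc_risk_profile <- function(activity, hourly_p_hit) {
  stopifnot(inherits(activity, "activity_profile"))
  if (length(hourly_p_hit) != 24) {
    stop("'hourly_p_hit' must have length 24", call. = FALSE)
  }
  out <- data.frame(hour = 0:23, p_hit = hourly_p_hit,
                    activity_rate = activity$hourly_rate,
                    risk = hourly_p_hit * activity$hourly_rate)
  attr(out, "species") <- activity$species
  class(out) <- c("avc_risk_profile", "data.frame")
  out
}
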