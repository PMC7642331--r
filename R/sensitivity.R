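#' Parameter specification for sensitivity analysis
#'
#' @param name parameter name (must match a model-input column).
#' @param dist `"uniform"` or `"normal"`.
#' @param min,max bounds (uniform).
#' @param mean,sd moments (normal).
#' @param lower optional lower truncation for normal margins.
#' @return a `param_spec` list.
#' @export
param_spec <- function(name, dist = c("uniform", "normal"),
                       min = NULL, max = NULL, mean = NULL, sd = NULL,
                       lower = -Inf) {
  dist <- match.arg(dist)
  if (dist == "uniform") {
    if (is.null(min) || is.null(max) || min > max) {
      stop(sprintf("parameter '%s': uniform needs min <= max", name), call. = FALSE)
    }
  } else {
    if (is.null(mean) || is.null(sd) || sd <= 0) {
      stop(sprintf("parameter '%s': normal needs mean and sd > 0", name), call. = FALSE)
    }
  }
  structure(list(name = name, dist = dist, min = min, max = max,
                 mean = mean, sd = sd, lower = lower),
            class = "param_spec")
}

#' Default parameter ranges for the collision-probability model
#'
#' Animal traits span the default species table: group-scaled length is
#' normal with the mean and SD of the six species' group lengths (truncated
#' positive), width and crossing speed uniform over the table's min-max.
#' Vehicle length and speed are normal around the default fleet mix, width
#' uniform across the classes; hourly volume uniform over 100-2400 veh/h.
#'
#' @param species a [species_traits()] table used to set the animal ranges.
#' @return named list of [param_spec()] objects, one per model input.
#' @export
default_param_specs <- function(species = default_species()) {
  gl <- group_length(species)
  va <- species$traverse_speed_ms
  wa <- species$body_width_m
  specs <- list(
    param_spec("animal_length_m", "normal", mean = mean(gl), sd = sd(gl),
               lower = 0.1),
    param_spec("animal_width_m", "uniform", min = min(wa), max = max(wa)),
    param_spec("animal_speed_ms", "uniform", min = min(va), max = max(va)),
    param_spec("vehicle_length_m", "normal", mean = 7.1, sd = 3.5, lower = 0.5),
    param_spec("vehicle_width_m", "uniform", min = 1.8, max = 2.6),
    param_spec("vehicle_speed_ms", "normal", mean = 18, sd = 4, lower = 1),
    param_spec("volume_vph", "uniform", min = 100, max = 2400)
  )
  setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Latin hypercube sample of model parameters
#'
#' Each parameter's range is split into `n` equal-probability strata with
#' one draw per stratum and the strata independently permuted across
#' parameters; non-uniform margins are obtained through the inverse CDF
#' (truncated-normal margins keep the stratification).
#'
#' @param specs named list of [param_spec()] objects.
#' @param n number of samples (>= 2).
#' @param seed optional RNG seed.
#' @return a data frame with `n` rows, one column per parameter.
#' @export
lhs_sample <- function(specs, n, seed = NULL) {
  if (n < 2) stop("'n' must be >= 2", call. = FALSE)
  if (!length(specs) || !all(vapply(specs, inherits, TRUE, "param_spec"))) {
    stop("'specs' must be a list of param_spec objects", call. = FALSE)
  }
  with_seed(seed, {
    u <- lhs::randomLHS(n, length(specs))
    cols <- lapply(seq_along(specs), function(j) {
      s <- specs[[j]]
      if (s$dist == "uniform") {
        qunif(u[, j], s$min, s$max)
      } else {
        plo <- pnorm(s$lower, s$mean, s$sd)
        qnorm(plo + u[, j] * (1 - plo), s$mean, s$sd)
      }
    })
    out <- as.data.frame(cols)
    names(out) <- vapply(specs, `[[`, "", "name")
    out
  })
}

#' Partial inclination coefficients with bootstrap confidence intervals
#'
#' The PIC of each parameter is its slope in a multiple linear regression of
#' the model output on all raw (unstandardised) parameters across the
#' sampled design. Percentile confidence intervals come from bootstrap
#' resampling of the design rows; a parameter is flagged significant when
#' its interval excludes zero. Constant (degenerate) parameters get a PIC
#' of exactly 0.
#'
#' @param samples data frame or matrix of parameter samples.
#' @param outputs model output, one value per row of `samples`.
#' @param n_boot number of bootstrap resamples.
#' @param conf confidence level.
#' @param seed optional RNG seed for the bootstrap.
#' @return a `sensitivity_result` data frame: `parameter`, `pic`, `ci_low`,
#'   `ci_high`, `significant`.
#' @export
pic_estimate <- function(samples, outputs, n_boot = 1000, conf = 0.95,
                         seed = NULL) {
  samples <- as.data.frame(samples)
  p <- ncol(samples)
  if (length(outputs) != nrow(samples)) {
    stop("'outputs' must have one value per sample row", call. = FALSE)
  }
  if (nrow(samples) < p + 2) {
    stop("need at least (number of parameters + 2) rows", call. = FALSE)
  }
  is_const <- vapply(samples, function(x) stats::var(x) == 0, TRUE)
  X <- cbind(`(Intercept)` = 1, as.matrix(samples[, !is_const, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop(sprintf("collinear parameter(s): %s", paste(aliased, collapse = ", ")),
         call. = FALSE)
  }
  beta <- qr.coef(qrX, outputs)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(X), replace = TRUE)
      qr.coef(qr(X[idx, , drop = FALSE]), outputs[idx])
    }, numeric(ncol(X)))
  })
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 1, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  out <- data.frame(parameter = names(samples),
                    pic = 0, ci_low = 0, ci_high = 0,
                    significant = FALSE, stringsAsFactors = FALSE)
  free <- names(samples)[!is_const]
  out$pic[!is_const] <- beta[free]
  out$ci_low[!is_const] <- ci[1, free]
  out$ci_high[!is_const] <- ci[2, free]
  out$significant <- out$ci_low > 0 | out$ci_high < 0
  class(out) <- c("sensitivity_result", "data.frame")
  out
}

#' @export
print.sensitivity_result <- function(x, digits = 4, ...) {
  cat("Partial inclination coefficients (bootstrap 95% CI)\n")
  y <- as.data.frame(x)
  for (col in c("pic", "ci_low", "ci_high")) y[[col]] <- signif(y[[col]], digits)
  y$significant <- ifelse(y$significant, "*", "")
  print(y, row.names = FALSE)
  invisible(x)
}

# Collision probability as a flat function of its seven raw inputs;
# column names match default_param_specs().
p_hit_flat <- function(d) {
  T_s <- (d$vehicle_width_m + d$animal_length_m) / d$animal_speed_ms +
    (d$vehicle_length_m + d$animal_width_m) / d$vehicle_speed_ms
  1 - exp(-(d$volume_vph / 3600) * T_s)
}

#' Global sensitivity analysis of collision probability
#'
#' Latin hypercube sampling over the model inputs, PIC estimation with
#' bootstrap confidence intervals, and per-parameter effect curves computed
#' with all other inputs held at their mean values.
#'
#' @param model function taking a data frame of parameter columns and
#'   returning the model output; defaults to the collision probability
#'   \eqn{P_h}.
#' @param specs named list of [param_spec()] objects.
#' @param n Latin hypercube sample size.
#' @param n_boot bootstrap resamples for the PIC intervals.
#' @param seed optional RNG seed.
#' @param effect_points grid size of the effect curves.
#' @return a `sensitivity_analysis`: list with `pic` (a
#'   [pic_estimate()] table), `effects` (long data frame `parameter`,
#'   `value`, `output`), `samples`, `n`, `n_boot`.
#' @examples
#' sa <- run_sensitivity(n = 200, n_boot = 100, seed = 1)
#' sa$pic
#' @export
run_sensitivity <- function(model = p_hit_flat, specs = default_param_specs(),
                            n = 1000, n_boot = 1000, seed = NULL,
                            effect_points = 50) {
  if (n < 50) {
    warning("small LHS sample (n < 50): PIC confidence intervals will be unstable")
  }
  samples <- lhs_sample(specs, n, seed = seed)
  outputs <- model(samples)
  pic <- pic_estimate(samples, outputs, n_boot = n_boot,
                      seed = if (is.null(seed)) NULL else seed + 1L)
  mid <- vapply(specs, function(s) {
    if (s$dist == "uniform") (s$min + s$max) / 2 else s$mean
  }, 0)
  effects <- do.call(rbind, lapply(names(specs), function(nm) {
    s <- specs[[nm]]
    rng <- if (s$dist == "uniform") c(s$min, s$max) else {
      c(max(s$lower, s$mean - 2 * s$sd), s$mean + 2 * s$sd)
    }
    grid <- seq(rng[1], rng[2], length.out = effect_points)
    d <- as.data.frame(as.list(mid))[rep(1, effect_points), , drop = FALSE]
    names(d) <- names(specs)
    d[[nm]] <- grid
    data.frame(parameter = nm, value = grid, output = model(d),
               stringsAsFactors = FALSE)
  }))
  structure(list(pic = pic, effects = effects, samples = samples,
                 n = n, n_boot = n_boot),
            class = "sensitivity_analysis")
}

#' @export
print.sensitivity_analysis <- function(x, ...) {
  cat(sprintf("Sensitivity analysis: LHS n = %d, %d bootstrap resamples\n",
              x$n, x$n_boot))
  print(x$pic)
  invisible(x)
}

#' @export
plot.sensitivity_analysis <- function(x, ...) {
  pars <- unique(x$effects$parameter)
  old <- par(mfrow = c(ceiling(length(pars) / 3), 3), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (nm in pars) {
    d <- x$effects[x$effects$parameter == nm, ]
    plot(d$value, d$output, type = "l", xlab = nm,
         ylab = expression(P[h]), main = nm, ...)
  }
  invisible(x)
}
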