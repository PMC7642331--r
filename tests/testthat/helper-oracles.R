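# Independent oracles used across the suite. These deliberately avoid the
# package's analytic code paths.

# Monte-Carlo collision oracle: vehicles arrive as a homogeneous Poisson
# process on a window; a crossing attempt starting at a uniform random time
# collides iff at least one arrival falls inside its coincidence window of
# length T. Simulated per trial from raw arrival positions.
mc_collision_fraction <- function(T_s, volume_vph, n_trials = 1e5, seed = 1) {
  set.seed(seed)
  lam <- volume_vph / 3600
  L <- 10 * T_s + 10          # process window, crossing start in [0, L - T]
  counts <- rpois(n_trials, lam * L)
  start <- runif(n_trials, 0, L - T_s)
  trial <- rep.int(seq_len(n_trials), counts)
  pos <- runif(sum(counts), 0, L)
  hit_arrival <- pos > start[trial] & pos <= start[trial] + T_s
  hits <- tabulate(trial[hit_arrival], nbins = n_trials) > 0
  mean(hits)
}

# true von Mises density on the 24-h circle (per hour)
dvm_hours <- function(h, mu_h, kappa) {
  th <- (h - mu_h) * pi / 12
  exp(kappa * (cos(th) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE)) * pi / 12
}

# fine numeric integration of the true overlap between two von Mises densities
true_vm_overlap <- function(mu1, k1, mu2, k2, n_grid = 20000) {
  x <- seq(0, 24, length.out = n_grid + 1)
  m <- pmin(dvm_hours(x, mu1, k1), dvm_hours(x, mu2, k2))
  sum((m[-1] + m[-length(m)]) / 2 * diff(x))
}

# trapezoid integral of a function over [0, 24]
trapz_24 <- function(f, n_grid = 20000) {
  x <- seq(0, 24, length.out = n_grid + 1)
  y <- f(x)
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

# analytic free-flow harmonic mean speed of a scenario mix: 1 / E[1/V] with V
# the truncated-normal desired speed (numeric integration per class)
analytic_freeflow_harmonic <- function(classes, scenario) {
  p <- scenario$proportions
  inv_means <- vapply(names(p), function(k) {
    cl <- classes[[k]]
    mu <- cl$free_speed_mean_kmh / 3.6
    s <- cl$free_speed_sd_kmh / 3.6
    if (s == 0) return(1 / mu)
    lo <- 0.5 * mu
    z <- integrate(function(v) dnorm(v, mu, s), lo, Inf)$value
    integrate(function(v) dnorm(v, mu, s) / v / z, lo, Inf)$value
  }, 0)
  1 / sum(p * inv_means)
}

# quick single-species trait row builder for hand-arithmetic checks
one_species <- function(name = "sp", mass = 65, len = 1.55, wid = 0.6,
                        grp = 1, va = NA_real_) {
  species_traits(name, mass, len, wid, grp, traverse_speed_ms = va)
}
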