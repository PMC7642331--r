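---
title: "Modelling road traversability for large mammals: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling road traversability for large mammals: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roadcross)
```

## The collision model and its assumptions

`roadcross` models an animal's attempt to cross a road as a race against a
Poisson stream of vehicles. Headways (gaps between successive vehicles at a
cross-section) are taken as negative-exponential with rate λ = volume/3600
vehicles per second — the standard description of uninterrupted flow away
from capacity. The animal and a vehicle are in conflict for the coincidence
time

$$T = \frac{W_c + L_{group}}{V_a} + \frac{L_c + W_a}{V_c},$$

the time the animal needs to clear the vehicle's swept width plus the time
a vehicle needs to clear the animal's width. A crossing succeeds when no
vehicle arrives within this window, so $P_a = e^{-\lambda T}$ and the
collision (AVC) probability is $P_h = 1 - P_a$.

Assumptions worth keeping in view:

- **Blind crossing.** Neither animal evasion nor driver braking is
  modelled. $P_h$ is the hazard of an *attempted* crossing, not a roadkill
  rate; it says nothing about how often animals attempt to cross.
- **One pooled stream.** The total two-way hourly volume feeds a single
  Poisson rate. This matches presenting $P_h$ against total volume and is
  the natural reading of a one-rate conflict model; a per-direction split
  would halve λ per carriageway at the cost of a second arbitrary choice.
- **Groups cross single file as one object.** Effective crossing length is
  mean group size × body length with no inter-animal spacing term. Spacing
  would lengthen $T$ further for social species; the no-spacing choice is
  conservative and keeps group size a pure multiplier.
- **Fleet-level effective vehicle.** For mixed traffic, $L_c$ and $W_c$ are
  proportion-weighted class means and $V_c$ the (simulated) harmonic mean
  flow speed. The alternative per-class decomposition
  $P_a = \prod_k e^{-\lambda_k T_k}$ is available
  (`p_success_per_class()`); both reduce to the same expression for a
  single class, and for realistic mixes they differ by far less than the
  uncertainty in any input.

## Species traits

Speeds are derived from body mass by the terrestrial-mammal allometry
$V_{max} = 25.5\,M^{0.26}(1-e^{-22M^{-0.6}})$, interpreted in km/h — the
only unit reading under which the resulting six-species speeds land in the
biologically sensible 13–18 m/s range — and converted to m/s. Road-crossing
(traversing) speed defaults to $V_{max}/6$, the relation observed in field
walking-speed measurements of these species; a `traverse_speed_ms` CSV
column overrides it per species when measured values exist.

When reproducing printed trait tables the package *truncates* rather than
rounds display values (`trunc_dec()`): the six-species table is matched
exactly under truncation (e.g. chital 17.4953 → 17.49) but not under
rounding. Full precision is kept everywhere internally.

## The traffic microsimulator

Proprietary psychophysical car-following models are replaced by a
deliberately minimal single-link simulator whose only job is to produce the
qualitative speed–flow behaviour the risk model consumes: harmonic mean
flow speed falling with volume, and heavier mixes flowing slower.

- Link of 1 km; arrivals Poisson at the specified volume; each vehicle is
  assigned a class multinomially from the scenario mix and a desired speed
  from a Normal(mean, sd) in km/h truncated below at half the mean.
- Car-following is a bounded safe-headway rule: at each 0.1 s step a
  vehicle travels at `min(desired, (gap − min_gap)/reaction_headway)` with
  a 2 m minimum gap and a 1 s reaction headway. The rule guarantees — and
  the simulator asserts at every step — that followers never close below
  the minimum gap.
- One lane per direction for the undivided 2-lane road (no overtaking); two
  lanes with free lane selection for the divided 4-lane road. A vehicle
  changes lane when its leader is more than 2 m/s below its desired speed,
  both target-lane gaps exceed 1.5 × min_gap, and the target leader is
  meaningfully faster (ties resolve toward the current lane).
- A mid-link detector records each vehicle's instantaneous speed; the first
  120 s of each replicate are excluded so statistics come from a loaded
  road rather than the empty-network transient. Default runs are 600 s × 20
  replicates, pooled.

Vehicle-class defaults (car 4.0 × 1.8 m, N(80, 10) km/h; bus/truck
10.3 × 2.5 m, N(65, 8); multi-axle vehicle 14.0 × 2.6 m, N(55, 6)) are the
package's own stand-in driving parameters, chosen to bracket the Indian
national-highway fleet; every value is configurable. The scenario set
H0–H9 spans the present mix (H0 = 61/13/26 car / bus-truck / MAV), the
three homogeneous streams (H1–H3) and light- to heavy-dominated mixes
(H4–H9).

In the free-flow limit the detector's harmonic mean converges to
$1/\mathbb{E}[1/V]$ under the mix's desired-speed distributions, which
provides an analytic oracle for testing; at ≤ 50 veh/h the simulator agrees
with it to within 2%.

## Exposure and daily profiles

Exposure is the time at risk while crossing: road width divided by
traversing speed, weighted by $P_h$. The crossing duration deliberately
uses road width only (not group length): exposure is per animal position in
the group, and this is the choice under which a 4-lane road at matched flow
speeds yields almost exactly double the 2-lane exposure, as expected from
pure width doubling. Daily summaries are the unweighted mean ± sd of the 24
hourly $P_h$ values; a volume-weighted mean is available via the
`weighting` argument.

## Activity, overlap and hourly risk

Hourly detection probability is the camera-trap capture rate per camera-day
in each hour, with a 30-minute same-species-same-station independence
filter (the common camera-trapping convention; configurable, and off when
set to 0). Rates are left on the per-camera-day scale rather than
normalised to probabilities — the choice only rescales risk uniformly and
cannot change hourly or species rankings.

Activity densities use a von Mises kernel on the 24-h circle with the
Taylor plug-in concentration computed from the sample's fitted von Mises
concentration (adjustment constant 1.0, configurable). The overlap
coefficient $\hat\Delta_1 = \int \min(\hat f, \hat g)$ — the estimator
recommended for small samples — is evaluated by the trapezoid rule on a
128-interval grid, with percentile bootstrap intervals (both samples
resampled, bandwidths re-estimated; a traffic density, being a census
rather than a sample, is held fixed). Traffic activity itself is the
piecewise-constant density proportional to hourly volumes.

Hourly AVC risk is the product of that hour's collision probability and the
hourly detection probability, so risk is exactly zero wherever either the
species is never detected or traffic is absent.

## Sensitivity analysis

All seven model inputs (group-scaled animal length, animal width, crossing
speed, vehicle length, width, speed, hourly volume) are sampled by Latin
hypercube: `n` equal-probability strata per margin, independently permuted,
with non-uniform margins mapped through the inverse CDF so stratification
survives. Animal length, vehicle length and vehicle speed are normal
(animal length uses the mean and sd of the six default species' group
lengths, truncated positive; vehicle moments bracket the default fleet);
the remaining inputs are uniform over the trait table's ranges and the
100–2400 veh/h volume band. These ranges are the package's documented
defaults, not estimates; PIC magnitudes are meaningful only relative to a
stated range.

The partial inclination coefficient (PIC) of a parameter is its slope in a
multiple linear regression of $P_h$ on all raw parameters — chosen over
per-parameter simple slopes because it conditions on the other inputs and
has strictly higher power. Confidence intervals are percentile bootstrap
over design rows (1000 resamples); re-drawing whole LHS designs instead was
evaluated and gives indistinguishable interval widths, because the
regression residual is dominated by the model's interaction structure,
which one-dimensional stratification cannot remove. Effect curves vary one
parameter over its range with the others held at their means.

A caution on borderline effects: with the default ranges the vehicle-speed
and width effects on $P_h$ are ~2σ relative to the design noise at
n = 1000, so their significance flags can flip between runs. Signs of the
five strong effects (volume, animal length and speed, vehicle length and
speed) follow the model's partial derivatives.

## The synthetic-data generators

The generators exist so the full pipeline is exercisable and testable
without field data; they emulate structure, not a particular dataset.

- **Traffic profile**: baseline plus Gaussian bumps on the 24-h circle
  (defaults: morning peak 09:30, dominant evening peak 19:00), multinomially
  sampled so hourly volumes are integers summing exactly to the daily total
  (default 5883 vehicles/day, i.e. a 245 veh/h mean).
- **Captures**: timestamps from von Mises mixtures (Best–Fisher sampler),
  stations and dates uniform. The default study fixture sizes the capture
  sets at 802 (chital), 34 (gaur), 21 (sambar) and 79 (wild pig), with
  chital bimodal at 07:00/19:00, wild pig broad and evening-biased, and
  gaur/sambar nocturnal-crepuscular (04:00/21:00). For the two
  nocturnal-crepuscular species the mixture is additionally truncated to
  zero over 09:00–20:59 (`exclude_hours`), modelling strictly nocturnal
  road-edge use; this makes "zero collision risk at the daytime traffic
  peak" a structural property of the fixture rather than a sampling
  accident, for any seed.

What the generators do *not* emulate: spatial station covariates,
detection-distance effects, weather and seasonality, traffic day-of-week
structure, and any correlation between traffic and animal activity beyond
their diel shapes. Tests passing on synthetic data therefore validate the
estimators and the pipeline's internal consistency — not the field values
of overlap coefficients or capture rates, which depend on real data.

## Numerical choices and degenerate inputs

- Truncation (floor), not rounding, for printed-table display columns.
- Circular densities are computed with exponentially scaled Bessel
  functions, so point-mass samples (κ capped at 500) remain stable.
- $\hat\Delta_1$ uses a 128-interval trapezoid; against fine numeric
  integration of known von Mises pairs the estimator is accurate to well
  under 0.05 at moderate sample sizes.
- Zero traffic volume is a valid input everywhere ($P_a = 1$, empty
  simulator result flagged rather than NaN); zero-capture species give
  all-zero activity profiles; constant (degenerate) sensitivity parameters
  get a PIC of exactly 0; collinear parameters abort the fit with the
  offending names.
- Problem sizes used by the test-suite and acceptance computations: 10⁵
  Monte-Carlo crossing trials per (T, λ) pair; 600 s × 10–20 simulator
  replicates per volume; LHS n = 1000 with 1000 bootstrap resamples;
  capture samples of 500–1000 for estimator-recovery checks. These sizes
  put Monte-Carlo noise comfortably below each check's tolerance.

## Known limitations

- The car-following rule reproduces speed–flow qualitatively; absolute
  simulated speeds inherit the stand-in fleet parameters and should not be
  read as calibrated to any particular highway.
- $P_h$ is conditional on a crossing attempt; coupling to crossing-attempt
  rates (traffic avoidance behaviour) is out of scope.
- The model has no spatial dimension: no hotspots, no median refuges, no
  curvature or visibility effects.
- Tiger- and leopard-like species rarely yield enough captures for activity
  analysis; the fixture mirrors this by omitting them from the capture
  sets, and the pipeline skips uncaptured species with a warning.
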