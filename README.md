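# roadcross

Traversability and collision risk of roads for large mammals under
heterogeneous traffic.

## The problem

Highways through wildlife habitat kill animals in vehicle collisions and, at
high traffic loads, become behavioural barriers to movement. Which species
are most at risk — and at what traffic volumes a road stops being crossable —
depends on the interaction of species traits (body size, group size,
crossing speed), road geometry (number and width of lanes) and traffic
characteristics (volume, composition, flow speed). `roadcross` implements a
complete modelling pipeline for this question, built around the large-mammal
community of central Indian tiger landscapes (chital, gaur, leopard, sambar,
tiger, wild pig) but configurable for any species set and fleet.

## The model

Vehicle headways at a road cross-section are treated as a Poisson process
with rate λ (vehicles/s). An animal (or single-file group) attempting a
"blind" crossing is in conflict with traffic for the coincidence time

    T = (W_c + L_group) / V_a + (L_c + W_a) / V_c      [seconds]

where `W_c`, `L_c`, `V_c` are effective vehicle width, length and speed,
`W_a`, `V_a` animal width and crossing speed, and `L_group` is body length
scaled by mean group size. The probability of a successful crossing and of
an animal–vehicle collision (AVC) are

    P_a = exp(−λT),    P_h = 1 − P_a

The road becomes a coin-flip barrier (`P_h = 0.5`) at the threshold volume
`3600·ln 2 / T` vehicles/h. Around this core the package provides:

- **Allometric speeds** — maximum running speed from body mass,
  `V_max = 25.5·M^0.26·(1 − e^(−22·M^(−0.6)))` km/h, with road-crossing
  speed `V_max/6`.
- **Traffic microsimulation** — a single-link, negative-exponential-headway,
  safe-headway car-following simulator for mixed car / bus-truck /
  multi-axle-vehicle streams (heterogeneity scenarios H0–H9), reporting
  harmonic mean flow speeds by volume, in place of proprietary simulators.
- **Exposure** — seconds at risk while crossing, as a function of road width
  and `P_h`.
- **Sensitivity analysis** — Latin hypercube sampling over all model inputs
  with bootstrap partial inclination coefficients (PIC).
- **Activity-weighted risk** — von Mises kernel activity densities from
  camera-trap records, the Δ̂₁ overlap coefficient between animal and
  traffic activity, and hourly AVC risk = hourly `P_h` × hourly detection
  probability.
- **Synthetic data** — generators for bimodal daily traffic profiles and
  camera-trap capture records, so the full pipeline runs with no field data.

## Worked example

```r
library(roadcross)

sp <- default_species()
tr <- traversability(sp)          # present-day mix H0, 2-lane road
summary(tr)
```

```
Traversability summary (reference volume 245 veh/h)
  species group_length_m  T_s p_hit_ref threshold_vph
   chital          12.63 5.47     0.311           456
     gaur          15.67 8.55     0.441           292
  leopard           2.43 1.99     0.126          1256
   sambar           5.98 3.31     0.202           754
    tiger           3.10 2.24     0.141          1114
 wild_pig          11.74 5.12     0.294           487
```

At a typical 245 vehicles/h, the slow, group-living gaur already fails 44%
of crossing attempts and faces a barrier threshold below 300 vehicles/h,
while the fast, solitary cats are at an order less risk and can traverse
until traffic exceeds ~1100–1260 vehicles/h. Adding simulated flow speeds
and activity:

```r
fx <- default_study_fixture(seed = 1)            # synthetic study inputs
ar <- run_activity_risk(fx$captures, fx$effort_camera_days,
                        fx$hourly_traffic, n_boot = 199, seed = 1)
ar$overlap
```

```
   species     dhat1    ci_low   ci_high
1   chital 0.7989548 0.7970602 0.8066838
2     gaur 0.4327501 0.3507181 0.4924599
3   sambar 0.4493499 0.3466470 0.5368188
4 wild_pig 0.6955751 0.6245537 0.7463005
```

The edge-tolerant chital and wild pig overlap traffic activity strongly
(Δ̂₁ ≈ 0.7–0.8) and carry collision risk at the evening traffic peak; the
nocturnal-crepuscular gaur and sambar overlap weakly and have zero risk at
the peak traffic hour.

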