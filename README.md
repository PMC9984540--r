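# pgti

Prompt-gamma time imaging (PGTI) analysis for in-vivo proton range
verification.

## What it does, and for whom

In proton therapy the dose stops at the Bragg peak, so the proton range in
the patient is the quantity to verify. Prompt gammas (PGs) — photons emitted
within picoseconds of a proton's non-elastic nuclear collision — trace the
proton path, and the distal fall-off of their emission profile marks the
stopping depth. Prompt-gamma *timing* monitors the summed time of flight

    TOF = T_p(r_v) + T_PG(r_v, r_d)

(proton transit time to the emission vertex plus gamma flight time to the
detector); prompt-gamma *time imaging* inverts this relation event by event
to reconstruct the vertex coordinate, which lets fast detectors at
different angles be merged in the space domain.

`pgti` is for detector and medical physicists studying this technique at
the design stage. It provides, as testable R functions:

* a Bragg–Kleeman proton kinematics model for PMMA phantoms (calibrated so
  148 MeV protons stop after 13.4 cm of PMMA),
* a synthetic event generator emulating two single-proton-regime
  experiments — 63 MeV cyclotron beam on a two-target phantom with an air
  cavity, and a 148 MeV pulsed synchro-cyclotron beam on a thick stopping
  target — including Poisson bunch occupancy, an energy-dependent Cherenkov
  module response, and the dark-count / bunch-structured backgrounds,
* per-detector reference time maps and the event-by-event TOF-to-vertex
  inversion, with the spatial background template that a TOF-flat
  background acquires under reconstruction,
* the integral fall-off shift statistic `d = F^-1(y_ref) - x_ref` with
  subsampling-bootstrap errors extrapolated through the `k/sqrt(N)` law,
* closed-form counting statistics: the random-coincidence rate
  `f_dia x DCR_SiPM x 2tau`, the effective intensity estimator
  `lambda = P(1)/P(0)`, and the single-proton-regime delivery time
  `N / (r (1 - exp(-lambda)))`.

## Worked example

Simulate the 63 MeV experiment and measure its range-shift sensitivity:

```r
library(pgti)
cfg <- pgti_preset("medicyc_63MeV")

ev <- generate_dataset(cfg, 600, seed = 42)
print(ev)
#> pgti_events: 600 events (signal 600, dark 0, random 0, scatter 0)
#>   event_id  label detector_id true_vertex_x_cm true_energy_MeV    tof_ps n_pe
#> 1        1 signal       det90        5.0864699        6.130000 1078.9366   10
#> 2        2 signal       det90        4.1138579        4.440000  905.6186    7
#> ...

scan <- sensitivity_scan(cfg, shifts_cm = c(0, 0.2, 0.4, 0.6, 1.0),
                         n_events_per_shift = 600, mode = "pgt", seed = 42,
                         spec = bootstrap_spec(n_toys = 5000, target_n = 600))
print(scan)
#> sensitivity scan (pgt mode, ps):
#>  shift_cm          d    sigma1   sigma2 n_events units
#>       0.0   1.692982  9.639562 19.27912      600    ps
#>       0.2  34.865079  9.130523 18.26105      600    ps
#>       0.4  37.669811 10.204560 20.40912      600    ps
#>       0.6  87.623288  8.198453 16.39691      600    ps
#>       1.0 107.319672  9.401490 18.80298      600    ps
```

Each row is one implemented air-cavity widening: `d` is the measured TOF
delay of the profile fall-off against a 20 000-event simulated reference
(note `d` tracks the shift at roughly 107 ps/cm, the inverse speed of the
protons exiting the thin target), and `sigma1`/`sigma2` are bootstrap
errors extrapolated to the 600-event statistics. Converting at 107 ps/cm:

```r
mean(scan$sigma2) / 107 * 10
#> [1] 1.74   # mm -- a 2-sigma range-shift sensitivity well below 4 mm
```

Counting statistics for the same setup:

```r
counting_summary(cfg)
#> $f_dia_hz               625000        # 0.025 p/bunch x 25 MHz
#> $dcr_coinc_hz           det90 3.775   # x 20 ns window, 302 Hz dark rate
#> $spr_delivery_time_s    0.6327907     # 1e7 protons at lambda = 1
```

Switching `mode = "pgti"` reconstructs every event into the space domain
with the reference-geometry time maps and reports `d` in cm; because the
`T_p` term is frozen at reference conditions, the recovered shift
under-reports the implemented one (slope below 1) — a documented property
of the online algorithm, not a defect.

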