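---
title: "Prompt-gamma time imaging: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prompt-gamma time imaging: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement this package models

In proton therapy the dose profile ends at the Bragg peak, so verifying the
proton range in vivo is the central quality-assurance problem. Prompt gammas
(PGs) — de-excitation photons emitted within picoseconds of a proton's
non-elastic nuclear collision — track the proton path, and their emission
profile falls off at the proton stopping depth. Prompt-gamma timing (PGT)
monitors that fall-off through the summed time of flight

$$\mathrm{TOF} = T_p(\mathbf{r}_v) + T_{PG}(\mathbf{r}_v, \mathbf{r}_d),$$

the proton transit time to the emission vertex $\mathbf{r}_v$ plus the gamma
flight time to the detector at $\mathbf{r}_d$. Prompt-gamma time imaging
(PGTI) goes one step further: because the right-hand side is a strictly
increasing function of the vertex depth for any physical detector placement,
the measured TOF can be inverted event by event into a vertex coordinate.
That conversion is what lets detectors at different angles — whose raw TOF
spectra are shifted and stretched differently by the $T_{PG}$ term — be
summed in the space domain.

This package implements that analysis chain end to end on synthetic data:
proton kinematics, an event generator emulating two single-proton-regime
experiments (63 MeV protons from a cyclotron with a 4 ns / 40 ns bunch
structure, and 148 MeV protons from a pulsed synchro-cyclotron with 16 ns
micro-bunches in 8 µs pulses every ms), the TOF-to-vertex inversion, the
integral fall-off shift statistic with subsampling-bootstrap errors, and the
closed-form counting-statistics models.

## Proton kinematics and the range-energy model

Ranges follow the Bragg–Kleeman law $R_{\mathrm{water}}(E) = \alpha E^p$
with $\alpha = 0.0022$ cm·MeV$^{-p}$ and $p = 1.77$. PMMA is described by a
single water-equivalent stopping ratio, calibrated once so that 148 MeV
protons stop after 13.4 cm of PMMA — the one stopping depth the experimental
record pins down for these phantoms. The calibrated ratio is 1.139, a few
percent below tabulated PMMA stopping ratios (1.15–1.17); we prefer the
measured anchor to a literature value because every downstream time scale
derives from it. With this calibration the inverse speed of 63 MeV protons
exiting the 1 cm thin target evaluates to 106.3 ps/cm, within 1% of the
107 ps/cm slope that converts TOF delays into range shifts.

`energy_at_depth()` inverts the range law in closed form, so the
range–energy pair is exactly self-consistent. `transit_time()` integrates
the inverse speed $1/v(E(x))$ by composite midpoint quadrature on steps of
at most 0.1 mm: the 5 mm target transit smear is only ~50 ps, so sub-ps
quadrature accuracy is needed. Air gaps are treated as lossless drifts
(air stopping over ≤ 4 cm is negligible at these energies), which makes the
proton arrival-time map piecewise: Bragg–Kleeman inside PMMA, linear at the
slab-exit speed inside air. Nuclear losses, scattering and straggling are
out of scope; their main observable effect (a softened fall-off) is absorbed
into the emission-profile edge width.

## The synthetic event generator

The generator's role is to produce event lists with the *statistical
structure* of the experiments, not a transport simulation:

* **Bunch occupancy** is Poisson with mean λ (0.025 p/bunch at 63 MeV,
  0.78 p/bunch at 148 MeV — the values estimated from the one-to-zero bunch
  ratio $P(1)/P(0) = \lambda$).
* **Emission profile**: zero in air and beyond the stopping depth, rising
  linearly with PMMA depth (the non-elastic cross-section grows as protons
  slow) by a default factor 1.6 at the end of range, and terminated by a
  logistic edge of width 0.8 mm whose midpoint sits 1 mm upstream of the
  stopping depth — prompt-gamma production stops slightly before the protons
  do because the producing reactions have MeV-scale thresholds.
* **Energy spectrum**: the 4.44 MeV (carbon) and 6.13 MeV (oxygen) lines
  (weights 0.25 and 0.15) over an exponential continuum on 2–7 MeV.
* **Detector response**: the intrinsic efficiency versus PG energy is a
  sigmoid plus a linear term per photoelectron threshold. The 6 p.e. curve
  is anchored to a 5% detection probability at 2 MeV and saturates near
  0.24; the 3 and 9 p.e. curves bracket it. Acceptance combines this
  efficiency with a point-detector solid-angle factor
  $A/(4\pi d^2)$ — adequate because the ≤ 2 cm crystal sits ≥ 14 cm away.
  Accepted events are drawn directly from the conditional (acceptance-
  weighted) vertex and energy distributions, which is exactly equivalent to
  brute-force thinning but makes high-statistics references cheap; the
  analytic acceptance fraction is recorded in the generation summary and
  verified against thinning in the tests.
* **Time stamps** come from the forward model plus independent Gaussian
  jitters for the module and the beam monitor. In the 63 MeV preset the
  module contributes 273.7 ps FWHM so that quadrature with the 156 ps
  monitor reproduces the 315 ps system response measured for that setup.
* **Backgrounds**, added on demand: (i) dark-count random coincidences,
  flat in TOF, with expected count $f_{dia} \times DCR_{SiPM} \times 2\tau
  \times$ livetime; (ii) when the monitor covers only a fraction $c$ of the
  beam, random coincidences of real secondaries with untagged protons —
  Gaussian in TOF with the micro-bunch spread $w/\sqrt{12}$ and expected
  count $n_{sig}(1-c)/c$, since a detected secondary pairs with an
  unrelated trigger whenever its parent proton missed the monitor;
  (iii) optionally (off by default) a localized bump at the
  monitor-to-detector proton flight time, emulating protons scattered off
  the monitor that convert in the module packaging.

The beam is a pencil along the axis: transverse spread is accepted in the
configuration but not transported. A single seed drives the dataset, with
per-event-class sub-streams derived deterministically, so event tables are
byte-identical under a fixed seed.

What passing tests on these data do *not* show: the generator has no
neutron-induced or room background, no pulse-shape information, and its
emission profile is a parametric shape rather than a nuclear model, so
agreement here validates the *analysis chain*, not the detector physics.

## Reconstruction

Each detector gets a reference time map: total TOF tabulated on a 0.2 mm
grid over the reference geometry, inverted by piecewise-linear
interpolation. Interpolation error is far below the ~1 cm spatial blur that
a 315 ps resolution induces through the ~150 ps/cm local slope. Maps are
built once from the *reference* geometry and reused for shifted data — this
is deliberate: the online algorithm cannot know the actual anatomy, and the
resulting bias (recovered shift smaller than implemented, slope below one)
is a property of the method, not a defect to be repaired by rebuilding maps.

Two numerical choices deserve note. First, a map cannot be non-monotone for
any physical placement — the proton's $1/v$ always exceeds $1/c$, the
largest possible $|dT_{PG}/dx|$ — but the builder still verifies
monotonicity and refuses with a diagnostic naming the offending interval
rather than guessing. Second, beyond the stopping depth the proton is at
rest and the raw map would be nearly flat wherever the gamma flight term is
stationary, making the margin non-invertible: time-jittered fall-off events
would pile up at the boundary. The map is therefore continued linearly with
the mean total-TOF slope over the last 1.5 cm before the stopping point —
the scale over which resolution blur actually spreads reconstructed edge
content — with a 4 cm margin. Out-of-range TOFs are kept and flagged, never
dropped silently, so count bookkeeping survives; they are excluded from
fall-off fitting.

With this estimator the recovered-versus-implemented shift slope converges
to ≈ 0.6 in the 63 MeV geometry. The bias direction and its origin (the
$T_p$ term frozen at reference conditions) match the experimental analysis;
the exact value depends on the local map slope at the fall-off and on the
reconstruction algorithm, so only the band (0.5, 1) is asserted.

Backgrounds that are flat in TOF do not stay flat in space: the inversion
imprints the map's Jacobian, $dN/dx \propto d\mathrm{TOF}/dx$. The spatial
background model is therefore built by pushing uniform TOF samples through
the same inversion, then fitted (single amplitude, least squares on an
off-signal region) and subtracted. For PGT the flat level is estimated from
an off-signal TOF window and subtracted directly. PGT subtraction precedes
the shift measurement; PGTI subtraction operates in the space domain, since
the event-by-event setting assumes the background level is unknown at
reconstruction time.

## The fall-off shift statistic and its errors

Profiles are compared through their normalised cumulative functions:
$x_{ref}$ is the distal maximum of the simulated reference profile (the
histogram maximum within the distal half of its support — the distal peak
precedes the fall-off), $y_{ref}$ the reference cumulative level there, and

$$d = F^{-1}(y_{ref}) - x_{ref}$$

with linear inverse interpolation. Integrating first filters bin noise and
makes no assumption about profile shape; the statistic is invariant under
count rescaling and recovers pure translations to within one bin (50 ps
time bins, 0.5 cm space bins by default, both configurable).

Statistical errors use toy experiments: sub-samples drawn *without*
replacement (sizes 30–135 in steps of 15, 5000 toys per size — kept small
relative to the parent sample to limit their statistical dependency), the
per-size spread taken as the sample standard deviation (a MAD-based
alternative sits behind a flag), and a one-parameter least-squares fit of
$\sigma(N) = k/\sqrt{N}$ through the origin extrapolated to the target
statistics. The two-sigma error is twice the one-sigma error by
construction. On the 63 MeV conditions (315 ps FWHM, 600 accepted PGs per
profile) this machinery yields a two-sigma range-shift error below 4 mm —
the acceptance script recomputes it end to end.

## Counting-statistics models

Three closed forms round out the analysis: the random-coincidence rate
$DCR_{coinc} = f_{dia} \times DCR_{SiPM} \times 2\tau$ (with
$f_{dia} = \lambda \times$ bunch rate, the small-λ trigger rate and the
arithmetic used experimentally); the effective-intensity estimator
$\hat\lambda = P(1)/P(0)$; and the single-proton-regime delivery time
$t = N_p / (r \, (1 - e^{-\lambda}))$, counting non-empty (taggable)
bunches at rate $r$ — the duty-cycle-weighted bunch rate for a pulsed
machine (0.8% duty cycle gives $5\times10^5$ bunches/s for the
synchro-cyclotron versus 25 MHz for the cyclotron). At λ = 1 this
reproduces both published delivery-time figures (0.63 s and 31.6 s for
$10^7$ protons).

## Problem sizes and open choices

The bundled analyses use 20 000-event simulated references, 600-event
measured profiles (the experimental statistics), and the full 5000-toy
bootstrap; property tests that estimate the PGTI slope run at 2000–4000
events per shift so the regression noise does not dominate the band check.
Detector distances in the 148 MeV two-detector setup are not recorded in
the experimental description; the preset uses representative values (25 cm
upstream at 157°, 15 cm at 90°), so the absolute PG-delay spans of that
setup are illustrative only. The monitor-coverage fraction is exposed as a
free parameter (the record quotes ≈ 20% while the intensity ratio implies
≈ 17%); the preset uses 0.2. Fit ranges and binnings for the resolution
fits are configuration values, not inferred from data.
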