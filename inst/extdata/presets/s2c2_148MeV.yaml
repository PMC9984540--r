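# 148 MeV pulsed synchro-cyclotron run: thick stopping PMMA target, two
# Cherenkov modules, one upstream (157 degrees) and one at the Bragg peak
# (90 degrees). Detector distances are not constrained by the experimental
# record; representative values are used.
name: s2c2_148MeV
seed: 148148
beam:
  energy_MeV: 148
  lambda_p_per_bunch: 0.78
  monitor_coverage: 0.2        # diamond covers ~20% of the beam spot
accelerator:
  bunch_period_ns: 16
  bunch_width_ns: 8
  pulse_width_us: 8
  pulse_period_ms: 1
geometry:
  slabs:
    - material: pmma
      thickness_cm: 23.0
range_model:
  alpha: 0.0022
  p: 1.77
  anchor_energy_MeV: 148
  anchor_range_cm: 13.4
  pmma_density: 1.19
monitor:
  time_resolution_fwhm_ps: 360
detectors:
  - id: detA
    angle_deg: 157
    distance_cm: 25
    anchor: entrance
    face_area_cm2: 2.0
    time_resolution_fwhm_ps: 167
    threshold_pe: 10
    dark_count_rate_hz: 0     # threshold high enough to cut dark counts
    pe_excess_mean: 11
  - id: detB
    angle_deg: 90
    distance_cm: 15
    anchor: bragg_peak
    face_area_cm2: 2.0
    time_resolution_fwhm_ps: 167
    threshold_pe: 10
    dark_count_rate_hz: 0
    pe_excess_mean: 11
emission:
  rise: 0.6
  falloff_retract_cm: 0.1
  falloff_sigma_cm: 0.08
spectrum:
  lines_MeV: [4.44, 6.13]
  line_weights: [0.25, 0.15]
  continuum_range_MeV: [2.0, 7.0]
  continuum_decay_MeV: 3.0
analysis:
  tof_binwidth_ps: 50
  space_binwidth_cm: 0.5
  tof_window_ps: [0, 4000]
  off_signal_window_ps: [3200, 4000]
  off_signal_region_cm: [14.0, 14.9]
  coincidence_window_ns: 15
backgrounds:
  scatter:
    enabled: false
    fraction: 0.05
    monitor_upstream_cm: 5.0
    width_fwhm_ps: 400
bootstrap:
  n_toys: 5000
  subsample_min: 30
  subsample_max: 135
  subsample_step: 15
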