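# 63 MeV cyclotron run: two-target PMMA phantom with a 3 cm air cavity,
# one Cherenkov module at 90 degrees / 14 cm facing the Bragg-peak region.
name: medicyc_63MeV
seed: 63063
beam:
  energy_MeV: 63
  lambda_p_per_bunch: 0.025
  monitor_coverage: 1.0        # collimated beam fully within the diamond
accelerator:
  bunch_period_ns: 40
  bunch_width_ns: 4
geometry:
  slabs:
    - material: pmma
      thickness_cm: 1.0
    - material: air
      thickness_cm: 3.0
    - material: pmma
      thickness_cm: 23.0
range_model:
  alpha: 0.0022
  p: 1.77
  anchor_energy_MeV: 148
  anchor_range_cm: 13.4
  pmma_density: 1.19
monitor:
  time_resolution_fwhm_ps: 156
detectors:
  - id: det90
    angle_deg: 90
    distance_cm: 14
    anchor: bragg_peak
    face_area_cm2: 1.0
    # module resolution chosen so that quadrature with the 156 ps monitor
    # reproduces the 315 ps system response
    time_resolution_fwhm_ps: 273.7
    threshold_pe: 6
    dark_count_rate_hz: 302
    pe_excess_mean: 1.5
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
  tof_window_ps: [0, 2200]
  off_signal_window_ps: [1700, 2200]
  off_signal_region_cm: [6.5, 7.45]
  coincidence_window_ns: 20
backgrounds:
  scatter:
    enabled: false
    fraction: 0.05
    monitor_upstream_cm: 2.0
    width_fwhm_ps: 300
bootstrap:
  n_toys: 5000
  subsample_min: 30
  subsample_max: 135
  subsample_step: 15
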