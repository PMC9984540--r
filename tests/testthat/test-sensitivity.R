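test_that("counting-statistics formulas agree with hand arithmetic", {
  expect_equal(random_coincidence_rate(625e3, 302, 20e-9), 3.775)
  expect_equal(random_coincidence_rate(0, 302, 20e-9), 0)
  # linear in each factor
  expect_equal(random_coincidence_rate(2 * 625e3, 302, 20e-9),
               2 * random_coincidence_rate(625e3, 302, 20e-9))
  expect_error(random_coincidence_rate(-1, 302, 20e-9), "non-negative")

  expect_equal(poisson_lambda(1000, 25), 0.025)
  expect_equal(poisson_lambda(500, 0), 0)
  expect_error(poisson_lambda(0, 5), "undefined")

  expect_equal(spr_delivery_time(1e7, 25e6, 1), 1e7 / (25e6 * (1 - exp(-1))))
  expect_equal(spr_delivery_time(1e7, 25e6, 1), 0.6328, tolerance = 1e-4)
  expect_equal(spr_delivery_time(1e7, 5e5, 1), 31.64, tolerance = 1e-3)
  # every bunch is occupied in the high-intensity limit
  expect_equal(spr_delivery_time(1e7, 25e6, 50), 1e7 / 25e6, tolerance = 1e-9)
  expect_error(spr_delivery_time(1e7, 0, 1), "positive")

  expect_equal(quadratic_difference(397, 360), sqrt(397^2 - 360^2))
  expect_equal(quadratic_difference(397, 360), 167.4, tolerance = 1e-3)
  expect_equal(quadratic_difference(315, 0), 315)
  expect_equal(quadratic_difference(315, 156), 273.7, tolerance = 1e-3)
  expect_error(quadratic_difference(100, 100), "strictly smaller")
})

test_that("bootstrap errors follow the k over sqrt(N) law", {
  cfg <- medicyc_cfg()
  ref <- generate_dataset(cfg, 20000, seed = 50)
  window <- cfg$analysis$tof_window_ps
  edges <- seq(window[1], window[2], by = cfg$analysis$tof_binwidth_ps)
  reference <- hist1d(ref$tof_ps, edges = edges)
  ev <- generate_dataset(cfg, 3000, seed = 51)
  be <- bootstrap_shift_error(ev$tof_ps, reference,
                              bootstrap_spec(n_toys = 600, target_n = 600),
                              seed = 52)
  expect_equal(be$sigma2, 2 * be$sigma1)
  expect_true(all(be$sizes$sigma > 0))
  # free power-law fit on the per-size spreads has exponent near -1/2
  pw <- stats::lm(log(sigma) ~ log(N), data = be$sizes)
  expect_lt(abs(stats::coef(pw)[2] + 0.5), 0.15)
  # errors shrink with subsample size
  expect_lt(be$sizes$sigma[nrow(be$sizes)], be$sizes$sigma[1])
  # residuals of the k/sqrt(N) fit show no systematic sign trend
  resid <- be$sizes$sigma - be$k / sqrt(be$sizes$N)
  n_pos <- sum(resid > 0)
  expect_gte(n_pos, 1)
  expect_lte(n_pos, nrow(be$sizes) - 1)
  expect_error(
    bootstrap_shift_error(ev$tof_ps[1:100], reference,
                          bootstrap_spec(n_toys = 100, target_n = 600)),
    "more events")
})

test_that("extrapolated errors match directly measured spreads", {
  cfg <- medicyc_cfg()
  ref <- generate_dataset(cfg, 20000, seed = 60)
  window <- cfg$analysis$tof_window_ps
  edges <- seq(window[1], window[2], by = cfg$analysis$tof_binwidth_ps)
  reference <- hist1d(ref$tof_ps, edges = edges)
  ev <- generate_dataset(cfg, 4000, seed = 61)
  small <- bootstrap_shift_error(
    ev$tof_ps, reference,
    bootstrap_spec(n_toys = 800, target_n = 1200), seed = 62)
  # measure the toy spread directly at the target size
  direct <- bootstrap_shift_error(
    ev$tof_ps, reference,
    bootstrap_spec(n_toys = 800, subsample_sizes = 1200, target_n = 1200),
    seed = 63)
  expect_equal(small$sigma1, direct$sizes$sigma[1], tolerance = 0.25)
  # ten-fold statistics shrink the extrapolated error by sqrt(10)
  big <- bootstrap_shift_error(
    ev$tof_ps, reference,
    bootstrap_spec(n_toys = 800, target_n = 12000), seed = 62)
  expect_equal(small$sigma1 / big$sigma1, sqrt(10), tolerance = 1e-9)
})

test_that("robust spread estimator stays close to the standard one", {
  cfg <- medicyc_cfg()
  ref <- generate_dataset(cfg, 20000, seed = 70)
  edges <- seq(0, 2200, 50)
  reference <- hist1d(ref$tof_ps, edges = edges)
  ev <- generate_dataset(cfg, 1000, seed = 71)
  spec <- bootstrap_spec(n_toys = 400, target_n = 600)
  sd_est <- bootstrap_shift_error(ev$tof_ps, reference, spec, seed = 72)
  mad_est <- bootstrap_shift_error(ev$tof_ps, reference, spec, seed = 72,
                                   estimator = "mad")
  expect_equal(mad_est$sigma1 / sd_est$sigma1, 1, tolerance = 0.3)
})

test_that("PGT sensitivity scan tracks the implemented shift at the exit speed", {
  cfg <- medicyc_cfg()
  scan <- sensitivity_scan(cfg, shifts_cm = c(0, 0.2, 0.4, 0.6, 1.0),
                           n_events_per_shift = 2000, mode = "pgt", seed = 30,
                           spec = bootstrap_spec(n_toys = 400, target_n = 2000))
  expect_equal(scan$units[1], "ps")
  # the zero-shift measurement is consistent with zero
  expect_lt(abs(scan$d[scan$shift_cm == 0]), 2 * scan$sigma2[1])
  slope <- stats::coef(stats::lm(d ~ shift_cm, data = scan))[2]
  model_slope <- attr(scan, "exit_inverse_speed_ps_per_cm")
  expect_equal(as.numeric(slope), model_slope, tolerance = 0.12)
  expect_error(sensitivity_scan(cfg, shifts_cm = c(0.2, 0.4)),
               "must include 0")
})

test_that("PGTI reconstruction with reference maps under-reports the shift", {
  cfg <- medicyc_cfg()
  scan <- sensitivity_scan(cfg, shifts_cm = seq(0, 1, 0.25),
                           n_events_per_shift = 3000, mode = "pgti",
                           seed = 31,
                           spec = bootstrap_spec(n_toys = 300,
                                                 target_n = 3000))
  expect_equal(scan$units[1], "cm")
  slope <- as.numeric(stats::coef(stats::lm(d ~ shift_cm, data = scan))[2])
  expect_gt(slope, 0.5)
  expect_lt(slope, 1.0)
})

test_that("a detector position error propagates into a profile offset", {
  reco <- medicyc_reco()
  set.seed(33)
  x <- sample_emission(pg_emission_profile(reco$map), 20000)
  tof <- forward_tof(x, reco$det, reco$map,
                     detector_fwhm_ps = 273.7, monitor_fwhm_ps = 156)
  edges <- seq(0, 10, 0.25)
  offsets <- c(0, 0.5, 1.0)
  profiles <- lapply(offsets, function(dy) {
    det2 <- reco$det
    det2$position[2] <- det2$position[2] + dy  # wrong assumed distance
    rm2 <- build_reference_map(reco$map, det2)
    rec <- invert_tof(tof, rm2)
    hist1d(rec$x_rec[rec$in_range], edges = edges)
  })
  shifts <- vapply(profiles, function(p)
    falloff_shift(p, profiles[[1]])$d, numeric(1))
  # monotone response of the same order as the perturbation (the gamma
  # flight-time error delta/c maps through the ~150 ps/cm local slope)
  expect_true(all(diff(abs(shifts)) > 0))
  expect_true(all(diff(shifts) > 0) || all(diff(shifts) < 0))
  expect_gt(abs(shifts[3]), 0.05)
  expect_lt(abs(shifts[3]), 1.0)
})
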