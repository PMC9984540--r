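test_that("bunch occupancy is Poisson with recoverable intensity", {
  expect_true(all(sample_bunch_occupancy(0, 1000, seed = 1) == 0))
  occ <- sample_bunch_occupancy(0.78, 1e6, seed = 2)
  se <- sqrt(0.78 / 1e6)
  expect_lt(abs(mean(occ) - 0.78), 3 * se)
  # the one-to-zero bunch ratio estimates lambda
  lam <- poisson_lambda(sum(occ == 0), sum(occ == 1))
  expect_lt(abs(lam - 0.78), 0.01)
  expect_identical(sample_bunch_occupancy(0.5, 100, seed = 7),
                   sample_bunch_occupancy(0.5, 100, seed = 7))
  expect_error(sample_bunch_occupancy(-0.1, 10), "non-negative")
})

test_that("lambda estimator is consistent at both experimental intensities", {
  for (lam in c(0.025, 0.78)) {
    est <- replicate(200, {
      occ <- stats::rpois(20000, lam)
      poisson_lambda(sum(occ == 0), sum(occ == 1))
    })
    se <- stats::sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - lam), 3 * se + 1e-4)
  }
})

test_that("emission profile is a proper density with a distal fall-off", {
  reco <- medicyc_reco()
  prof <- pg_emission_profile(reco$map)
  expect_true(all(prof$density >= 0))
  expect_equal(sum(prof$density) * prof$grid_step, 1, tolerance = 1e-9)
  expect_true(all(prof$density[prof$x > prof$range_end] == 0))
  # no emission inside the air gap
  expect_true(all(prof$density[prof$x > 1.01 & prof$x < 3.99] == 0))
  # fall-off midpoint (half of the pre-fall-off level) near the range end
  plateau <- prof$density[which.min(abs(prof$x - (prof$range_end - 0.5)))]
  distal <- prof$x > prof$range_end - 1
  xs <- prof$x[distal]
  cross <- xs[which(prof$density[distal] < plateau / 2)[1]]
  expect_lt(abs(cross - prof$range_end), 0.2)
})

test_that("detection probability is anchored, monotone, ordered in threshold", {
  expect_equal(detection_probability(2, 6), 0.05, tolerance = 1e-9)
  expect_equal(detection_probability(0, 3), 0)
  expect_equal(detection_probability(0, 9), 0)
  e <- seq(0, 10, 0.1)
  p3 <- detection_probability(e, 3)
  p6 <- detection_probability(e, 6)
  p9 <- detection_probability(e, 9)
  expect_true(all(p3 >= p6 & p6 >= p9))
  for (p in list(p3, p6, p9)) {
    expect_true(all(diff(p) >= 0))
    expect_true(all(p >= 0 & p <= 1))
  }
  # interpolated thresholds stay between the tabulated curves
  p45 <- detection_probability(e, 4.5)
  expect_true(all(p45 <= p3 + 1e-12 & p45 >= p6 - 1e-12))
})

test_that("forward TOF reproduces the deterministic flight-time geometry", {
  reco <- medicyc_reco()
  # vertex at the perpendicular foot, 14 cm away: T_PG = 14 cm / c
  x_foot <- reco$det$position[1]
  tof <- forward_tof(x_foot, reco$det, reco$map)
  t_pg <- tof - eval_time_map(reco$map, x_foot)
  expect_equal(t_pg, 14 / kinematic_constants$light_speed * 1000,
               tolerance = 1e-9)
  expect_equal(t_pg, 467, tolerance = 1e-3)
  # widening the air gap delays post-gap vertices by shift x inverse speed
  cfg <- reco$cfg
  s <- 0.6
  map_s <- proton_time_map(build_geometry(cfg, shift_cm = s),
                           cfg$beam$energy_MeV, model = reco$model)
  e_exit <- as.numeric(energy_at_depth(63, 1, "pmma", reco$model))
  x_post <- 5.0
  d_tof <- eval_time_map(map_s, x_post + s) - eval_time_map(reco$map, x_post)
  expect_equal(d_tof, s * inverse_speed(e_exit), tolerance = 1e-6)
  expect_error(forward_tof(reco$map$range_end + 1, reco$det, reco$map),
               "outside the time-map support")
})

test_that("dataset generation is reproducible with conserved labels", {
  cfg <- medicyc_cfg()
  a <- generate_dataset(cfg, 300, seed = 99)
  b <- generate_dataset(cfg, 300, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 300)
  expect_true(all(a$label == "signal"))
  s <- attr(a, "summary")
  expect_equal(s$n_signal + s$n_dark + s$n_random + s$n_scatter, nrow(a))
  # signal vertices live inside the proton range
  expect_true(all(a$true_vertex_x_cm >= 0 &
                    a$true_vertex_x_cm <= s$range_end_cm))
  empty <- generate_dataset(cfg, 0, seed = 1)
  expect_equal(nrow(empty), 0)
})

test_that("accepted fraction matches brute-force thinning", {
  reco <- medicyc_reco()
  prof <- pg_emission_profile(reco$map)
  det <- reco$det
  det$face_area_cm2 <- det$face_area_cm2 * 1000  # keep counts testable
  ana <- acceptance_fraction(prof, det)
  # brute force: emit candidates, thin by efficiency x solid angle
  set.seed(31)
  n <- 40000
  vx <- sample_emission(prof, n)
  en <- sample_pg_energy(n)
  w <- det$face_area_cm2 /
    (4 * pi * ((vx - det$position[1])^2 + det$position[2]^2))
  p <- detection_probability(en, det$threshold_pe) * w
  expect_lt(max(p), 1)
  acc <- mean(stats::runif(n) < p)
  se <- sqrt(ana$fraction * (1 - ana$fraction) / n)
  expect_lt(abs(acc - ana$fraction), 4 * se)
})

test_that("background injection matches the coincidence-rate model", {
  cfg <- medicyc_cfg()
  ev <- generate_dataset(cfg, 400, seed = 5)
  with_bg <- add_backgrounds(ev, cfg, livetime_s = 100, seed = 6)
  s <- attr(with_bg, "summary")
  # f_dia x DCR x 2tau x livetime = 625 kHz x 302 Hz x 20 ns x 100 s
  expect_equal(s$expected_dark, 625e3 * 302 * 20e-9 * 100, tolerance = 1e-9)
  n_dark <- sum(with_bg$label == "dark")
  expect_lt(abs(n_dark - s$expected_dark), 5 * sqrt(s$expected_dark))
  expect_equal(nrow(with_bg), s$n_signal + s$n_dark + s$n_random + s$n_scatter)
  # dark TOFs are flat over the analysis window
  dark <- with_bg$tof_ps[with_bg$label == "dark"]
  expect_gt(stats::ks.test(dark, "punif", cfg$analysis$tof_window_ps[1],
                           cfg$analysis$tof_window_ps[2])$p.value, 1e-4)
  # full coverage and zero dark rate leave the event list untouched
  cfg0 <- cfg
  cfg0$detectors[[1]]$dark_count_rate_hz <- 0
  ev0 <- generate_dataset(validate_config(unclass(cfg0)), 200, seed = 7)
  none <- add_backgrounds(ev0, validate_config(unclass(cfg0)),
                          livetime_s = 100, seed = 8)
  expect_equal(nrow(none), 200)
  expect_true(all(none$label == "signal"))
})

test_that("partial monitor coverage produces bunch-width random coincidences", {
  cfg <- s2c2_cfg()
  ev <- generate_dataset(cfg, 2000, seed = 12)
  with_bg <- add_backgrounds(ev, cfg, livetime_s = 10, seed = 13)
  rc <- with_bg$tof_ps[with_bg$label == "random_coincidence"]
  # expected count: n_signal (1 - coverage) / coverage with coverage 0.2
  expect_gt(length(rc), 2000 * 4 * 0.8)
  expect_lt(length(rc), 2000 * 4 * 1.2)
  bunch_sigma <- cfg$accelerator$bunch_width_ns * 1000 / sqrt(12)
  expect_equal(stats::sd(rc), bunch_sigma, tolerance = 0.05)
})
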