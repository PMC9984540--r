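test_that("reference map is monotone and anchored at the entrance flight time", {
  reco <- medicyc_reco()
  rm1 <- reco$ref_map
  expect_true(all(diff(rm1$tof_ps) > 0))
  # at x = 0 the proton term vanishes: pure gamma flight time to the detector
  d0 <- sqrt(sum(reco$det$position^2))
  expect_equal(rm1$tof_ps[1], d0 / kinematic_constants$light_speed * 1000,
               tolerance = 1e-9)
  # refinement leaves shared nodes unchanged
  fine <- build_reference_map(reco$map, reco$det, grid_step = 0.01)
  shared <- intersect(round(rm1$x, 9), round(fine$x, 9))
  expect_equal(rm1$tof_ps[match(shared, round(rm1$x, 9))],
               fine$tof_ps[match(shared, round(fine$x, 9))],
               tolerance = 1e-9)
})

test_that("TOF inversion interpolates linearly and flags out-of-range", {
  two_node <- structure(list(detector_id = "toy", x = c(0, 1),
                             tof_ps = c(500, 640), grid_step = 1,
                             range_end = 1),
                        class = "reference_time_map")
  rec <- invert_tof(c(570, 500, 640, 499, 641), two_node)
  expect_equal(rec$x_rec, c(0.5, 0, 1, 0, 1))
  expect_equal(rec$in_range, c(TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("zero-jitter forward model round-trips through the inversion", {
  reco <- medicyc_reco()
  set.seed(4)
  x <- runif(1000, 0, reco$map$range_end)
  tof <- forward_tof(x, reco$det, reco$map)
  rec <- invert_tof(tof, reco$ref_map)
  expect_true(all(rec$in_range))
  expect_lt(max(abs(rec$x_rec - x)), reco$ref_map$grid_step / 2)
})

test_that("dataset reconstruction preserves counts per detector", {
  cfg <- s2c2_cfg()
  ev <- generate_dataset(cfg, 1500, seed = 3)
  map <- attr(ev, "map")
  dets <- lapply(build_detectors(cfg), resolve_detector, map = map)
  names(dets) <- vapply(dets, `[[`, character(1), "id")
  maps <- lapply(dets, function(d) build_reference_map(map, d))
  rec <- reconstruct_dataset(ev, maps)
  expect_equal(nrow(rec), nrow(ev))
  expect_true(all(!is.na(rec$x_rec)))
  expect_equal(sum(rec$in_range) + sum(!rec$in_range), nrow(ev))
  # merged histogram equals the sum of the per-detector ones
  edges <- seq(0, 18, 0.5)
  merged <- hist1d(rec$x_rec[rec$in_range], edges = edges)
  per_det <- lapply(names(maps), function(id)
    hist1d(rec$x_rec[rec$in_range & rec$detector_id == id], edges = edges))
  expect_equal(merged$counts, Reduce(`+`, lapply(per_det, `[[`, "counts")))
  expect_error(reconstruct_dataset(ev, maps["detA"]), "no reference map")
})

test_that("detectors at different angles agree in space but not in time", {
  cfg <- s2c2_cfg()
  ev <- generate_dataset(cfg, 6000, seed = 11)
  map <- attr(ev, "map")
  dets <- lapply(build_detectors(cfg), resolve_detector, map = map)
  names(dets) <- vapply(dets, `[[`, character(1), "id")
  maps <- lapply(dets, function(d) build_reference_map(map, d))
  rec <- reconstruct_dataset(ev, maps)
  edges <- seq(0, 18, 0.5)
  pos <- vapply(names(maps), function(id)
    falloff_position(hist1d(rec$x_rec[rec$in_range & rec$detector_id == id],
                            edges = edges)), numeric(1))
  # reconstructed fall-off positions agree to within one spatial bin pair
  expect_lt(abs(diff(pos)), 1.0)
  # while the raw TOF distributions are far apart
  tof_means <- vapply(names(maps), function(id)
    mean(ev$tof_ps[ev$detector_id == id]), numeric(1))
  expect_gt(abs(diff(tof_means)), 200)
})

test_that("single detector with zero jitter reproduces the emission profile", {
  reco <- medicyc_reco()
  prof <- pg_emission_profile(reco$map)
  set.seed(8)
  w <- pgti:::.solid_angle_weight(prof$x, reco$det)
  x <- sample_emission(prof, 20000)
  tof <- forward_tof(x, reco$det, reco$map)
  rec <- invert_tof(tof, reco$ref_map)
  edges <- seq(0, 6.5, 0.25)
  h_rec <- hist1d(rec$x_rec[rec$in_range], edges = edges)
  h_true <- hist1d(x, edges = edges)
  expect_lt(max(abs(h_rec$counts - h_true$counts)), 40)  # binning edge effects
})

test_that("flat-TOF background reconstructs with the inverse-map Jacobian", {
  # linear map: uniform TOF stays uniform in space
  lin <- structure(list(detector_id = "lin", x = seq(0, 10, 0.1),
                        tof_ps = 500 + 40 * seq(0, 10, 0.1),
                        grid_step = 0.1, range_end = 10),
                   class = "reference_time_map")
  edges <- seq(0, 10, 0.5)
  tpl <- background_template(lin, c(500, 900), edges = edges,
                             n_samples = 2e5, seed = 2)
  expect_equal(sum(tpl$counts * diff(tpl$edges)), 1, tolerance = 1e-9)
  expect_lt(stats::sd(tpl$counts) / mean(tpl$counts), 0.05)
  expect_identical(tpl$counts,
                   background_template(lin, c(500, 900), edges = edges,
                                       n_samples = 2e5, seed = 2)$counts)
  # a doubled map slope compresses the same TOF span into half the space,
  # doubling the local template density (dN/dx = const x dTOF/dx)
  kink_x <- seq(0, 10, 0.1)
  kink_t <- 500 + ifelse(kink_x <= 5, 40 * kink_x, 200 + 80 * (kink_x - 5))
  kink <- structure(list(detector_id = "kink", x = kink_x, tof_ps = kink_t,
                         grid_step = 0.1, range_end = 10),
                    class = "reference_time_map")
  tpl2 <- background_template(kink, c(500, 1100), edges = edges,
                              n_samples = 4e5, seed = 3)
  lo <- mean(tpl2$counts[bin_centers(tpl2) < 5])
  hi <- mean(tpl2$counts[bin_centers(tpl2) > 5])
  expect_equal(hi / lo, 2, tolerance = 0.05)
  expect_error(background_template(lin, c(700, 700), edges = edges),
               "degenerate")
})
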