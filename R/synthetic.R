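#' Prompt-gamma detector module description
#'
#' A Cherenkov detection module (PbF2 crystal on a SiPM) characterised by its
#' placement, active area, time resolution, photoelectron threshold,
#' energy-dependent intrinsic efficiency and dark count rate. Placement is
#' given as an angle from the beam direction plus a distance from a named
#' anchor (target entrance or Bragg-peak depth) and resolved to coordinates
#' once the proton time map, hence the stopping depth, is known.
#'
#' @param id Detector identifier (string).
#' @param angle_deg Angle from the beam (+x) direction in degrees; 90 is
#'   perpendicular, >90 looks upstream.
#' @param distance_cm Distance from the anchor point in cm.
#' @param anchor `"bragg_peak"` or `"entrance"`.
#' @param face_area_cm2 Crystal face area in cm^2.
#' @param time_resolution_fwhm_ps Module time resolution (FWHM, ps).
#' @param threshold_pe Acquisition threshold in photoelectrons.
#' @param efficiency_params Per-threshold sigmoid+linear coefficients, see
#'   [default_efficiency_params()].
#' @param dark_count_rate_hz SiPM dark count rate above threshold, Hz.
#' @param pe_excess_mean Mean number of photoelectrons detected above
#'   threshold (Poisson), used to emulate the charge spectrum.
#' @return An object of class `detector_module`.
#' @export
detector_module <- function(id, angle_deg, distance_cm,
                            anchor = c("bragg_peak", "entrance"),
                            face_area_cm2 = 1,
                            time_resolution_fwhm_ps = 273.7,
                            threshold_pe = 6,
                            efficiency_params = default_efficiency_params(),
                            dark_count_rate_hz = 302,
                            pe_excess_mean = 1.5) {
  anchor <- match.arg(anchor)
  stopifnot(distance_cm > 0, face_area_cm2 > 0,
            time_resolution_fwhm_ps > 0, threshold_pe >= 0,
            dark_count_rate_hz >= 0)
  structure(list(id = id, angle_deg = angle_deg, distance_cm = distance_cm,
                 anchor = anchor, face_area_cm2 = face_area_cm2,
                 time_resolution_fwhm_ps = time_resolution_fwhm_ps,
                 threshold_pe = threshold_pe,
                 efficiency_params = efficiency_params,
                 dark_count_rate_hz = dark_count_rate_hz,
                 pe_excess_mean = pe_excess_mean,
                 position = NULL),
            class = "detector_module")
}

#' Resolve a detector's position in beam coordinates
#'
#' @param detector A [detector_module()].
#' @param map A [proton_time_map()] (supplies the Bragg-peak depth).
#' @return The detector with `$position` set to a 3-vector (cm); the beam
#'   runs along +x and the detector lies in the x-y plane.
#' @export
resolve_detector <- function(detector, map) {
  stopifnot(inherits(detector, "detector_module"),
            inherits(map, "proton_time_map"))
  x0 <- if (detector$anchor == "bragg_peak") map$range_end else 0
  th <- detector$angle_deg * pi / 180
  detector$position <- c(x0 + detector$distance_cm * cos(th),
                         detector$distance_cm * sin(th), 0)
  detector
}

#' Default intrinsic-efficiency coefficients
#'
#' Sigmoid-plus-linear parametrisation of the module's intrinsic detection
#' probability versus prompt-gamma energy, one coefficient set per supported
#' photoelectron threshold (3, 6, 9 p.e.). The 6 p.e. curve is anchored to a
#' 5% detection probability at 2 MeV and saturates near 0.24 above 8 MeV;
#' the 3 and 9 p.e. curves bracket it from above and below. The probability
#' is zero at zero energy by construction.
#'
#' @return A data frame with columns `threshold_pe`, `amplitude`, `e_mid`,
#'   `width`, `linear`.
#' @export
default_efficiency_params <- function() {
  # 6 p.e. amplitude solved so the curve passes through (2 MeV, 0.05)
  a6 <- (0.05 - 0.002 * 2) /
    (stats::plogis((2 - 3.0) / 0.8) - stats::plogis(-3.0 / 0.8))
  data.frame(
    threshold_pe = c(3, 6, 9),
    amplitude    = c(0.26, a6, 0.17),
    e_mid        = c(2.2, 3.0, 3.8),
    width        = c(0.8, 0.8, 0.9),
    linear       = c(0.002, 0.002, 0.0015)
  )
}

.efficiency_curve <- function(energy, row) {
  base <- stats::plogis(-row$e_mid / row$width)
  p <- row$amplitude *
    (stats::plogis((energy - row$e_mid) / row$width) - base) +
    row$linear * energy
  pmin(pmax(p, 0), 1)
}

#' Intrinsic detection probability of a prompt gamma
#'
#' Probability that a prompt gamma of the given energy produces more than
#' `threshold_pe` photoelectrons in the module. Non-decreasing in energy and
#' non-increasing in threshold; thresholds between the tabulated ones are
#' linearly interpolated on the probability.
#'
#' @param energy Gamma energy in MeV (vectorised).
#' @param threshold_pe Acquisition threshold in photoelectrons.
#' @param params Coefficient table, see [default_efficiency_params()].
#' @return Detection probability in \[0, 1\].
#' @examples
#' detection_probability(2, 6)  # 0.05 by calibration
#' @export
detection_probability <- function(energy, threshold_pe = 6,
                                  params = default_efficiency_params()) {
  if (any(energy < 0)) stop("energy must be non-negative")
  stopifnot(threshold_pe >= 0)
  thr <- params$threshold_pe
  if (threshold_pe <= min(thr)) return(.efficiency_curve(energy, params[which.min(thr), ]))
  if (threshold_pe >= max(thr)) return(.efficiency_curve(energy, params[which.max(thr), ]))
  i <- findInterval(threshold_pe, thr)
  if (thr[i] == threshold_pe) return(.efficiency_curve(energy, params[i, ]))
  w <- (threshold_pe - thr[i]) / (thr[i + 1] - thr[i])
  (1 - w) * .efficiency_curve(energy, params[i, ]) +
    w * .efficiency_curve(energy, params[i + 1, ])
}

#' Prompt-gamma emission profile along the beam axis
#'
#' Normalised vertex density of prompt-gamma emission: zero in air and beyond
#' the stopping depth, rising slowly with depth in PMMA (the non-elastic
#' cross-section grows as the proton slows) and falling off through a logistic
#' edge whose midpoint sits `falloff_retract_cm` upstream of the stopping
#' depth.
#'
#' @param map A [proton_time_map()] carrying the geometry and stopping depth.
#' @param rise Fractional rise of the emission density over the proton path.
#' @param falloff_retract_cm Distance between the fall-off midpoint and the
#'   stopping depth, cm.
#' @param falloff_sigma_cm Logistic width of the fall-off edge, cm.
#' @param grid_step Grid spacing in cm.
#' @return Object of class `pg_emission_profile`: list with `x`, `density`
#'   (integrates to 1), `falloff_midpoint`, `range_end`.
#' @export
pg_emission_profile <- function(map, rise = 0.6, falloff_retract_cm = 0.1,
                                falloff_sigma_cm = 0.08, grid_step = 0.02) {
  stopifnot(inherits(map, "proton_time_map"), grid_step > 0,
            falloff_sigma_cm > 0, falloff_retract_cm >= 0)
  geom <- map$geometry
  x <- seq(0, map$range_end, by = grid_step)
  in_pmma <- rep(FALSE, length(x))
  depth <- numeric(length(x))
  cum <- 0
  for (i in seq_len(nrow(geom))) {
    sel <- x >= geom$x_from[i] & x <= min(geom$x_to[i], map$range_end)
    if (geom$material[i] != "air") {
      in_pmma[sel] <- TRUE
      depth[sel] <- cum + (x[sel] - geom$x_from[i])
      cum <- cum + min(geom$thickness[i], map$range_end - geom$x_from[i])
    }
  }
  x_mid <- map$range_end - falloff_retract_cm
  dens <- ifelse(in_pmma,
                 (1 + rise * depth / max(depth)) *
                   stats::plogis((x_mid - x) / falloff_sigma_cm),
                 0)
  dens <- dens / (sum(dens) * grid_step)
  structure(list(x = x, density = dens, falloff_midpoint = x_mid,
                 range_end = map$range_end, grid_step = grid_step),
            class = "pg_emission_profile")
}

#' Sample vertex positions from an emission profile
#'
#' Inverse-CDF sampling on the profile grid, optionally re-weighted by a
#' position-dependent acceptance (e.g. a solid-angle factor).
#'
#' @param profile A [pg_emission_profile()].
#' @param n Number of vertices.
#' @param weight Optional non-negative weights on `profile$x`.
#' @param seed Optional RNG seed.
#' @return Vertex positions in cm.
#' @export
sample_emission <- function(profile, n, weight = NULL, seed = NULL) {
  stopifnot(inherits(profile, "pg_emission_profile"), n >= 0)
  dens <- profile$density
  if (!is.null(weight)) {
    stopifnot(length(weight) == length(dens), all(weight >= 0))
    dens <- dens * weight
  }
  cdf <- cumsum(dens)
  cdf <- cdf / cdf[length(cdf)]
  with_seed(seed, {
    u <- stats::runif(n)
    idx <- findInterval(u, cdf) + 1
    idx <- pmin(idx, length(profile$x))
    # jitter uniformly within the grid cell, clamped to the support
    v <- profile$x[idx] + (stats::runif(n) - 0.5) * profile$grid_step
    pmin(pmax(v, 0), profile$range_end)
  })
}

#' Default prompt-gamma energy spectrum parameters
#'
#' Mixture of the 4.44 MeV (carbon) and 6.13 MeV (oxygen) de-excitation
#' lines over an exponential continuum on 2-7 MeV.
#'
#' @return A list with `lines_MeV`, `line_weights`, `continuum_range_MeV`,
#'   `continuum_decay_MeV`.
#' @export
default_spectrum_params <- function() {
  list(lines_MeV = c(4.44, 6.13), line_weights = c(0.25, 0.15),
       continuum_range_MeV = c(2, 7), continuum_decay_MeV = 3)
}

#' Sample prompt-gamma energies
#'
#' @param n Number of draws.
#' @param params Spectrum parameters, see [default_spectrum_params()].
#' @param seed Optional RNG seed.
#' @return Energies in MeV.
#' @export
sample_pg_energy <- function(n, params = default_spectrum_params(),
                             seed = NULL) {
  w_line <- sum(params$line_weights)
  stopifnot(w_line < 1, all(params$line_weights >= 0))
  with_seed(seed, {
    comp <- stats::runif(n)
    e <- numeric(n)
    br <- cumsum(params$line_weights)
    for (i in seq_along(params$lines_MeV)) {
      lo <- if (i == 1) 0 else br[i - 1]
      e[comp >= lo & comp < br[i]] <- params$lines_MeV[i]
    }
    cont <- comp >= w_line
    m <- sum(cont)
    if (m) {
      r <- params$continuum_range_MeV
      s <- params$continuum_decay_MeV
      u <- stats::runif(m)
      # inverse CDF of truncated exponential on [r1, r2]
      e[cont] <- r[1] - s * log(1 - u * (1 - exp(-(r[2] - r[1]) / s)))
    }
    e
  })
}

#' Forward TOF model for a prompt-gamma vertex
#'
#' The measured coincidence time decomposes as
#' `TOF = T_p(r_v) + T_PG(r_v, r_d)`: the proton arrival time at the vertex
#' plus the gamma flight time to the detector, smeared by the detector and
#' beam-monitor Gaussian jitters and an optional uniform smear (e.g. the
#' residual bunch width). With all jitters zero the value is deterministic.
#'
#' @param vertex_x Vertex positions in cm (within the time-map support).
#' @param detector A resolved [detector_module()] (with `$position`).
#' @param map A [proton_time_map()].
#' @param detector_fwhm_ps,monitor_fwhm_ps Gaussian jitters, FWHM in ps.
#' @param uniform_width_ps Width of an additional uniform smear in ps.
#' @param seed Optional RNG seed.
#' @return TOF values in ps.
#' @export
forward_tof <- function(vertex_x, detector, map,
                        detector_fwhm_ps = 0, monitor_fwhm_ps = 0,
                        uniform_width_ps = 0, seed = NULL) {
  stopifnot(inherits(map, "proton_time_map"))
  if (is.null(detector$position))
    stop("detector position unresolved; call resolve_detector() first")
  if (any(vertex_x < 0 | vertex_x > map$range_end + 1e-9))
    stop("vertex outside the time-map support [0, range_end]")
  tp <- eval_time_map(map, vertex_x)
  d <- sqrt((vertex_x - detector$position[1])^2 +
              detector$position[2]^2 + detector$position[3]^2)
  tpg <- d / kinematic_constants$light_speed * 1000
  n <- length(vertex_x)
  with_seed(seed, {
    jit <- 0
    if (detector_fwhm_ps > 0)
      jit <- jit + stats::rnorm(n, 0, fwhm_to_sigma(detector_fwhm_ps))
    if (monitor_fwhm_ps > 0)
      jit <- jit + stats::rnorm(n, 0, fwhm_to_sigma(monitor_fwhm_ps))
    if (uniform_width_ps > 0)
      jit <- jit + stats::runif(n, -uniform_width_ps / 2, uniform_width_ps / 2)
    tp + tpg + jit
  })
}

#' Poisson bunch occupancy
#'
#' Number of protons per accelerator bunch under single-proton-regime
#' delivery: independent Poisson draws with mean `lambda`.
#'
#' @param lambda Mean protons per bunch (>= 0).
#' @param n_bunches Number of bunches.
#' @param seed Optional RNG seed.
#' @return Integer vector of occupancies.
#' @export
sample_bunch_occupancy <- function(lambda, n_bunches, seed = NULL) {
  if (lambda < 0) stop("lambda must be non-negative")
  stopifnot(n_bunches >= 1)
  with_seed(seed, stats::rpois(n_bunches, lambda))
}

.solid_angle_weight <- function(x, detector) {
  d2 <- (x - detector$position[1])^2 + detector$position[2]^2 +
    detector$position[3]^2
  detector$face_area_cm2 / (4 * pi * d2)
}

#' Analytic acceptance fraction of generated prompt gammas
#'
#' Expected fraction of emitted prompt gammas that are detected: the
#' emission-weighted mean solid-angle factor times the spectrum-weighted mean
#' intrinsic detection probability.
#'
#' @param profile A [pg_emission_profile()].
#' @param detector A resolved [detector_module()].
#' @param spectrum Spectrum parameters, see [default_spectrum_params()].
#' @return A list with `solid_angle`, `mean_efficiency` and their product
#'   `fraction`.
#' @export
acceptance_fraction <- function(profile, detector,
                                spectrum = default_spectrum_params()) {
  w <- .solid_angle_weight(profile$x, detector)
  omega <- sum(profile$density * w) * profile$grid_step
  # spectrum mean of the efficiency: lines exactly, continuum on a fine grid
  r <- spectrum$continuum_range_MeV
  s <- spectrum$continuum_decay_MeV
  eg <- seq(r[1], r[2], length.out = 501)
  cd <- exp(-(eg - r[1]) / s)
  cd <- cd / sum(cd)
  w_line <- spectrum$line_weights
  eff <- sum(w_line * detection_probability(spectrum$lines_MeV,
                                            detector$threshold_pe,
                                            detector$efficiency_params)) +
    (1 - sum(w_line)) * sum(cd * detection_probability(
      eg, detector$threshold_pe, detector$efficiency_params))
  list(solid_angle = omega, mean_efficiency = eff, fraction = omega * eff)
}

.empty_events <- function() {
  data.frame(event_id = integer(), label = character(),
             detector_id = character(), true_vertex_x_cm = numeric(),
             true_energy_MeV = numeric(), tof_ps = numeric(),
             n_pe = integer(), stringsAsFactors = FALSE)
}

#' Generate a synthetic prompt-gamma event list
#'
#' Draws `n_signal_events` accepted signal events per the experiment
#' configuration: vertices from the emission profile re-weighted by the
#' solid-angle factor, energies from the prompt-gamma spectrum thinned by the
#' intrinsic detection probability, TOF stamps from the forward model with
#' the configured detector and monitor jitters. Identical seeds give
#' identical event tables. A generation summary (per-label counts and the
#' analytic acceptance fraction) is attached as attribute `summary`.
#'
#' @param config A validated experiment configuration, see [load_config()]
#'   or [pgti_preset()].
#' @param n_signal_events Number of accepted signal events (>= 0).
#' @param seed RNG seed (integer).
#' @param shift_cm Widening of the air cavity relative to the reference
#'   geometry, in cm (an implemented proton-range shift).
#' @return A `pgti_events` data frame with columns `event_id`, `label`,
#'   `detector_id`, `true_vertex_x_cm`, `true_energy_MeV`, `tof_ps`, `n_pe`.
#' @export
generate_dataset <- function(config, n_signal_events, seed,
                             shift_cm = 0) {
  stopifnot(inherits(config, "pgti_config"), n_signal_events >= 0)
  model <- build_range_model(config)
  geom <- build_geometry(config, shift_cm = shift_cm)
  map <- proton_time_map(geom, config$beam$energy_MeV, model = model)
  em <- config$emission
  profile <- pg_emission_profile(map, rise = em$rise,
                                 falloff_retract_cm = em$falloff_retract_cm,
                                 falloff_sigma_cm = em$falloff_sigma_cm)
  dets <- lapply(build_detectors(config), resolve_detector, map = map)
  acc <- lapply(dets, acceptance_fraction, profile = profile,
                spectrum = config$spectrum)
  fracs <- vapply(acc, `[[`, numeric(1), "fraction")

  events <- .empty_events()
  if (n_signal_events > 0) {
    alloc <- with_seed(sub_seed(seed, 0), {
      as.integer(stats::rmultinom(1, n_signal_events, fracs))
    })
    parts <- vector("list", length(dets))
    for (k in seq_along(dets)) {
      nk <- alloc[k]
      if (nk == 0) { parts[[k]] <- .empty_events(); next }
      det <- dets[[k]]
      sk <- sub_seed(seed, k)
      w <- .solid_angle_weight(profile$x, det)
      vx <- sample_emission(profile, nk, weight = w, seed = sk)
      en <- with_seed(sub_seed(seed, k + 100), {
        # rejection-sample energies against the detection probability
        out <- numeric(0)
        pmax_det <- max(detection_probability(
          seq(0, 10, 0.1), det$threshold_pe, det$efficiency_params))
        while (length(out) < nk) {
          cand <- sample_pg_energy(2 * nk + 50, config$spectrum)
          keep <- stats::runif(length(cand)) <
            detection_probability(cand, det$threshold_pe,
                                  det$efficiency_params) / pmax_det
          out <- c(out, cand[keep])
        }
        out[seq_len(nk)]
      })
      tof <- forward_tof(vx, det, map,
                         detector_fwhm_ps = det$time_resolution_fwhm_ps,
                         monitor_fwhm_ps = config$monitor$time_resolution_fwhm_ps,
                         seed = sub_seed(seed, k + 200))
      npe <- with_seed(sub_seed(seed, k + 300), {
        det$threshold_pe + stats::rpois(nk, det$pe_excess_mean)
      })
      parts[[k]] <- data.frame(event_id = 0L, label = "signal",
                               detector_id = det$id, true_vertex_x_cm = vx,
                               true_energy_MeV = en, tof_ps = tof,
                               n_pe = as.integer(npe),
                               stringsAsFactors = FALSE)
    }
    events <- do.call(rbind, parts)
    events$event_id <- seq_len(nrow(events))
  }
  class(events) <- c("pgti_events", "data.frame")
  attr(events, "summary") <- list(
    n_signal = nrow(events), n_dark = 0L, n_random = 0L, n_scatter = 0L,
    acceptance = acc, shift_cm = shift_cm, seed = seed,
    range_end_cm = map$range_end)
  attr(events, "map") <- map
  attr(events, "profile") <- profile
  events
}

#' Append background events to an event list
#'
#' Adds the background classes observed in the coincidence data: (i) random
#' coincidences of SiPM dark counts with proton triggers, flat in TOF with
#' expected count `DCR_coinc x livetime` (the product of the trigger
#' frequency, the dark count rate and the coincidence window); (ii) random
#' coincidences of real secondaries with untagged-proton triggers when the
#' monitor covers only part of the beam, Gaussian in TOF with the micro-bunch
#' standard deviation `bunch_width / sqrt(12)`; (iii) optionally, a localized
#' bump of protons scattered from the monitor into the module, at the
#' monitor-to-detector flight time.
#'
#' @param events A `pgti_events` table from [generate_dataset()].
#' @param config The experiment configuration.
#' @param livetime_s Acquisition live time in seconds (> 0).
#' @param seed RNG seed.
#' @return The event table with background rows appended and the generation
#'   summary updated.
#' @export
add_backgrounds <- function(events, config, livetime_s, seed) {
  stopifnot(inherits(events, "pgti_events"), livetime_s > 0)
  summ <- attr(events, "summary")
  map <- attr(events, "map")
  model <- build_range_model(config)
  if (is.null(map)) {
    geom <- build_geometry(config, shift_cm = summ$shift_cm %||% 0)
    map <- proton_time_map(geom, config$beam$energy_MeV, model = model)
  }
  dets <- lapply(build_detectors(config), resolve_detector, map = map)
  window <- config$analysis$tof_window_ps
  lambda <- config$beam$lambda_p_per_bunch
  f_dia <- lambda * effective_bunch_rate(config)
  two_tau <- config$analysis$coincidence_window_ns * 1e-9
  coverage <- config$beam$monitor_coverage

  out <- list(events)
  counts <- c(dark = 0L, random = 0L, scatter = 0L)
  for (k in seq_along(dets)) {
    det <- dets[[k]]
    sig_k <- events$tof_ps[events$label == "signal" &
                             events$detector_id == det$id]
    # (i) dark-count random coincidences: flat in TOF
    mu_dark <- f_dia * det$dark_count_rate_hz * two_tau * livetime_s
    n_dark <- with_seed(sub_seed(seed, 400 + k), stats::rpois(1, mu_dark))
    if (n_dark > 0) {
      tof <- with_seed(sub_seed(seed, 500 + k),
                       stats::runif(n_dark, window[1], window[2]))
      out[[length(out) + 1]] <- data.frame(
        event_id = 0L, label = "dark", detector_id = det$id,
        true_vertex_x_cm = NA_real_, true_energy_MeV = NA_real_,
        tof_ps = tof, n_pe = det$threshold_pe + 1L, stringsAsFactors = FALSE)
      counts["dark"] <- counts["dark"] + n_dark
    }
    # (ii) untagged-proton random coincidences: Gaussian with the bunch sigma
    if (coverage < 1 && length(sig_k)) {
      mu_rc <- length(sig_k) * (1 - coverage) / coverage
      n_rc <- with_seed(sub_seed(seed, 600 + k), stats::rpois(1, mu_rc))
      if (n_rc > 0) {
        bunch_sigma_ps <- config$accelerator$bunch_width_ns * 1000 / sqrt(12)
        tof <- with_seed(sub_seed(seed, 700 + k),
                         stats::rnorm(n_rc, mean(sig_k), bunch_sigma_ps))
        out[[length(out) + 1]] <- data.frame(
          event_id = 0L, label = "random_coincidence", detector_id = det$id,
          true_vertex_x_cm = NA_real_, true_energy_MeV = NA_real_,
          tof_ps = tof, n_pe = det$threshold_pe + 1L,
          stringsAsFactors = FALSE)
        counts["random"] <- counts["random"] + n_rc
      }
    }
    # (iii) monitor-scattered protons converting in the module packaging
    sc <- config$backgrounds$scatter
    if (isTRUE(sc$enabled) && length(sig_k)) {
      n_sc <- with_seed(sub_seed(seed, 800 + k),
                        stats::rpois(1, sc$fraction * length(sig_k)))
      if (n_sc > 0) {
        d_md <- sqrt(sum((det$position - c(-sc$monitor_upstream_cm, 0, 0))^2))
        t_sc <- d_md * inverse_speed(config$beam$energy_MeV)
        tof <- with_seed(sub_seed(seed, 900 + k),
                         stats::rnorm(n_sc, t_sc,
                                      fwhm_to_sigma(sc$width_fwhm_ps)))
        out[[length(out) + 1]] <- data.frame(
          event_id = 0L, label = "scatter", detector_id = det$id,
          true_vertex_x_cm = NA_real_, true_energy_MeV = NA_real_,
          tof_ps = tof, n_pe = det$threshold_pe + 1L,
          stringsAsFactors = FALSE)
        counts["scatter"] <- counts["scatter"] + n_sc
      }
    }
  }
  res <- do.call(rbind, out)
  res$event_id <- seq_len(nrow(res))
  class(res) <- c("pgti_events", "data.frame")
  summ$n_dark <- summ$n_dark + as.integer(counts["dark"])
  summ$n_random <- summ$n_random + as.integer(counts["random"])
  summ$n_scatter <- summ$n_scatter + as.integer(counts["scatter"])
  summ$expected_dark <- f_dia * dets[[1]]$dark_count_rate_hz * two_tau *
    livetime_s
  attr(res, "summary") <- summ
  attr(res, "map") <- map
  attr(res, "profile") <- attr(events, "profile")
  res
}

#' @export
print.pgti_events <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("pgti_events: %d events", nrow(x)))
  if (!is.null(s))
    cat(sprintf(" (signal %d, dark %d, random %d, scatter %d)",
                s$n_signal, s$n_dark, s$n_random, s$n_scatter))
  cat("\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
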