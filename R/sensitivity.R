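#' Subsampling-bootstrap specification
#'
#' Toy-experiment sizes and counts used to estimate the statistical error of
#' the fall-off shift. Sub-samples are drawn WITHOUT replacement and kept
#' small relative to the parent sample to limit their statistical dependency;
#' the spread at each size is extrapolated to the full statistics through the
#' k/sqrt(N) law.
#'
#' @param n_toys Toy experiments per subsample size (>= 100).
#' @param subsample_sizes Vector of subsample sizes.
#' @param target_n Statistics at which the error is reported.
#' @return An object of class `bootstrap_spec`.
#' @export
bootstrap_spec <- function(n_toys = 5000,
                           subsample_sizes = seq(30, 135, by = 15),
                           target_n = 600) {
  stopifnot(n_toys >= 100, all(subsample_sizes >= 2), target_n >= 1)
  structure(list(n_toys = n_toys,
                 subsample_sizes = sort(unique(subsample_sizes)),
                 target_n = target_n),
            class = "bootstrap_spec")
}

# fall-off shift of a toy histogram against precomputed reference levels
.toy_shift <- function(counts, edges, x_ref, y_ref) {
  cdf <- .edge_cdf(counts)
  if (y_ref < cdf[1] || y_ref > cdf[length(cdf)]) return(NA_real_)
  .invert_cdf(edges, cdf, y_ref) - x_ref
}

#' Bootstrap error of the fall-off shift, extrapolated in statistics
#'
#' For each subsample size N, draws `n_toys` subsamples of the measured
#' events without replacement, computes the fall-off shift of each toy
#' against the reference, and takes the spread as sigma(N). A one-parameter
#' least-squares fit of sigma(N) = k/sqrt(N) through the origin (in
#' 1/sqrt(N)) extrapolates to the target statistics; the two-sigma error is
#' twice the one-sigma error by construction.
#'
#' @param values Measured event coordinates (TOF in ps or position in cm).
#' @param reference High-statistics reference profile, a [hist1d()].
#' @param spec A [bootstrap_spec()]; all sizes must be below
#'   `length(values)`.
#' @param seed RNG seed.
#' @param edges Bin edges for the toy histograms (default: the reference's).
#' @param estimator Spread estimator: sample standard deviation (default) or
#'   a robust MAD-based alternative.
#' @param distal_fraction Passed to the fall-off statistic.
#' @return An object of class `bootstrap_error`: list with `sigma1`,
#'   `sigma2` (= 2 sigma1), `k`, `target_n`, and the per-size table
#'   `sizes` (N, sigma).
#' @export
bootstrap_shift_error <- function(values, reference, spec = bootstrap_spec(),
                                  seed = 1, edges = NULL,
                                  estimator = c("sd", "mad"),
                                  distal_fraction = 0.5) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(spec, "bootstrap_spec"), inherits(reference, "hist1d"))
  n <- length(values)
  if (n <= max(spec$subsample_sizes))
    stop(sprintf("need more events (%d) than the largest subsample size (%d)",
                 n, max(spec$subsample_sizes)))
  if (is.null(edges)) edges <- reference$edges
  x_ref <- .distal_maximum(reference, distal_fraction)
  y_ref <- stats::approx(reference$edges, .edge_cdf(reference$counts),
                         xout = x_ref)$y
  nb <- length(edges) - 1
  bin_idx <- findInterval(values, edges)
  keep <- bin_idx >= 1 & bin_idx <= nb & values < edges[nb + 1]
  bin_idx <- bin_idx[keep]
  n <- length(bin_idx)
  sig <- numeric(length(spec$subsample_sizes))
  with_seed(seed, {
    for (j in seq_along(spec$subsample_sizes)) {
      N <- spec$subsample_sizes[j]
      ds <- numeric(spec$n_toys)
      for (t in seq_len(spec$n_toys)) {
        cnt <- tabulate(bin_idx[sample.int(n, N)], nbins = nb)
        ds[t] <- .toy_shift(cnt, edges, x_ref, y_ref)
      }
      ds <- ds[!is.na(ds)]
      sig[j] <- if (estimator == "sd") stats::sd(ds) else
        stats::mad(ds, constant = 1.4826)
    }
  })
  u <- 1 / sqrt(spec$subsample_sizes)
  k <- sum(u * sig) / sum(u^2)
  sigma1 <- k / sqrt(spec$target_n)
  structure(list(sigma1 = sigma1, sigma2 = 2 * sigma1, k = k,
                 target_n = spec$target_n, estimator = estimator,
                 sizes = data.frame(N = spec$subsample_sizes, sigma = sig)),
            class = "bootstrap_error")
}

#' @export
print.bootstrap_error <- function(x, ...) {
  cat(sprintf("bootstrap fall-off error: k = %.3g, sigma1(N=%d) = %.3g, sigma2 = %.3g\n",
              x$k, x$target_n, x$sigma1, x$sigma2))
  invisible(x)
}

#' Effective beam intensity from bunch-occupancy counts
#'
#' The ratio of one-proton to empty bunches estimates the Poisson mean
#' protons-per-bunch: P(1)/P(0) = lambda.
#'
#' @param count_zero Number of empty bunches (> 0).
#' @param count_one Number of one-proton bunches.
#' @return The lambda estimate.
#' @export
poisson_lambda <- function(count_zero, count_one) {
  if (count_zero <= 0)
    stop("no empty bunches observed: lambda estimate undefined")
  stopifnot(count_one >= 0)
  count_one / count_zero
}

#' Random-coincidence rate between dark counts and proton triggers
#'
#' `DCR_coinc = f_dia * DCR_SiPM * 2 tau`: the accidental-coincidence rate
#' between the beam-monitor proton triggers and the photodetector dark
#' counts within the coincidence window.
#'
#' @param f_dia_hz Proton trigger rate in the beam monitor, Hz.
#' @param dcr_sipm_hz Dark count rate above threshold, Hz.
#' @param window_2tau_s Full coincidence window width (2 tau) in seconds.
#' @return Rate in Hz; linear in each factor.
#' @examples
#' random_coincidence_rate(625e3, 302, 20e-9)  # ~3.8 Hz
#' @export
random_coincidence_rate <- function(f_dia_hz, dcr_sipm_hz, window_2tau_s) {
  if (any(c(f_dia_hz, dcr_sipm_hz, window_2tau_s) < 0))
    stop("all factors must be non-negative")
  f_dia_hz * dcr_sipm_hz * window_2tau_s
}

#' Delivery time in the single-proton regime
#'
#' Time needed to deliver `n_protons` taggable protons when bunches are
#' Poisson-occupied with mean `lambda`: only non-empty bunches contribute a
#' time tag, at rate `bunch_rate * (1 - exp(-lambda))`. For a pulsed
#' synchro-cyclotron, `bunch_rate_hz` is the duty-cycle-weighted effective
#' bunch rate.
#'
#' @param n_protons Number of protons to deliver.
#' @param bunch_rate_hz Effective bunch rate in Hz (> 0).
#' @param lambda Mean protons per bunch (> 0).
#' @return Delivery time in seconds.
#' @examples
#' spr_delivery_time(1e7, 25e6, 1)   # cyclotron, ~0.63 s
#' spr_delivery_time(1e7, 5e5, 1)    # pulsed synchro-cyclotron, ~31.6 s
#' @export
spr_delivery_time <- function(n_protons, bunch_rate_hz, lambda) {
  stopifnot(n_protons > 0)
  if (bunch_rate_hz <= 0) stop("bunch_rate_hz must be positive")
  if (lambda <= 0) stop("lambda must be positive")
  n_protons / (bunch_rate_hz * (1 - exp(-lambda)))
}

#' Quadrature decomposition of a time resolution
#'
#' Removes an independent Gaussian component from a total FWHM:
#' `sqrt(total^2 - component^2)`. Used to split the coincidence time
#' resolution into beam-monitor and gamma-detector contributions.
#'
#' @param total_fwhm Total FWHM (> component).
#' @param component_fwhm Known component FWHM (>= 0).
#' @return The remaining component's FWHM, same units.
#' @examples
#' quadratic_difference(397, 360)  # ~167
#' @export
quadratic_difference <- function(total_fwhm, component_fwhm) {
  stopifnot(component_fwhm >= 0)
  if (component_fwhm >= total_fwhm)
    stop("component must be strictly smaller than the total")
  sqrt(total_fwhm^2 - component_fwhm^2)
}

#' Range-shift sensitivity scan
#'
#' End-to-end sensitivity measurement: for each implemented air-cavity shift
#' a dataset is generated, histogrammed (PGT: TOF domain) or reconstructed
#' with the REFERENCE-geometry maps (PGTI: space domain), optionally
#' background-subtracted, compared to a high-statistics simulated reference
#' through the fall-off shift statistic, and dressed with subsampling
#' bootstrap errors.
#'
#' @param config Experiment configuration, see [pgti_preset()].
#' @param shifts_cm Implemented shifts in cm; must include 0 (the reference).
#' @param n_events_per_shift Accepted signal events per shift.
#' @param mode `"pgt"` (time domain, results in ps) or `"pgti"` (space
#'   domain via reference-map reconstruction, results in cm).
#' @param seed RNG seed.
#' @param spec A [bootstrap_spec()]; its `target_n` defaults to
#'   `n_events_per_shift`.
#' @param n_reference Accepted events in the simulated reference profile.
#' @param livetime_s If non-NULL, background events are added for this live
#'   time and subtracted before the shift measurement.
#' @return A data frame of class `sensitivity_scan` with columns
#'   `shift_cm`, `d`, `sigma1`, `sigma2`, `n_events`, `units`; the reference
#'   histogram and configuration are attached as attributes.
#' @export
sensitivity_scan <- function(config, shifts_cm = c(0, 0.2, 0.4, 0.6, 1.0),
                             n_events_per_shift = 600,
                             mode = c("pgt", "pgti"), seed = 1,
                             spec = NULL, n_reference = 20000,
                             livetime_s = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "pgti_config"))
  if (!any(shifts_cm == 0))
    stop("shifts_cm must include 0 (the reference geometry)")
  if (is.null(spec))
    spec <- bootstrap_spec(target_n = n_events_per_shift)

  ref_events <- generate_dataset(config, n_reference,
                                 seed = sub_seed(seed, 9999))
  ref_map0 <- attr(ref_events, "map")
  dets <- lapply(build_detectors(config), resolve_detector, map = ref_map0)
  names(dets) <- vapply(dets, `[[`, character(1), "id")
  maps <- lapply(dets, function(d) build_reference_map(ref_map0, d))

  if (mode == "pgt") {
    window <- config$analysis$tof_window_ps
    edges <- seq(window[1], window[2], by = config$analysis$tof_binwidth_ps)
    reference <- hist1d(ref_events$tof_ps, edges = edges)
    units <- "ps"
  } else {
    rec_ref <- reconstruct_dataset(ref_events, maps)
    xmax <- max(maps[[1]]$x)
    edges <- seq(0, xmax + config$analysis$space_binwidth_cm,
                 by = config$analysis$space_binwidth_cm)
    reference <- hist1d(rec_ref$x_rec[rec_ref$in_range], edges = edges)
    units <- "cm"
  }

  rows <- vector("list", length(shifts_cm))
  for (i in seq_along(shifts_cm)) {
    s <- shifts_cm[i]
    ev <- generate_dataset(config, n_events_per_shift,
                           seed = sub_seed(seed, i), shift_cm = s)
    if (!is.null(livetime_s))
      ev <- add_backgrounds(ev, config, livetime_s,
                            seed = sub_seed(seed, 2000 + i))
    if (mode == "pgt") {
      vals <- ev$tof_ps
      h <- hist1d(vals, edges = edges)
      if (!is.null(livetime_s))
        h <- subtract_flat_background(h, config$analysis$off_signal_window_ps)
    } else {
      rec <- reconstruct_dataset(ev, maps)
      vals <- rec$x_rec[rec$in_range]
      h <- hist1d(vals, edges = edges)
      if (!is.null(livetime_s)) {
        tpl <- background_template(maps[[1]], config$analysis$tof_window_ps,
                                   edges = edges, seed = sub_seed(seed, 3000 + i))
        h <- subtract_pgti_background(h, tpl,
                                      config$analysis$off_signal_region_cm)
      }
    }
    fs <- falloff_shift(h, reference)
    be <- bootstrap_shift_error(vals, reference, spec,
                                seed = sub_seed(seed, 4000 + i),
                                edges = edges)
    rows[[i]] <- data.frame(shift_cm = s, d = fs$d, sigma1 = be$sigma1,
                            sigma2 = be$sigma2, n_events = length(vals),
                            units = units, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_scan", "data.frame")
  attr(out, "reference") <- reference
  attr(out, "mode") <- mode
  attr(out, "maps") <- maps
  exit_e <- .thin_target_exit_energy(config)
  attr(out, "exit_inverse_speed_ps_per_cm") <-
    if (is.na(exit_e)) NA_real_ else inverse_speed(exit_e)
  out
}

# energy of the beam after the first PMMA slab (NA if the first slab stops it)
.thin_target_exit_energy <- function(config) {
  model <- build_range_model(config)
  geom <- build_geometry(config)
  first <- geom[1, ]
  if (first$material == "air") return(config$beam$energy_MeV)
  e <- energy_at_depth(config$beam$energy_MeV, first$thickness,
                       first$material, model)
  if (attr(e, "stopped")[1]) NA_real_ else as.numeric(e)
}

#' @export
print.sensitivity_scan <- function(x, ...) {
  cat(sprintf("sensitivity scan (%s mode, %s):\n", attr(x, "mode"),
              x$units[1]))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
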