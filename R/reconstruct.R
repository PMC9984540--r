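#' Build a per-detector reference time map
#'
#' Tabulates the total expected TOF, `T_p(x) + T_PG(x, r_d)`, on a position
#' grid for the REFERENCE geometry. The map is the invertible forward model
#' used for event-by-event reconstruction; it is built once from the
#' reference geometry and deliberately reused for shifted data, which biases
#' the recovered shift low (slope below one) because the `T_p` term is the
#' reference one. Beyond the stopping depth the map is continued linearly
#' with the mean total-TOF slope over the last `slope_window_cm` before the
#' stopping point, so that time-jittered TOFs from fall-off vertices remain
#' invertible instead of piling up at the map boundary.
#'
#' @param map A [proton_time_map()] of the reference geometry.
#' @param detector A resolved [detector_module()].
#' @param grid_step Grid spacing in cm (default 0.02, i.e. 0.2 mm).
#' @param margin_cm Grid extension beyond the stopping depth, cm (generous, so that time-jittered fall-off TOFs of moderately shifted geometries stay invertible).
#' @param slope_window_cm Window before the stopping depth over which the
#'   continuation slope is averaged.
#' @return An object of class `reference_time_map`: list with `detector_id`,
#'   `x` (cm) and `tof_ps`, strictly increasing in `x`.
#' @export
build_reference_map <- function(map, detector, grid_step = 0.02,
                                margin_cm = 4, slope_window_cm = 1.5) {
  stopifnot(inherits(map, "proton_time_map"), grid_step > 0, margin_cm >= 0,
            slope_window_cm > 0)
  if (is.null(detector$position))
    stop("detector position unresolved; call resolve_detector() first")
  x <- seq(0, map$range_end + margin_cm, by = grid_step)
  tp <- eval_time_map(map, x)
  d <- sqrt((x - detector$position[1])^2 + detector$position[2]^2 +
              detector$position[3]^2)
  tof <- tp + d / kinematic_constants$light_speed * 1000
  beyond <- x > map$range_end
  if (any(beyond)) {
    t_total <- function(xx) eval_time_map(map, xx) +
      sqrt((xx - detector$position[1])^2 + detector$position[2]^2 +
             detector$position[3]^2) / kinematic_constants$light_speed * 1000
    w <- min(slope_window_cm, map$range_end)
    slope <- (t_total(map$range_end) - t_total(map$range_end - w)) / w
    tof[beyond] <- t_total(map$range_end) +
      (x[beyond] - map$range_end) * slope
  }
  dt <- diff(tof)
  if (any(dt <= 0)) {
    i <- which(dt <= 0)[1]
    stop(sprintf(paste0(
      "reference time map for detector '%s' is not monotone on ",
      "[%.3f, %.3f] cm: the gamma flight-time term decreases faster than ",
      "the proton arrival time grows"), detector$id, x[i], x[i + 1]))
  }
  structure(list(detector_id = detector$id, x = x, tof_ps = tof,
                 grid_step = grid_step, range_end = map$range_end),
            class = "reference_time_map")
}

#' @export
print.reference_time_map <- function(x, ...) {
  cat(sprintf("Reference time map '%s': %d nodes, x in [0, %.2f] cm, TOF in [%.0f, %.0f] ps\n",
              x$detector_id, length(x$x), max(x$x),
              min(x$tof_ps), max(x$tof_ps)))
  invisible(x)
}

#' Invert measured TOFs into vertex coordinates
#'
#' Piecewise-linear inverse interpolation of the reference time map. TOFs
#' below (above) the map range are assigned the first (last) grid position
#' and flagged out of range; they are kept for count bookkeeping but should
#' be excluded from fall-off fitting.
#'
#' @param tof TOF values in ps.
#' @param ref_map A [build_reference_map()] result.
#' @return A data frame with `x_rec` (cm) and `in_range` (logical).
#' @export
invert_tof <- function(tof, ref_map) {
  stopifnot(inherits(ref_map, "reference_time_map"))
  x <- stats::approx(ref_map$tof_ps, ref_map$x, xout = tof, rule = 1)$y
  lo <- tof < ref_map$tof_ps[1]
  hi <- tof > ref_map$tof_ps[length(ref_map$tof_ps)]
  x[lo] <- ref_map$x[1]
  x[hi] <- ref_map$x[length(ref_map$x)]
  data.frame(x_rec = x, in_range = !(lo | hi))
}

#' Reconstruct an event list into the space domain
#'
#' Applies [invert_tof()] per detector, enabling detectors at different
#' angles to be merged in space: their raw TOF histograms differ (the gamma
#' flight-time term depends on the detector position) but their reconstructed
#' vertex profiles agree.
#'
#' @param events A `pgti_events` table.
#' @param maps A named list of [build_reference_map()] results, one per
#'   detector id occurring in `events`.
#' @return The events with `x_rec` and `in_range` columns appended
#'   (count-preserving: every input row is returned).
#' @export
reconstruct_dataset <- function(events, maps) {
  stopifnot(is.data.frame(events), is.list(maps))
  ids <- unique(events$detector_id)
  missing <- setdiff(ids, names(maps))
  if (length(missing))
    stop("no reference map for detector(s): ", paste(missing, collapse = ", "))
  events$x_rec <- NA_real_
  events$in_range <- NA
  for (id in ids) {
    sel <- events$detector_id == id
    rec <- invert_tof(events$tof_ps[sel], maps[[id]])
    events$x_rec[sel] <- rec$x_rec
    events$in_range[sel] <- rec$in_range
  }
  events
}

#' Spatial template of a TOF-flat background
#'
#' The image, under the reconstruction, of a background that is flat in TOF:
#' uniform TOF samples are pushed through [invert_tof()] and histogrammed.
#' The template inherits the Jacobian of the inverse map (where the map slope
#' doubles, the spatial density halves) and is the shape fitted and
#' subtracted from reconstructed profiles.
#'
#' @param ref_map A [build_reference_map()] result.
#' @param tof_window Length-2 TOF interval in ps covering the analysis range.
#' @param edges Spatial bin edges in cm for the template histogram.
#' @param n_samples Number of uniform TOF samples.
#' @param seed RNG seed.
#' @return A [hist1d()] whose counts are normalised to unit integral
#'   (density per cm).
#' @export
background_template <- function(ref_map, tof_window, edges,
                                n_samples = 200000, seed = 1) {
  stopifnot(length(tof_window) == 2)
  if (diff(tof_window) <= 0) stop("degenerate TOF window")
  tof <- with_seed(seed, stats::runif(n_samples, tof_window[1], tof_window[2]))
  rec <- invert_tof(tof, ref_map)
  x <- rec$x_rec[rec$in_range]
  h <- hist1d(x, edges = edges)
  w <- diff(h$edges)
  total <- sum(h$counts * w)
  if (total <= 0) stop("no in-range samples fall in the template bins")
  h$counts <- h$counts / total
  h
}
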