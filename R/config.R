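#' Load and validate an experiment configuration
#'
#' Configurations are plain YAML describing the accelerator time structure,
#' beam delivery, phantom geometry, range model, beam monitor, detector
#' modules, emission/spectrum models and analysis settings. Two bundled
#' presets reproduce the experimental setups: `medicyc_63MeV` (63 MeV
#' cyclotron, two-target air-cavity phantom, one module at 90 degrees) and
#' `s2c2_148MeV` (148 MeV pulsed synchro-cyclotron, thick stopping target,
#' modules at 157 and 90 degrees).
#'
#' @param path Path to a YAML configuration file.
#' @return A validated object of class `pgti_config`.
#' @seealso [pgti_preset()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' Load a bundled configuration preset
#'
#' @param name `"medicyc_63MeV"` or `"s2c2_148MeV"`.
#' @return A validated `pgti_config`.
#' @export
pgti_preset <- function(name = c("medicyc_63MeV", "s2c2_148MeV")) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "pgti")
  if (path == "") stop("preset not found: ", name)
  load_config(path)
}

.need <- function(cfg, field, where) {
  parts <- strsplit(field, "$", fixed = TRUE)[[1]]
  x <- cfg
  for (p in parts) {
    if (is.null(x[[p]]))
      stop(sprintf("configuration field missing: %s", field))
    x <- x[[p]]
  }
  x
}

#' Validate a configuration list
#'
#' Checks presence and consistency of every field the pipeline uses and
#' returns the config blessed as `pgti_config`. Violations raise errors
#' naming the offending field.
#'
#' @param cfg A named list (e.g. from [yaml::read_yaml()]).
#' @return A `pgti_config`.
#' @export
validate_config <- function(cfg) {
  for (f in c("name", "seed", "beam$energy_MeV", "beam$lambda_p_per_bunch",
              "beam$monitor_coverage", "accelerator$bunch_period_ns",
              "accelerator$bunch_width_ns", "geometry$slabs",
              "range_model$alpha", "range_model$p",
              "range_model$anchor_energy_MeV", "range_model$anchor_range_cm",
              "monitor$time_resolution_fwhm_ps", "detectors",
              "emission$rise", "emission$falloff_retract_cm",
              "emission$falloff_sigma_cm",
              "analysis$tof_binwidth_ps", "analysis$space_binwidth_cm",
              "analysis$tof_window_ps", "analysis$coincidence_window_ns"))
    .need(cfg, f, "config")
  acc <- cfg$accelerator
  if (acc$bunch_width_ns > acc$bunch_period_ns)
    stop("accelerator$bunch_width_ns exceeds bunch_period_ns")
  if (!is.null(acc$pulse_width_us) || !is.null(acc$pulse_period_ms)) {
    if (is.null(acc$pulse_width_us) || is.null(acc$pulse_period_ms))
      stop("accelerator: pulse_width_us and pulse_period_ms must be set together")
    if (acc$pulse_width_us * 1e-3 > acc$pulse_period_ms)
      stop("accelerator$pulse_width_us exceeds pulse_period_ms")
  }
  if (cfg$beam$lambda_p_per_bunch < 0)
    stop("beam$lambda_p_per_bunch must be non-negative")
  if (cfg$beam$monitor_coverage <= 0 || cfg$beam$monitor_coverage > 1)
    stop("beam$monitor_coverage must lie in (0, 1]")
  for (sl in cfg$geometry$slabs) {
    if (is.null(sl$material) || is.null(sl$thickness_cm))
      stop("geometry$slabs entries need material and thickness_cm")
    if (sl$thickness_cm <= 0) stop("geometry slab thickness must be positive")
  }
  if (!length(cfg$detectors)) stop("detectors list is empty")
  for (d in cfg$detectors) {
    for (f in c("id", "angle_deg", "distance_cm", "anchor",
                "time_resolution_fwhm_ps", "threshold_pe"))
      if (is.null(d[[f]]))
        stop(sprintf("detector definition missing field: %s", f))
    if (d$time_resolution_fwhm_ps <= 0)
      stop(sprintf("detector %s: time_resolution_fwhm_ps must be positive",
                   d$id))
  }
  if (is.null(cfg$spectrum)) cfg$spectrum <- default_spectrum_params()
  if (length(cfg$analysis$tof_window_ps) != 2)
    stop("analysis$tof_window_ps must be a length-2 interval")
  if (is.null(cfg$backgrounds)) cfg$backgrounds <- list()
  if (is.null(cfg$backgrounds$scatter))
    cfg$backgrounds$scatter <- list(enabled = FALSE)
  structure(cfg, class = "pgti_config")
}

#' @export
print.pgti_config <- function(x, ...) {
  cat(sprintf("pgti_config '%s': %g MeV, lambda = %g p/bunch, %d detector(s)\n",
              x$name, x$beam$energy_MeV, x$beam$lambda_p_per_bunch,
              length(x$detectors)))
  invisible(x)
}

#' Build the range-energy model described by a configuration
#' @param config A `pgti_config`.
#' @return A [range_energy_model()].
#' @export
build_range_model <- function(config) {
  rm <- config$range_model
  range_energy_model(alpha = rm$alpha, p = rm$p,
                     anchor_energy = rm$anchor_energy_MeV,
                     anchor_range = rm$anchor_range_cm,
                     pmma_density = rm$pmma_density %||% 1.19)
}

#' Build the slab geometry described by a configuration
#'
#' @param config A `pgti_config`.
#' @param shift_cm Widening of the (single) air slab, emulating an
#'   anatomical change; an error if the geometry has no air gap and
#'   `shift_cm != 0`.
#' @return A [slab_geometry()].
#' @export
build_geometry <- function(config, shift_cm = 0) {
  mats <- vapply(config$geometry$slabs, `[[`, character(1), "material")
  thick <- vapply(config$geometry$slabs, `[[`, numeric(1), "thickness_cm")
  if (shift_cm != 0) {
    i <- which(mats == "air")
    if (!length(i))
      stop("geometry has no air gap to shift")
    thick[i[1]] <- thick[i[1]] + shift_cm
  }
  slab_geometry(mats, thick)
}

#' Build detector modules from a configuration
#' @param config A `pgti_config`.
#' @return A list of [detector_module()] objects (positions unresolved).
#' @export
build_detectors <- function(config) {
  lapply(config$detectors, function(d)
    detector_module(id = d$id, angle_deg = d$angle_deg,
                    distance_cm = d$distance_cm, anchor = d$anchor,
                    face_area_cm2 = d$face_area_cm2 %||% 1,
                    time_resolution_fwhm_ps = d$time_resolution_fwhm_ps,
                    threshold_pe = d$threshold_pe,
                    dark_count_rate_hz = d$dark_count_rate_hz %||% 0,
                    pe_excess_mean = d$pe_excess_mean %||% 1.5))
}

#' Duty-cycle-weighted bunch rate of the accelerator
#'
#' `1 / bunch_period`, scaled by the macro-pulse duty cycle when the machine
#' is pulsed (e.g. 8 us pulses every ms give a 0.008 duty cycle).
#'
#' @param config A `pgti_config`.
#' @return Effective bunch rate in Hz.
#' @export
effective_bunch_rate <- function(config) {
  acc <- config$accelerator
  rate <- 1e9 / acc$bunch_period_ns
  if (!is.null(acc$pulse_width_us))
    rate <- rate * (acc$pulse_width_us * 1e3) / (acc$pulse_period_ms * 1e6)
  rate
}

#' Counting-statistics summary of a configuration
#'
#' Evaluates the closed-form counting models: the proton trigger rate in
#' the monitor, the dark-count random-coincidence rate, and the
#' single-proton-regime delivery time for a given proton budget.
#'
#' @param config A `pgti_config`.
#' @param n_protons Proton budget for the delivery-time estimate.
#' @param spr_lambda Protons per bunch assumed for the delivery-time
#'   estimate (1 = the nominal single-proton-regime working point).
#' @return A list with `f_dia_hz`, `dcr_coinc_hz` (per detector),
#'   `effective_bunch_rate_hz`, `spr_delivery_time_s`.
#' @export
counting_summary <- function(config, n_protons = 1e7, spr_lambda = 1) {
  rate <- effective_bunch_rate(config)
  f_dia <- config$beam$lambda_p_per_bunch * rate
  two_tau <- config$analysis$coincidence_window_ns * 1e-9
  dcr <- vapply(config$detectors, function(d)
    random_coincidence_rate(f_dia, d$dark_count_rate_hz %||% 0, two_tau),
    numeric(1))
  names(dcr) <- vapply(config$detectors, `[[`, character(1), "id")
  list(f_dia_hz = f_dia, dcr_coinc_hz = dcr,
       effective_bunch_rate_hz = rate,
       spr_delivery_time_s = spr_delivery_time(n_protons, rate, spr_lambda))
}

# --- delimited-text persistence -------------------------------------------

#' Write / read an event table as tab-delimited text
#'
#' @param events A `pgti_events` data frame.
#' @param path Output file.
#' @return `read_events` returns a `pgti_events` data frame.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  class(ev) <- c("pgti_events", "data.frame")
  ev
}

#' Write / read a histogram as delimited text
#'
#' Columns: `edge_left`, `edge_right`, `counts`.
#'
#' @param h A [hist1d()].
#' @param path Output file.
#' @return `read_histogram` returns a `hist1d`.
#' @export
write_histogram <- function(h, path) {
  d <- data.frame(edge_left = h$edges[-length(h$edges)],
                  edge_right = h$edges[-1], counts = h$counts)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histogram
#' @export
read_histogram <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  hist1d_from_counts(c(d$edge_left, d$edge_right[nrow(d)]), d$counts)
}

#' Write / read a reference time map as delimited text
#'
#' Two columns (`x_cm`, `tof_ps`) preceded by a comment line naming the
#' detector.
#'
#' @param map A [build_reference_map()] result.
#' @param path Output file.
#' @return `read_reference_map` returns a `reference_time_map`.
#' @export
write_reference_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# detector: ", map$detector_id), con)
  writeLines("x_cm\ttof_ps", con)
  utils::write.table(data.frame(map$x, map$tof_ps), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_map
#' @export
read_reference_map <- function(path) {
  first <- readLines(path, n = 1)
  id <- sub("^# detector: ", "", first)
  d <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1)
  structure(list(detector_id = id, x = d$x_cm, tof_ps = d$tof_ps,
                 grid_step = stats::median(diff(d$x_cm)),
                 range_end = NA_real_),
            class = "reference_time_map")
}

# --- pipeline orchestration -----------------------------------------------

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(serialize(unclass(config), NULL, version = 3), tf)
  unname(tools::md5sum(tf))
}

.manifest <- function(config, seed, counts = NULL, outputs = character()) {
  list(config_hash = .config_hash(config), seed = seed,
       package_version = as.character(utils::packageVersion("pgti")),
       event_counts = counts, outputs = outputs,
       timestamp = format(Sys.time(), tz = "UTC"))
}

#' Run a pipeline stage
#'
#' Orchestrates the analysis stages over a configuration, with deterministic
#' outputs for a fixed seed and a run manifest recording the configuration
#' hash, seed, package version, per-stage event counts and output files.
#'
#' Commands: `"simulate"` (event table + generation summary),
#' `"reconstruct"` (simulate, build reference maps, reconstruct),
#' `"analyze"` (simulate, histogram, fall-off shift against a simulated
#' reference with bootstrap errors), `"sensitivity"` (a [sensitivity_scan()]
#' table), `"counting"` (the closed-form counting statistics).
#'
#' @param command One of `simulate`, `reconstruct`, `analyze`,
#'   `sensitivity`, `counting`.
#' @param config A `pgti_config`.
#' @param out_dir Optional output directory; when given, stage products are
#'   written as delimited text and listed in the manifest.
#' @param n_events Accepted signal events for simulation stages.
#' @param shifts_cm Implemented shifts for the sensitivity stage.
#' @param mode `"pgt"` or `"pgti"` for the sensitivity stage.
#' @param seed RNG seed (defaults to the configuration's).
#' @param ... Passed on to the stage worker.
#' @return A list with elements `result` and `manifest`.
#' @export
run_pipeline <- function(command = c("simulate", "reconstruct", "analyze",
                                     "sensitivity", "counting"),
                         config, out_dir = NULL, n_events = 600,
                         shifts_cm = c(0, 0.2, 0.4, 0.6, 1.0),
                         mode = "pgt", seed = NULL, ...) {
  command <- match.arg(command)
  stopifnot(inherits(config, "pgti_config"))
  seed <- seed %||% config$seed
  outputs <- character()
  save <- function(writer, obj, name) {
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      p <- file.path(out_dir, name)
      writer(obj, p)
      outputs <<- c(outputs, p)
    }
  }
  counts <- NULL
  result <- switch(
    command,
    simulate = {
      ev <- generate_dataset(config, n_events, seed = seed, ...)
      counts <- attr(ev, "summary")[c("n_signal", "n_dark", "n_random",
                                      "n_scatter")]
      save(write_events, ev, "events.tsv")
      ev
    },
    reconstruct = {
      ev <- generate_dataset(config, n_events, seed = seed, ...)
      map <- attr(ev, "map")
      dets <- lapply(build_detectors(config), resolve_detector, map = map)
      maps <- lapply(dets, function(d) build_reference_map(map, d))
      names(maps) <- vapply(dets, `[[`, character(1), "id")
      rec <- reconstruct_dataset(ev, maps)
      counts <- list(n_events = nrow(rec), n_in_range = sum(rec$in_range))
      for (id in names(maps))
        save(write_reference_map, maps[[id]],
             paste0("reference_map_", id, ".tsv"))
      save(write_events, rec, "reconstructed_events.tsv")
      rec
    },
    analyze = {
      ev <- generate_dataset(config, n_events, seed = seed, ...)
      ref <- generate_dataset(config, 20000, seed = sub_seed(seed, 9999))
      window <- config$analysis$tof_window_ps
      edges <- seq(window[1], window[2],
                   by = config$analysis$tof_binwidth_ps)
      h <- hist1d(ev$tof_ps, edges = edges)
      reference <- hist1d(ref$tof_ps, edges = edges)
      fs <- falloff_shift(h, reference)
      be <- bootstrap_shift_error(ev$tof_ps, reference,
                                  bootstrap_spec(target_n = n_events),
                                  seed = sub_seed(seed, 1))
      counts <- list(n_events = nrow(ev))
      save(write_histogram, h, "tof_profile.tsv")
      save(write_histogram, reference, "tof_reference.tsv")
      list(shift = fs, errors = be, profile = h, reference = reference)
    },
    sensitivity = {
      scan <- sensitivity_scan(config, shifts_cm = shifts_cm,
                               n_events_per_shift = n_events, mode = mode,
                               seed = seed, ...)
      counts <- list(n_events_per_shift = n_events,
                     n_shifts = length(shifts_cm))
      save(function(obj, p) utils::write.table(as.data.frame(obj), p,
                                               sep = "\t", quote = FALSE,
                                               row.names = FALSE),
           scan, "sensitivity.tsv")
      scan
    },
    counting = counting_summary(config, ...)
  )
  manifest <- .manifest(config, seed, counts, outputs)
  save(function(obj, p) yaml::write_yaml(obj, p), manifest, "manifest.yaml")
  list(result = result, manifest = manifest)
}
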