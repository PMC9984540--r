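#' Physical constants for proton kinematics
#'
#' Proton rest energy (MeV) and the speed of light (cm/ns) used throughout
#' the package. Positions are in cm along the beam axis (origin at the
#' upstream face of the first target), times in ps.
#'
#' @format A list with elements `proton_rest_energy` (938.272 MeV) and
#'   `light_speed` (29.9792 cm/ns).
#' @export
kinematic_constants <- list(
  proton_rest_energy = 938.272,
  light_speed        = 29.9792458
)

#' Bragg-Kleeman range-energy model
#'
#' The residual range of a proton of kinetic energy E in water is modelled as
#' `R_water(E) = alpha * E^p`. Other materials are described by a single
#' water-equivalent stopping ratio: `R_mat(E) = R_water(E) / ratio`. The PMMA
#' ratio is calibrated so that 148 MeV protons stop after `anchor_range` cm of
#' PMMA, the only range datum available for these phantoms; with the default
#' coefficients the calibrated ratio is about 1.14.
#'
#' @param alpha Range coefficient in cm * MeV^-p for water.
#' @param p Range exponent (dimensionless, typically 1.7-1.8).
#' @param anchor_energy Calibration energy in MeV.
#' @param anchor_range PMMA stopping depth at `anchor_energy`, in cm.
#' @param pmma_density PMMA density in g/cm^3 (recorded, not used by the
#'   range law once the ratio is calibrated).
#' @return An object of class `range_energy_model` with the coefficients and
#'   a material table (`water`, `pmma`, `air`). Air is treated as a lossless
#'   drift: protons cross air gaps at constant speed.
#' @examples
#' m <- range_energy_model()
#' residual_range(148, "pmma", m)  # 13.4 cm by calibration
#' @export
range_energy_model <- function(alpha = 0.0022, p = 1.77,
                               anchor_energy = 148, anchor_range = 13.4,
                               pmma_density = 1.19) {
  stopifnot(alpha > 0, p > 1.5, p < 2.0, anchor_range > 0)
  wer_pmma <- alpha * anchor_energy^p / anchor_range
  if (wer_pmma <= 1)
    stop("calibrated PMMA water-equivalent ratio must exceed 1")
  materials <- data.frame(
    name              = c("water", "pmma", "air"),
    density           = c(1.0, pmma_density, 1.2e-3),
    water_equiv_ratio = c(1.0, wer_pmma, NA_real_),
    lossless          = c(FALSE, FALSE, TRUE),
    stringsAsFactors  = FALSE
  )
  structure(list(alpha = alpha, p = p, materials = materials,
                 anchor = c(energy = anchor_energy, range = anchor_range)),
            class = "range_energy_model")
}

#' @export
print.range_energy_model <- function(x, ...) {
  cat("Bragg-Kleeman range-energy model\n")
  cat(sprintf("  R_water(E) = %.4g * E^%.3g  [cm, MeV]\n", x$alpha, x$p))
  cat(sprintf("  calibration: %g MeV protons stop after %g cm of PMMA\n",
              x$anchor[["energy"]], x$anchor[["range"]]))
  print(x$materials, row.names = FALSE)
  invisible(x)
}

.material_row <- function(material, model) {
  i <- match(material, model$materials$name)
  if (is.na(i)) stop("unknown material: ", material)
  model$materials[i, ]
}

#' Relativistic speed fraction of a proton
#'
#' @param energy Kinetic energy in MeV (vectorised).
#' @return beta = v/c = sqrt(1 - (m / (m + E))^2), in [0, 1).
#' @examples
#' proton_beta(938.272)  # gamma = 2, beta = sqrt(3)/2
#' @export
proton_beta <- function(energy) {
  if (any(energy < 0)) stop("energy must be non-negative")
  m <- kinematic_constants$proton_rest_energy
  sqrt(1 - (m / (m + energy))^2)
}

#' Inverse proton speed
#'
#' Time to cross one cm at kinetic energy E, the local slope of the proton
#' arrival-time map: `1000 / (proton_beta(E) * c)` in ps/cm. Strictly decreasing in E.
#'
#' @param energy Kinetic energy in MeV (vectorised), strictly positive.
#' @return Inverse speed in ps/cm.
#' @export
inverse_speed <- function(energy) {
  if (any(energy <= 0)) stop("inverse_speed requires energy > 0 (stopped proton)")
  1000 / (proton_beta(energy) * kinematic_constants$light_speed)
}

#' Residual proton range in a material
#'
#' @param energy Kinetic energy in MeV (vectorised).
#' @param material Material name (`"pmma"` or `"water"`).
#' @param model A [range_energy_model()].
#' @return Range in cm; strictly increasing in energy, 0 at E = 0.
#' @export
residual_range <- function(energy, material = "pmma",
                           model = range_energy_model()) {
  if (any(energy < 0)) stop("energy must be non-negative")
  row <- .material_row(material, model)
  if (isTRUE(row$lossless))
    stop("material '", material, "' is a lossless drift; range is undefined")
  model$alpha * energy^model$p / row$water_equiv_ratio
}

#' Proton energy after a given depth of material
#'
#' Closed-form inversion of the Bragg-Kleeman law:
#' `E(d)` satisfies `residual_range(E) = residual_range(E0) - d`.
#' Depths at or beyond the residual range return 0 with attribute
#' `stopped = TRUE` for the corresponding entries.
#'
#' @param entry_energy Entry kinetic energy in MeV (scalar).
#' @param depth Depth in cm (vectorised), non-negative.
#' @param material,model See [residual_range()].
#' @return Energy in MeV with logical attribute `stopped`.
#' @export
energy_at_depth <- function(entry_energy, depth, material = "pmma",
                            model = range_energy_model()) {
  stopifnot(length(entry_energy) == 1, entry_energy >= 0)
  if (any(depth < 0)) stop("depth must be non-negative")
  row <- .material_row(material, model)
  r0 <- residual_range(entry_energy, material, model)
  rem <- r0 - depth
  stopped <- rem <= 0
  e <- numeric(length(depth))
  e[!stopped] <- (rem[!stopped] * row$water_equiv_ratio / model$alpha)^(1 / model$p)
  attr(e, "stopped") <- stopped
  e
}

#' Proton transit time through a slab
#'
#' Composite-midpoint integral of [inverse_speed()] over depth, on steps of at
#' most `step` cm (0.1 mm default; the 51 ps smear of a 5 mm target needs
#' sub-ps accuracy). Additive over consecutive slabs.
#'
#' @param entry_energy Entry kinetic energy in MeV.
#' @param thickness Slab thickness in cm.
#' @param material,model See [residual_range()].
#' @param step Maximum quadrature step in cm.
#' @return Transit time in ps.
#' @export
transit_time <- function(entry_energy, thickness, material = "pmma",
                         model = range_energy_model(), step = 0.01) {
  stopifnot(thickness >= 0, step > 0)
  if (thickness == 0) return(0)
  row <- .material_row(material, model)
  if (isTRUE(row$lossless))
    return(thickness * inverse_speed(entry_energy))
  if (thickness > residual_range(entry_energy, material, model) + 1e-12)
    stop("proton stops inside the slab: thickness exceeds residual range")
  n <- ceiling(thickness / step)
  h <- thickness / n
  mids <- (seq_len(n) - 0.5) * h
  e_mid <- energy_at_depth(entry_energy, mids, material, model)
  sum(inverse_speed(pmax(e_mid, 1e-9))) * h
}

#' Slab geometry along the beam axis
#'
#' @param material Character vector of material names.
#' @param thickness Numeric vector of slab thicknesses in cm.
#' @return A `slab_geometry` data frame with upstream/downstream faces.
#' @export
slab_geometry <- function(material, thickness) {
  stopifnot(length(material) == length(thickness))
  if (any(thickness <= 0)) stop("slab thickness must be positive")
  g <- data.frame(material = material, thickness = thickness,
                  stringsAsFactors = FALSE)
  g$x_from <- cumsum(c(0, thickness[-length(thickness)]))
  g$x_to <- g$x_from + g$thickness
  class(g) <- c("slab_geometry", "data.frame")
  g
}

#' Two-target air-cavity phantom
#'
#' The reference phantom of the 63 MeV measurements: a thin PMMA target, an
#' air gap emulating an anatomical cavity, and a thick stopping PMMA block.
#' Widening the gap by `shift_cm` shifts the proton range downstream.
#'
#' @param thin_cm Thin target thickness in cm (default 1).
#' @param gap_cm Reference air-gap width in cm (default 3).
#' @param thick_cm Thick target thickness in cm (default 23).
#' @param shift_cm Extra gap width in cm (an implemented range shift).
#' @return A [slab_geometry()].
#' @export
two_target_geometry <- function(thin_cm = 1, gap_cm = 3, thick_cm = 23,
                                shift_cm = 0) {
  slab_geometry(c("pmma", "air", "pmma"),
                c(thin_cm, gap_cm + shift_cm, thick_cm))
}

#' Proton arrival-time map T_p(x)
#'
#' Cumulative proton arrival time at grid nodes along the beam axis, the
#' `T_p` term of the TOF decomposition TOF = T_p(r_v) + T_PG(r_v, r_d).
#' Inside a lossless air gap the slope equals the inverse speed at the energy
#' exiting the previous slab. The map ends where the proton stops; node times
#' are computed by fixed-step quadrature from each slab face, so refining
#' `grid_step` leaves shared nodes unchanged.
#'
#' @param geometry A [slab_geometry()].
#' @param entry_energy Beam kinetic energy in MeV.
#' @param grid_step Node spacing in cm (default 0.02).
#' @param model A [range_energy_model()].
#' @return An object of class `proton_time_map`: list with `x` (cm), `t_ps`,
#'   `energy` (MeV at each node), `range_end` (stopping position in cm),
#'   `entry_energy` and `geometry`.
#' @export
proton_time_map <- function(geometry, entry_energy, grid_step = 0.02,
                            model = range_energy_model()) {
  stopifnot(inherits(geometry, "slab_geometry"), grid_step > 0,
            entry_energy > 0)
  xs <- 0; ts <- 0; es <- entry_energy
  e_in <- entry_energy; t0 <- 0
  range_end <- NA_real_
  for (i in seq_len(nrow(geometry))) {
    mat <- geometry$material[i]
    row <- .material_row(mat, model)
    thick <- geometry$thickness[i]
    if (isTRUE(row$lossless)) {
      d_nodes <- seq(grid_step, thick, by = grid_step)
      if (!length(d_nodes) || max(d_nodes) < thick)
        d_nodes <- unique(c(d_nodes, thick))
      slope <- inverse_speed(e_in)
      xs <- c(xs, geometry$x_from[i] + d_nodes)
      ts <- c(ts, t0 + d_nodes * slope)
      es <- c(es, rep(e_in, length(d_nodes)))
      t0 <- t0 + thick * slope
    } else {
      r <- residual_range(e_in, mat, model)
      d_max <- min(thick, r)
      d_nodes <- seq(grid_step, d_max, by = grid_step)
      if (!length(d_nodes) || max(d_nodes) < d_max)
        d_nodes <- unique(c(d_nodes, d_max))
      t_nodes <- vapply(d_nodes, function(d)
        transit_time(e_in, d, mat, model), numeric(1))
      e_nodes <- energy_at_depth(e_in, d_nodes, mat, model)
      xs <- c(xs, geometry$x_from[i] + d_nodes)
      ts <- c(ts, t0 + t_nodes)
      es <- c(es, as.numeric(e_nodes))
      if (r <= thick) {
        range_end <- geometry$x_from[i] + r
        e_in <- 0
        break
      }
      t0 <- t0 + t_nodes[length(t_nodes)]
      e_in <- as.numeric(e_nodes[length(e_nodes)])
    }
  }
  if (is.na(range_end))
    stop("proton does not stop within the geometry; extend the last slab")
  if (any(diff(ts) <= 0))
    stop("proton time map is not strictly increasing")
  structure(list(x = xs, t_ps = ts, energy = es, range_end = range_end,
                 entry_energy = entry_energy, geometry = geometry,
                 model = model),
            class = "proton_time_map")
}

#' @export
print.proton_time_map <- function(x, ...) {
  cat(sprintf("Proton arrival-time map: %g MeV beam, %d nodes\n",
              x$entry_energy, length(x$x)))
  cat(sprintf("  stops at x = %.3f cm after %.1f ps\n",
              x$range_end, max(x$t_ps)))
  invisible(x)
}

#' Evaluate a proton time map at arbitrary positions
#'
#' Linear interpolation of T_p(x); positions beyond the stopping point take
#' the stopping-time value (the proton is at rest there).
#'
#' @param map A [proton_time_map()].
#' @param x Positions in cm.
#' @return Times in ps.
#' @export
eval_time_map <- function(map, x) {
  stopifnot(inherits(map, "proton_time_map"))
  if (any(x < 0)) stop("positions must be >= 0 (upstream of the phantom)")
  stats::approx(map$x, map$t_ps, xout = pmin(x, map$range_end),
                rule = 2)$y
}
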