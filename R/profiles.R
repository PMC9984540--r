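#' One-dimensional histogram with half-open bins
#'
#' Bins are half-open `[left, right)`; the final edge is exclusive, values on
#' it fall outside. Counts are non-negative at construction and may only go
#' negative after background subtraction.
#'
#' @param x Values to bin (ps or cm).
#' @param edges Strictly increasing bin edges; overrides `binwidth`/`range`.
#' @param binwidth Bin width used with `range` when `edges` is absent.
#' @param range Length-2 interval covered when building edges from
#'   `binwidth`; defaults to the data range padded to whole bins.
#' @return An object of class `hist1d`: list with `edges`, `counts`,
#'   `n_out` (values outside the edges).
#' @export
hist1d <- function(x, edges = NULL, binwidth = NULL, range = NULL) {
  if (is.null(edges)) {
    if (is.null(binwidth)) stop("provide either edges or binwidth")
    if (is.null(range)) {
      lo <- floor(min(x) / binwidth) * binwidth
      hi <- ceiling(max(x) / binwidth + 1e-9) * binwidth
    } else {
      lo <- range[1]; hi <- range[2]
    }
    edges <- seq(lo, hi, by = binwidth)
    if (edges[length(edges)] < hi) edges <- c(edges, hi)
  }
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  idx <- findInterval(x, edges)
  inside <- idx >= 1 & idx < length(edges) &
    x < edges[length(edges)]   # right edge exclusive
  counts <- tabulate(idx[inside], nbins = length(edges) - 1)
  structure(list(edges = edges, counts = as.numeric(counts),
                 n_out = sum(!inside)),
            class = "hist1d")
}

#' Construct a histogram from precomputed counts
#'
#' @param edges Strictly increasing bin edges.
#' @param counts Bin contents (length `length(edges) - 1`).
#' @return A `hist1d`.
#' @export
hist1d_from_counts <- function(edges, counts) {
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  stopifnot(length(counts) == length(edges) - 1)
  structure(list(edges = edges, counts = as.numeric(counts), n_out = 0L),
            class = "hist1d")
}

#' @export
print.hist1d <- function(x, ...) {
  cat(sprintf("hist1d: %d bins on [%g, %g), %g entries (%d outside)\n",
              length(x$counts), x$edges[1], x$edges[length(x$edges)],
              sum(x$counts), x$n_out))
  invisible(x)
}

#' Bin midpoints of a histogram
#' @param h A [hist1d()].
#' @return Numeric vector of bin centres.
#' @export
bin_centers <- function(h) (h$edges[-1] + h$edges[-length(h$edges)]) / 2

#' Convert a Gaussian FWHM to its rms width
#'
#' @param fwhm Full width at half maximum (>= 0).
#' @return `fwhm / (2 sqrt(2 ln 2))`.
#' @export
fwhm_to_rms <- function(fwhm) {
  if (any(fwhm < 0)) stop("fwhm must be non-negative")
  fwhm / (2 * sqrt(2 * log(2)))
}

#' Convert a Gaussian rms width to its FWHM
#' @param rms Standard deviation (>= 0).
#' @return `rms * 2 sqrt(2 ln 2)`.
#' @export
rms_to_fwhm <- function(rms) {
  if (any(rms < 0)) stop("rms must be non-negative")
  rms * (2 * sqrt(2 * log(2)))
}

#' Fit a Gaussian convolved with a fixed-width uniform to a TOF peak
#'
#' Least-squares fit of
#' `A [Phi((t - mu + w/2)/sigma) - Phi((t - mu - w/2)/sigma)] / w + B`
#' with the uniform width `w` held fixed: the TOF peak of a thin target is
#' the system response convolved with the (uniform) proton transit time, so
#' the Gaussian FWHM of the deconvolved fit is the coincidence time
#' resolution (CTR). `w = 0` reduces to a plain Gaussian fit.
#'
#' @param hist A [hist1d()] with at least 10 populated bins spanning the peak.
#' @param uniform_width Fixed uniform width `w` in the histogram units.
#' @return An object of class `ctr_fit`: list with `sigma`, `fwhm`,
#'   `centroid`, `amplitude`, `baseline`, `uniform_width` and standard
#'   errors `sigma_se`, `fwhm_se`.
#' @export
fit_gauss_conv_uniform <- function(hist, uniform_width = 0) {
  stopifnot(inherits(hist, "hist1d"), uniform_width >= 0)
  if (sum(hist$counts > 0) < 10)
    stop("need at least 10 populated bins to fit the peak")
  t <- bin_centers(hist)
  y <- hist$counts
  b0 <- stats::quantile(y, 0.1, names = FALSE)
  mu0 <- sum(t * pmax(y - b0, 0)) / max(sum(pmax(y - b0, 0)), 1e-12)
  s0 <- sqrt(max(sum((t - mu0)^2 * pmax(y - b0, 0)) /
                   max(sum(pmax(y - b0, 0)), 1e-12) -
                   uniform_width^2 / 12, (diff(range(t)) / 50)^2))
  shape <- function(t, mu, sigma, w) {
    if (w > 0) {
      (stats::pnorm((t - mu + w / 2) / sigma) -
         stats::pnorm((t - mu - w / 2) / sigma)) / w
    } else {
      stats::dnorm(t, mu, sigma)
    }
  }
  a0 <- max(y - b0) / max(shape(mu0, mu0, s0, uniform_width), 1e-12)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * shape(t, mu, sigma, uniform_width) + B,
      start = list(A = a0, mu = mu0, sigma = s0, B = b0),
      lower = c(A = 0, mu = -Inf, sigma = 1e-9, B = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("CTR fit failed to converge: ",
                             conditionMessage(e),
                             sprintf(" [n bins = %d, start sigma = %.3g]",
                                     length(y), s0)))
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  structure(list(sigma = unname(co["sigma"]),
                 fwhm = sigma_to_fwhm(unname(co["sigma"])),
                 centroid = unname(co["mu"]),
                 amplitude = unname(co["A"]),
                 baseline = unname(co["B"]),
                 uniform_width = uniform_width,
                 sigma_se = unname(se["sigma"]),
                 fwhm_se = sigma_to_fwhm(unname(se["sigma"])),
                 amplitude_se = unname(se["A"]),
                 fit = fit),
            class = "ctr_fit")
}

#' @export
print.ctr_fit <- function(x, ...) {
  cat(sprintf("CTR fit: FWHM = %.1f +/- %.1f (sigma %.1f, uniform width %g)\n",
              x$fwhm, x$fwhm_se, x$sigma, x$uniform_width))
  cat(sprintf("  centroid %.1f, amplitude %.3g, baseline %.3g\n",
              x$centroid, x$amplitude, x$baseline))
  invisible(x)
}

.bins_within <- function(h, window) {
  h$edges[-length(h$edges)] >= window[1] & h$edges[-1] <= window[2]
}

#' Subtract a flat background estimated from an off-signal window
#'
#' The mean bin content over the off-signal window is subtracted from every
#' bin, without clamping (bins may go slightly negative). The subtracted
#' level and its standard error are attached as attributes `level` and
#' `level_se`.
#'
#' @param hist A [hist1d()].
#' @param off_window Length-2 interval containing only background.
#' @param signal_window Optional length-2 interval of the signal region; if
#'   given, the off-window must be disjoint from it.
#' @return The background-subtracted `hist1d`.
#' @export
subtract_flat_background <- function(hist, off_window, signal_window = NULL) {
  stopifnot(inherits(hist, "hist1d"), length(off_window) == 2)
  if (!is.null(signal_window) &&
      off_window[1] < signal_window[2] && signal_window[1] < off_window[2])
    stop("off-signal window overlaps the signal region")
  sel <- .bins_within(hist, off_window)
  if (!any(sel)) stop("off-signal window contains no complete bin")
  level <- mean(hist$counts[sel])
  out <- hist
  out$counts <- hist$counts - level
  attr(out, "level") <- level
  attr(out, "level_se") <- stats::sd(hist$counts[sel]) / sqrt(sum(sel))
  out
}

#' Fit and subtract a reconstructed-background template
#'
#' The spatial image of a TOF-flat background is not flat (see
#' [background_template()]). Its amplitude is fitted by least squares on an
#' off-signal region of the reconstructed profile and the scaled template is
#' subtracted bin-wise. The fitted amplitude is attached as attribute
#' `amplitude`.
#'
#' @param hist Reconstructed spatial profile, a [hist1d()].
#' @param template A [background_template()] with identical bin edges.
#' @param off_region Length-2 spatial interval containing only background.
#' @return The template-subtracted `hist1d`.
#' @export
subtract_pgti_background <- function(hist, template, off_region) {
  stopifnot(inherits(hist, "hist1d"), inherits(template, "hist1d"))
  if (length(hist$edges) != length(template$edges) ||
      max(abs(hist$edges - template$edges)) > 1e-9)
    stop("histogram and template binning differ")
  sel <- .bins_within(hist, off_region)
  if (!any(sel)) stop("off-signal region contains no complete bin")
  tc <- template$counts * diff(template$edges)  # expected counts shape
  denom <- sum(tc[sel]^2)
  a <- if (denom > 0) sum(hist$counts[sel] * tc[sel]) / denom else 0
  out <- hist
  out$counts <- hist$counts - a * tc
  attr(out, "amplitude") <- a
  out
}

# cumulative distribution at bin edges (starts at 0, ends at 1)
.edge_cdf <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("profile has no counts")
  c(0, cumsum(counts)) / total
}

# inverse of the edge CDF by linear interpolation (first crossing)
.invert_cdf <- function(edges, cdf, y) {
  if (y < cdf[1] || y > cdf[length(cdf)])
    stop("target cumulative level outside the profile's range")
  i <- which(cdf >= y)[1]
  if (i == 1) return(edges[1])
  dy <- cdf[i] - cdf[i - 1]
  if (dy <= 0) return(edges[i - 1])
  edges[i - 1] + (y - cdf[i - 1]) / dy * (edges[i] - edges[i - 1])
}

#' Integral fall-off shift between a profile and a reference
#'
#' The range-shift statistic: both profiles are integrated into normalised
#' cumulative functions, the reference position `x_ref` is the distal maximum
#' of the reference profile (the peak location within the distal part of its
#' support), `y_ref` is the reference cumulative level there, and the shift
#' is `d = F_profile^{-1}(y_ref) - x_ref` by linear inverse interpolation.
#' Using the integral filters bin noise and makes no assumption about the
#' profile shape; the statistic is invariant under rescaling of either
#' profile's total counts and equivariant under common translations.
#'
#' @param profile Measured profile, a [hist1d()] (TOF in ps, or position in
#'   cm for reconstructed profiles).
#' @param reference High-statistics simulated reference profile on any grid
#'   covering `x_ref`.
#' @param distal_fraction Fraction of the reference support (from its
#'   upstream edge) excluded when locating the distal maximum.
#' @param x_ref Optional override of the reference position.
#' @return A list of class `falloff_shift` with `d`, `x_ref`, `y_ref` and
#'   `n_events` (total profile counts).
#' @export
falloff_shift <- function(profile, reference, distal_fraction = 0.5,
                          x_ref = NULL) {
  stopifnot(inherits(profile, "hist1d"), inherits(reference, "hist1d"))
  if (is.null(x_ref))
    x_ref <- .distal_maximum(reference, distal_fraction)
  cdf_ref <- .edge_cdf(reference$counts)
  y_ref <- stats::approx(reference$edges, cdf_ref, xout = x_ref)$y
  if (is.na(y_ref)) stop("x_ref lies outside the reference histogram")
  cdf_p <- .edge_cdf(profile$counts)
  d <- .invert_cdf(profile$edges, cdf_p, y_ref) - x_ref
  structure(list(d = d, x_ref = x_ref, y_ref = y_ref,
                 n_events = sum(profile$counts)),
            class = "falloff_shift")
}

# distal maximum: peak location restricted to the distal part of the support
.distal_maximum <- function(reference, distal_fraction = 0.5) {
  ctr <- bin_centers(reference)
  pop <- which(reference$counts > 0)
  if (!length(pop)) stop("reference profile is empty")
  lo <- ctr[pop[1]]
  hi <- ctr[pop[length(pop)]]
  window <- ctr >= lo + distal_fraction * (hi - lo)
  cand <- which(window & reference$counts == max(reference$counts[window]))
  ctr[cand[length(cand)]]
}

#' @export
print.falloff_shift <- function(x, ...) {
  cat(sprintf("fall-off shift d = %.2f (x_ref = %.2f, y_ref = %.3f, n = %g)\n",
              x$d, x$x_ref, x$y_ref, x$n_events))
  invisible(x)
}
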