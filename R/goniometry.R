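#' Refraction correction of goniometer detector angles
#'
#' A goniometer reads the detector angle in air, but the scattering event
#' happens inside a medium of higher refractive index, so light refracts at
#' the sample surface on its way out. For a thin sample far from the
#' detector the mapping reduces to Snell's law about the nearer surface
#' normal:
#' `theta_scat = asin((n_det / n_sample) * sin(theta_meas))` for detector
#' angles below 90 degrees and `180 - asin(...)` above. The correction
#' compresses the effective angular sampling range towards each normal.
#'
#' @param theta_meas detector angle(s) relative to the incident beam,
#'   degrees in \[0, 180\], excluding 90 (grazing, undefined branch).
#' @param n_sample refractive index of the scattering medium.
#' @param n_det refractive index on the detector side (air by default).
#' @return scattering angle(s), degrees.
#' @export
#' @examples
#' refraction_correct(60, n_sample = 1.556)  # about 33.8 degrees
refraction_correct <- function(theta_meas, n_sample, n_det = 1) {
  stopifnot(n_sample > 0, n_det > 0)
  if (n_sample < n_det) stop("n_sample must be >= n_det")
  if (any(theta_meas < 0 | theta_meas > 180)) {
    stop("theta_meas must lie in [0, 180] degrees")
  }
  if (any(theta_meas == 90)) {
    stop("theta_meas = 90 degrees lies on neither branch of the correction")
  }
  th <- theta_meas * pi / 180
  inner <- asin((n_det / n_sample) * sin(th)) * 180 / pi
  ifelse(theta_meas < 90, inner, 180 - inner)
}

#' Solid angle subtended by a circular detector aperture
#'
#' Planar-disc approximation `Omega = pi * (d / 2)^2 / D^2`, valid when the
#' aperture is small compared with its distance from the sample.
#'
#' @param aperture_diameter aperture diameter, mm.
#' @param detector_distance sample-to-aperture distance, mm.
#' @return solid angle in steradians.
#' @export
#' @examples
#' detector_solid_angle(8.2, 128)  # about 3.2e-3 sr
detector_solid_angle <- function(aperture_diameter, detector_distance) {
  stopifnot(aperture_diameter > 0, detector_distance > 0)
  if (aperture_diameter >= detector_distance) {
    warning("aperture comparable to detector distance; planar-disc approximation invalid")
  }
  pi * (aperture_diameter / 2)^2 / detector_distance^2
}

#' Goniometry dataset container
#'
#' Bundles a raw angle scan with the geometry needed to reduce it: the
#' detector angles (degrees, instrument frame), the measured intensities,
#' and the refractive indices, aperture and sample geometry.
#'
#' @param angles_meas detector angles, degrees in \[0, 180\]; the occluded
#'   band (60, 120) must be absent.
#' @param intensity measured intensity at each angle (arbitrary units before
#'   correction).
#' @param n_sample,n_det refractive indices (sample side and detector side).
#' @param aperture_diameter,detector_distance detector aperture geometry, mm.
#' @param sample_thickness sample thickness, mm.
#' @return An object of class `goniometry_dataset`.
#' @export
goniometry_dataset <- function(angles_meas, intensity, n_sample = 1.556,
                               n_det = 1, aperture_diameter = 8.2,
                               detector_distance = 128,
                               sample_thickness = 0.33) {
  stopifnot(length(angles_meas) == length(intensity))
  if (any(angles_meas < 0 | angles_meas > 180)) {
    stop("angles must lie in [0, 180] degrees")
  }
  if (any(angles_meas > 60 & angles_meas < 120)) {
    stop("angles in the occluded band (60, 120) degrees are not measurable")
  }
  if (n_sample <= n_det) stop("n_sample must exceed n_det")
  structure(list(angles_meas = angles_meas, intensity = intensity,
                 n_sample = n_sample, n_det = n_det,
                 aperture_diameter = aperture_diameter,
                 detector_distance = detector_distance,
                 sample_thickness = sample_thickness),
            class = "goniometry_dataset")
}

#' Normalize and background-correct a goniometer scan
#'
#' Converts raw per-angle intensities into per-steradian phase-function
#' samples: the matching clear-matrix (scatterer-free) angular scan is
#' subtracted to remove surface-scattering background, and the result is
#' divided by the detector solid angle and the clear-sample total
#' transmission. Negative post-subtraction values are floored at zero and
#' flagged (the angular grid is kept intact).
#'
#' @param raw a [goniometry_dataset()].
#' @param clear_total_transmission total transmission of the clear reference
#'   sample, fraction in (0, 1\].
#' @param clear_angular clear-sample angular scan aligned to `raw`; use zeros
#'   to skip the subtraction. The 0-degree entry (unscattered beam) is not
#'   subtracted.
#' @return data frame with `angle_meas`, `angle_scat`, `value` (per
#'   steradian) and `floored` (logical).
#' @export
normalize_and_correct <- function(raw, clear_total_transmission,
                                  clear_angular = NULL) {
  stopifnot(inherits(raw, "goniometry_dataset"))
  if (clear_total_transmission <= 0 || clear_total_transmission > 1) {
    stop("clear_total_transmission must lie in (0, 1]")
  }
  if (is.null(clear_angular)) clear_angular <- numeric(length(raw$intensity))
  if (length(clear_angular) != length(raw$intensity)) {
    stop("clear_angular must align with the raw angle grid")
  }
  omega <- detector_solid_angle(raw$aperture_diameter, raw$detector_distance)
  sub <- ifelse(raw$angles_meas == 0, 0, clear_angular)
  val <- (raw$intensity - sub) / (omega * clear_total_transmission)
  floored <- val < 0
  val[floored] <- 0
  data.frame(angle_meas = raw$angles_meas,
             angle_scat = refraction_correct(raw$angles_meas, raw$n_sample,
                                             raw$n_det),
             value = val, floored = floored)
}

#' Fit one Henyey-Greenstein lobe to a section of a corrected scan
#'
#' Weighted nonlinear least squares of `s * stHG(g)` against per-steradian
#' phase-function samples from either the forward (`theta_meas < 60`) or
#' backward (`theta_meas > 120`) section. Because forward-scattering data
#' spans orders of magnitude, each point is weighted by
#' `max(values) / value`, which equalizes the relative influence of all
#' angles. The scale `s` is profiled out in closed form (weighted linear
#' regression through the origin at fixed `g`), leaving a one-dimensional
#' search over `g` on its section-specific bounds, solved by a coarse grid
#' scan refined with golden-section search.
#'
#' @param angles_scat refraction-corrected scattering angles, degrees.
#' @param values per-steradian phase-function samples (non-negative).
#' @param section `"forward"` (g in \[0, 1)) or `"backward"` (g in (-1, 0\]).
#' @return list with `g`, `s` (scale), `rss` (weighted residual sum of
#'   squares) and `n_used`.
#' @details The weight multiplies the residual, so the minimized objective
#'   is the sum of squared *relative* deviations (scaled by the section
#'   maximum) — the appropriate treatment when measurement noise is
#'   proportional to the signal.
#' @export
fit_sthg_section <- function(angles_scat, values,
                             section = c("forward", "backward")) {
  section <- match.arg(section)
  keep <- is.finite(values) & values > 0
  angles_scat <- angles_scat[keep]
  values <- values[keep]
  if (length(values) == 0 || all(values == 0)) {
    stop("no positive measurements in this section; cannot fit")
  }
  if (length(values) < 3) stop("need at least 3 positive points to fit a lobe")
  ct <- cos(angles_scat * pi / 180)
  w <- (max(values) / values)^2
  obj <- function(g) {
    p <- hg_density(g, ct)
    s <- sum(w * p * values) / sum(w * p^2)
    sum(w * (s * p - values)^2)
  }
  bounds <- if (section == "forward") c(0, 0.999) else c(-0.999, 0)
  grid <- seq(bounds[1], bounds[2], length.out = 101)
  rg <- vapply(grid, obj, numeric(1))
  i <- which.min(rg)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(obj, lower = lo, upper = hi, tol = 1e-9)
  g <- opt$minimum
  p <- hg_density(g, ct)
  s <- sum(w * p * values) / sum(w * p^2)
  if (!is.finite(s) || s <= 0) stop("section fit failed to produce a positive scale")
  list(g = g, s = s, rss = opt$objective, n_used = length(values))
}

#' Combine forward and backward lobe fits into two-term HG parameters
#'
#' The forward fraction is the ratio of the fitted scale factors,
#' `alpha = s_f / (s_f + s_b)`; the lobe anisotropies carry through.
#'
#' @param s_f,s_b fitted scales of the forward and backward lobes (>= 0, not
#'   both zero).
#' @param g_f,g_b fitted forward and backward anisotropies.
#' @return a [tthg_params()] object.
#' @export
#' @examples
#' combine_tthg(0.855, 0.145, 0.983, 0)  # g1 = 0.84
combine_tthg <- function(s_f, s_b, g_f, g_b) {
  stopifnot(s_f >= 0, s_b >= 0)
  if (s_f == 0 && s_b == 0) stop("s_f and s_b cannot both be zero")
  tthg_params(alpha = s_f / (s_f + s_b), gf = g_f, gb = g_b)
}

#' Fit a two-term HG phase function to a goniometer scan
#'
#' Full reduction pipeline: background-correct and normalize the scan
#' ([normalize_and_correct()]), split it at the instrument's occlusion band
#' (forward: measured angle < 60 degrees, 0 degrees excluded as it contains
#' the unscattered beam; backward: measured angle > 120 degrees), fit each
#' lobe ([fit_sthg_section()]), and combine ([combine_tthg()]). Because each
#' lobe's tail leaks into the other's section, the pipeline alternates:
#' after an initial backward fit, the fitted backward pedestal is subtracted
#' from the forward section before the forward fit, and vice versa, for
#' `refine` rounds. One round removes essentially all of the leakage bias
#' for forward-dominated materials.
#'
#' @param raw a [goniometry_dataset()].
#' @inheritParams normalize_and_correct
#' @param refine number of cross-subtraction refinement rounds (at least
#'   one; the forward lobe is refit once more against the final backward
#'   pedestal so the combined pair is mutually consistent).
#' @return a [tthg_params()] object with attributes `s_f`, `s_b`,
#'   `forward_fit`, `backward_fit` and `corrected` (the reduced scan).
#' @export
fit_goniometry <- function(raw, clear_total_transmission, clear_angular = NULL,
                           refine = 2) {
  corr <- normalize_and_correct(raw, clear_total_transmission, clear_angular)
  # sections split at the instrument's occlusion band; the measured 60 and
  # 120 degree endpoints belong to their respective sections, while the
  # 0 degree transmission point (unscattered beam) is excluded
  fwd <- corr$angle_meas > 0 & corr$angle_meas <= 60
  bwd <- corr$angle_meas >= 120
  if (!any(fwd) || !any(bwd)) stop("need measurements in both sections")
  ct_f <- cos(corr$angle_scat[fwd] * pi / 180)
  ct_b <- cos(corr$angle_scat[bwd] * pi / 180)

  fit_b <- fit_sthg_section(corr$angle_scat[bwd], corr$value[bwd], "backward")
  fit_f <- NULL
  for (k in seq_len(max(refine, 1))) {
    vf <- corr$value[fwd] - fit_b$s * hg_density(fit_b$g, ct_f)
    fit_f <- fit_sthg_section(corr$angle_scat[fwd], vf, "forward")
    vb <- corr$value[bwd] - fit_f$s * hg_density(fit_f$g, ct_b)
    fit_b <- fit_sthg_section(corr$angle_scat[bwd], vb, "backward")
  }
  vf <- corr$value[fwd] - fit_b$s * hg_density(fit_b$g, ct_f)
  fit_f <- fit_sthg_section(corr$angle_scat[fwd], vf, "forward")
  out <- combine_tthg(fit_f$s, fit_b$s, fit_f$g, fit_b$g)
  attr(out, "s_f") <- fit_f$s
  attr(out, "s_b") <- fit_b$s
  attr(out, "forward_fit") <- fit_f
  attr(out, "backward_fit") <- fit_b
  attr(out, "corrected") <- corr
  out
}

#' Scattering-coefficient and optical-thickness bounds from anisotropy bounds
#'
#' Single-scattering goniometry requires an optically thin sample. Given a
#' reduced scattering coefficient and a literature range for the anisotropy,
#' the scattering coefficient is bracketed by `mus = mus_prime / (1 - g)`
#' and the sample's optical thickness (in scattering mean free paths) by
#' `thickness * mus`.
#'
#' @param mus_prime reduced scattering coefficient, 1/mm.
#' @param g_low,g_high anisotropy bounds, `0 < g_low <= g_high < 1`.
#' @param thickness physical sample thickness, mm.
#' @return An object of class `mfp_estimate`: `mus_low`, `mus_high` (1/mm)
#'   and `mfp_low`, `mfp_high` (mean free paths).
#' @export
#' @examples
#' estimate_optical_thickness(0.334, 0.8, 0.9, 0.33)
estimate_optical_thickness <- function(mus_prime, g_low, g_high, thickness) {
  stopifnot(mus_prime > 0, thickness > 0)
  if (!(g_low > 0 && g_low <= g_high && g_high < 1)) {
    stop("need 0 < g_low <= g_high < 1")
  }
  mus_low <- mus_prime / (1 - g_low)
  mus_high <- mus_prime / (1 - g_high)
  structure(list(mus_low = mus_low, mus_high = mus_high,
                 mfp_low = thickness * mus_low, mfp_high = thickness * mus_high),
            class = "mfp_estimate")
}

#' @export
print.mfp_estimate <- function(x, ...) {
  cat(sprintf("mus in [%.3g, %.3g] 1/mm; optical thickness in [%.3g, %.3g] MFP\n",
              x$mus_low, x$mus_high, x$mfp_low, x$mfp_high))
  invisible(x)
}

#' Write / read a goniometry dataset as CSV with a metadata header
#'
#' The header carries the geometry as `# key: value` lines, followed by a
#' two-column `angle_deg,intensity` table.
#'
#' @param dataset a [goniometry_dataset()].
#' @param path file path.
#' @export
write_goniometry <- function(dataset, path) {
  stopifnot(inherits(dataset, "goniometry_dataset"))
  hdr <- sprintf("# %s: %.17g",
                 c("n_sample", "n_det", "aperture_diameter",
                   "detector_distance", "sample_thickness"),
                 c(dataset$n_sample, dataset$n_det, dataset$aperture_diameter,
                   dataset$detector_distance, dataset$sample_thickness))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("angle_deg,intensity", con)
  writeLines(sprintf("%.17g,%.17g", dataset$angles_meas, dataset$intensity), con)
  invisible(path)
}

#' @rdname write_goniometry
#' @export
read_goniometry <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#\\s*", "", hdr), ":\\s*")
  meta <- vapply(kv, function(x) as.numeric(x[2]), numeric(1))
  names(meta) <- vapply(kv, `[[`, character(1), 1)
  body <- read.table(text = lines[!grepl("^#", lines)], header = TRUE, sep = ",")
  goniometry_dataset(body$angle_deg, body$intensity,
                     n_sample = meta[["n_sample"]], n_det = meta[["n_det"]],
                     aperture_diameter = meta[["aperture_diameter"]],
                     detector_distance = meta[["detector_distance"]],
                     sample_thickness = meta[["sample_thickness"]])
}
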