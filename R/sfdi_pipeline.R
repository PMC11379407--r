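signed_freqs <- function(n) {
  k <- seq_len(n) - 1
  ifelse(k > n / 2, k / n - 1, k / n)
}

raised_cosine <- function(d, w) {
  b <- numeric(length(d))
  inside <- abs(d) < w
  b[inside] <- cos(pi * d[inside] / (2 * w))^2
  b
}

# band-stop profile: flat zero core of half-width `core`, raised-cosine
# edges of width `edge`. A flat core wider than the smoothing kernel keeps
# the stopband closed after Gaussian smoothing.
flat_stop <- function(d, core, edge) {
  out <- rep(1, length(d))
  a <- abs(d)
  out[a <= core] <- 0
  roll <- a > core & a < core + edge
  out[roll] <- sin(pi * (a[roll] - core) / (2 * edge))^2
  out
}

gauss_smooth_circular <- function(v, sigma = 1) {
  half <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(v)
  idx <- outer(seq_len(n), seq(-half, half), function(i, o) ((i + o - 1) %% n) + 1)
  as.vector(matrix(v[idx], n) %*% k)
}

#' Single-phase Fourier-domain demodulation
#'
#' Extracts per-pixel DC and AC intensity from a single sinusoidally
#' patterned frame (modulation along the image columns) by filtering in the
#' 2D Fourier domain.
#'
#' In `"notch"` mode the DC image is obtained by removing the positive and
#' negative AC peaks (plus `harmonics_to_remove` harmonic pairs) with
#' inverted raised-cosine bandstop filters, smoothed by a Gaussian of
#' standard deviation 1 frequency pixel to limit ringing. The AC image
#' removes the DC peak, the negative AC peak and the harmonic pairs, keeps
#' the positive lobe, and doubles the inverse-transform magnitude to
#' account for the discarded conjugate, so a pure cosine of modulation
#' amplitude `a` demodulates to `m_ac = a`.
#'
#' In `"anisotropic"` mode the same operations use directional masks that
#' are narrow along the modulation axis (half-width `0.15 fx` by default)
#' and wide along the orthogonal axis, which preserves image detail when
#' the DC and AC peaks are closely spaced.
#'
#' @param image 2D intensity matrix (rows y, columns x), exposure
#'   normalized.
#' @param fx pattern spatial frequency, 1/mm; needs at least 4 pixels per
#'   period on the grid.
#' @param pixel_pitch mm per pixel.
#' @param mode `"notch"` or `"anisotropic"`.
#' @param harmonics_to_remove number of harmonic pairs notched beyond the
#'   fundamental.
#' @param notch_halfwidth,dc_halfwidth,ortho_halfwidth filter half-widths as
#'   fractions of `fx` (`notch`, the AC/harmonic stops), of `fx` (`dc`, the
#'   DC-peak stop used for the AC image) and of the orthogonal Nyquist
#'   (`ortho`, anisotropic mode only).
#' @return An object of class `demodulated_image` with per-pixel `m_dc` and
#'   `m_ac` matrices, `fx` and `pixel_pitch`.
#' @export
fourier_demod_single <- function(image, fx, pixel_pitch,
                                 mode = c("notch", "anisotropic"),
                                 harmonics_to_remove = 2,
                                 notch_halfwidth = 0.25, dc_halfwidth = 0.5,
                                 ortho_halfwidth = 0.8) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(image), fx > 0, pixel_pitch > 0)
  f0 <- fx * pixel_pitch  # cycles per pixel along x
  if (f0 >= 0.5) stop("pattern frequency at or beyond the pixel Nyquist limit")
  if (f0 > 0.25) stop("need at least 4 pixels per pattern period")
  nx <- ncol(image)
  ny <- nrow(image)
  u <- signed_freqs(nx)
  v <- signed_freqs(ny)
  db <- 1 / nx  # one frequency bin along the modulation axis
  # flat stop cores no narrower than the smoothing kernel's support
  wn <- max(notch_halfwidth * f0, 3 * db)
  w0 <- max(dc_halfwidth * f0, 3 * db)
  edge <- max(1.5 * db, 0.25 * wn)
  # the DC stop (plus edge and smoothing) must not reach the AC peak
  w0 <- min(w0, max(f0 - edge - 3 * db, 2 * db))

  stop_at <- function(center, core) flat_stop(u - center, core, edge)
  dc_mask_u <- rep(1, nx)
  for (h in seq_len(1 + harmonics_to_remove)) {
    dc_mask_u <- dc_mask_u * stop_at(h * f0, wn) * stop_at(-h * f0, wn)
  }
  ac_mask_u <- stop_at(0, w0) * stop_at(-f0, wn)
  for (h in 1 + seq_len(harmonics_to_remove)) {
    ac_mask_u <- ac_mask_u * stop_at(h * f0, wn) * stop_at(-h * f0, wn)
  }
  dc_mask_u <- gauss_smooth_circular(dc_mask_u)
  ac_mask_u <- gauss_smooth_circular(ac_mask_u)

  if (mode == "notch") {
    dc_mask <- matrix(dc_mask_u, ny, nx, byrow = TRUE)
    ac_mask <- matrix(ac_mask_u, ny, nx, byrow = TRUE)
  } else {
    # directional masks: stops act near the v axis and release away from
    # it; the AC image keeps a band-pass around the positive lobe that is
    # narrow in u and wide in v
    wv <- ortho_halfwidth * 0.5
    vband <- raised_cosine(v, wv)
    dc_mask <- 1 - outer(vband, 1 - dc_mask_u)
    keep_u <- gauss_smooth_circular(
      1 - flat_stop(u - f0, max(notch_halfwidth, 0.15) * f0, edge))
    ac_mask <- outer(vband, keep_u)
  }

  F <- fft(image)
  m_dc <- Re(fft(F * dc_mask, inverse = TRUE)) / (nx * ny)
  m_ac <- 2 * Mod(fft(F * ac_mask, inverse = TRUE)) / (nx * ny)
  structure(list(m_dc = m_dc, m_ac = m_ac, fx = fx,
                 pixel_pitch = pixel_pitch, mode = mode),
            class = "demodulated_image")
}

#' @export
print.demodulated_image <- function(x, ...) {
  cat(sprintf("demodulated image %dx%d at fx = %.3g /mm (%s): mean DC %.4g, mean AC %.4g\n",
              nrow(x$m_dc), ncol(x$m_dc), x$fx, x$mode, mean(x$m_dc),
              mean(x$m_ac)))
  invisible(x)
}

#' Reference calibration of demodulated intensities
#'
#' Converts demodulated sample intensities into reflectance using a
#' reference measurement of known optical properties:
#' `Rd = (M / M_ref) * Rd_ref_pred`, channel-wise for DC and AC. The ratio
#' cancels the projector intensity profile and system transfer function.
#' Pixels where the reference is non-positive are masked (NA).
#'
#' @param sample,reference [fourier_demod_single()] results of identical
#'   shape.
#' @param rd_ref_pred predicted reflectance of the reference at the
#'   acquisition frequency (a [reflectance_pair()]).
#' @return a [reflectance_pair()] holding per-pixel DC and AC reflectance
#'   matrices.
#' @export
calibrate <- function(sample, reference, rd_ref_pred) {
  stopifnot(inherits(sample, "demodulated_image"),
            inherits(reference, "demodulated_image"),
            inherits(rd_ref_pred, "reflectance_pair"))
  if (!all(dim(sample$m_dc) == dim(reference$m_dc))) {
    stop("sample and reference shapes differ")
  }
  bad_dc <- !(reference$m_dc > 0)
  bad_ac <- !(reference$m_ac > 0)
  dc <- sample$m_dc / reference$m_dc * rd_ref_pred$dc
  ac <- sample$m_ac / reference$m_ac * rd_ref_pred$ac
  dc[bad_dc] <- NA_real_
  ac[bad_ac] <- NA_real_
  reflectance_pair(dc = dc, ac = ac, fx = sample$fx)
}

#' Invert per-pixel reflectance pairs into optical-property maps
#'
#' Looks up each pixel's (DC, AC) reflectance in a precomputed inversion
#' table by bilinear interpolation in log-reflectance coordinates (and log
#' property values). Pixels are marked undetermined when their AC
#' reflectance reaches or exceeds the DC value (no physical solution for a
#' low-pass scattering medium), when either value falls outside the table
#' grid, or when a surrounding table node is itself flagged or uncovered.
#'
#' @param rd a [reflectance_pair()] with per-pixel matrices (from
#'   [calibrate()]).
#' @param lut an [build_lut()] inversion table at the same spatial
#'   frequency.
#' @return An object of class `property_map`: `mua_map`,
#'   `mus_prime_map` (1/mm, NA where undetermined) and
#'   `undetermined_mask`.
#' @export
invert_map <- function(rd, lut) {
  stopifnot(inherits(rd, "reflectance_pair"), inherits(lut, "inversion_lut"))
  if (!is.na(rd$fx) && !isTRUE(all.equal(rd$fx, lut$fx))) {
    stop("LUT spatial frequency does not match the acquisition")
  }
  dc <- as.vector(rd$dc)
  ac <- as.vector(rd$ac)
  lx <- log(lut$dc_grid)
  ly <- log(lut$ac_grid)
  n1 <- length(lx)
  n2 <- length(ly)
  x <- log(dc)
  y <- log(ac)
  ok <- is.finite(x) & is.finite(y) & ac < dc &
    x >= lx[1] & x <= lx[n1] & y >= ly[1] & y <= ly[n2]
  i <- pmin(pmax(findInterval(x, lx), 1L), n1 - 1L)
  j <- pmin(pmax(findInterval(y, ly), 1L), n2 - 1L)
  tx <- (x - lx[i]) / (lx[i + 1] - lx[i])
  ty <- (y - ly[j]) / (ly[j + 1] - ly[j])
  interp <- function(surface) {
    s <- log(surface)
    v00 <- s[cbind(i, j)]
    v10 <- s[cbind(i + 1L, j)]
    v01 <- s[cbind(i, j + 1L)]
    v11 <- s[cbind(i + 1L, j + 1L)]
    exp((1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
          (1 - tx) * ty * v01 + tx * ty * v11)
  }
  mua <- mus <- rep(NA_real_, length(dc))
  if (any(ok)) {
    mua[ok] <- interp(lut$mua_surface)[ok]
    mus[ok] <- interp(lut$mus_prime_surface)[ok]
  }
  und <- !is.finite(mua) | !is.finite(mus)
  mua[und] <- NA_real_
  mus[und] <- NA_real_
  shape <- dim(rd$dc) %||% length(dc)
  structure(list(mua_map = array(mua, shape),
                 mus_prime_map = array(mus, shape),
                 undetermined_mask = array(und, shape), fx = lut$fx),
            class = "property_map")
}

#' @export
print.property_map <- function(x, ...) {
  cat(sprintf("property map %s: %.1f%% undetermined; mua median %.3g, mus' median %.3g /mm\n",
              paste(dim(x$mua_map), collapse = "x"),
              100 * mean(x$undetermined_mask),
              stats::median(x$mua_map, na.rm = TRUE),
              stats::median(x$mus_prime_map, na.rm = TRUE)))
  invisible(x)
}

#' Inverse Monte Carlo optical-property fit
#'
#' Determines absorption and reduced scattering from integrating-sphere
#' style measurements by iterating a forward Monte Carlo slab model inside
#' a nonnegative least-squares search. Two measurement modes are
#' supported: `"thin_RT"` fits the diffuse reflectance and transmittance of
#' a thin slab (1 mm beam, cyclic 2 mm lateral box), and
#' `"thick_R_transflectance"` fits the reflectance of an optically thick
#' block (4 mm beam) together with the thin sample's transflectance (one
#' minus its absorbed fraction).
#'
#' Each objective evaluation reruns the forward model with the same seed
#' (common random numbers), making the stochastic objective effectively
#' deterministic and smooth enough for a Nelder-Mead search on
#' square-root-transformed properties, which enforces nonnegativity while
#' allowing exact zeros.
#'
#' @param measurements measured fractions in \[0, 1\]: `c(R, T)` for
#'   `"thin_RT"`, `c(R_thick, transflectance)` for the other mode.
#' @param mode measurement mode.
#' @param spf phase function of the material.
#' @param thickness thin-sample thickness, mm.
#' @param thick_depth thick-block depth, mm.
#' @param n_medium medium refractive index.
#' @param init optional starting `c(mua, mus_prime)`; defaults to
#'   `c(0.1, 1)`.
#' @param n_photons photons per objective evaluation.
#' @param seed RNG seed reused at every evaluation.
#' @param maxit Nelder-Mead iteration cap.
#' @return list with `mua`, `mus_prime`, `residual` (objective at the
#'   optimum), `fitted` (modelled measurements) and `convergence`.
#' @export
inverse_mc_fit <- function(measurements,
                           mode = c("thin_RT", "thick_R_transflectance"),
                           spf, thickness, thick_depth = 17,
                           n_medium = 1.56, init = NULL, n_photons = 2e4,
                           seed = 7, maxit = 150) {
  mode <- match.arg(mode)
  stopifnot(length(measurements) == 2, all(measurements >= 0),
            all(measurements <= 1), thickness > 0)
  forward <- function(mua, mus_prime) {
    cfg <- transport_config(mua = mua, spf = spf, mus_prime = mus_prime,
                            n_medium = n_medium, n_photons = n_photons,
                            seed = seed)
    if (mode == "thin_RT") {
      s <- simulate_slab(cfg, thickness, beam_diameter = 1, lateral_period = 2)
      c(s$R, s$T)
    } else {
      thick <- simulate_slab(cfg, thick_depth, beam_diameter = 4,
                             lateral_period = 8)
      thin <- simulate_slab(cfg, thickness, beam_diameter = 1,
                            lateral_period = 2)
      c(thick$R, thin$transflectance)
    }
  }
  obj <- function(p) {
    m <- forward(p[1]^2, max(p[2]^2, 1e-6))
    sum((m - measurements)^2)
  }
  if (is.null(init)) init <- c(0.1, 1)
  opt <- optim(sqrt(init), obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-8))
  # restart from the incumbent: Nelder-Mead simplices collapse easily on
  # the slightly rough common-random-number objective
  opt2 <- optim(opt$par, obj, method = "Nelder-Mead",
                control = list(maxit = maxit, reltol = 1e-8))
  if (opt2$value <= opt$value) opt <- opt2
  noise_floor <- 4 * length(measurements) / n_photons
  if (opt$convergence > 1 && opt$value > noise_floor) {
    stop("inverse MC fit failed to converge: code ", opt$convergence,
         " (residual ", format(opt$value), ")")
  }
  mua <- opt$par[1]^2
  mus_prime <- max(opt$par[2]^2, 1e-6)
  list(mua = mua, mus_prime = mus_prime, residual = opt$value,
       fitted = forward(mua, mus_prime), convergence = opt$convergence)
}
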