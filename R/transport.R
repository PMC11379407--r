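#' Speed of light in vacuum, mm/ns
#' @noRd
C_MM_NS <- 299.792458

#' Monte Carlo transport configuration
#'
#' Collects the optical properties, geometry-independent settings and seed
#' for a photon-transport run. Either `mus` or `mus_prime` must be given;
#' when `mus_prime` is supplied the scattering coefficient is derived as
#' `mus = mus_prime / (1 - g1)` with `g1` the anisotropy of the supplied
#' phase function.
#'
#' Scattering deflections are sampled in closed form for a single-term HG
#' phase function, and through a numerical inverse-CDF table (built with
#' [build_inverse_cdf()] at `delta_c = 1e-4` unless one is passed directly)
#' for any other phase function.
#'
#' Photons whose path grows beyond `roulette_mfps` transport mean free paths
#' enter an unbiased survival roulette (probability 1/2 checkpoints at each
#' doubling of the path, surviving photons doubling their weight). This
#' leaves every expectation unchanged while keeping the heavy-tailed
#' non-absorbing half-space runs tractable; set it to `Inf` for analog
#' transport with unit weights.
#'
#' @param mua absorption coefficient, 1/mm (>= 0).
#' @param spf phase function: an `spf_params` object or an
#'   `inverse_cdf_table`.
#' @param mus scattering coefficient, 1/mm.
#' @param mus_prime reduced scattering coefficient, 1/mm (alternative to
#'   `mus`).
#' @param n_medium,n_outside refractive indices of the medium and its
#'   surroundings.
#' @param t_max time-of-flight cap, ns; photons still in flight at the cap
#'   are dropped and counted.
#' @param n_photons number of photons to launch.
#' @param seed integer seed for the deterministic transport RNG.
#' @param roulette_mfps path-stretching roulette onset, transport mean free
#'   paths.
#' @return An object of class `transport_config`.
#' @export
transport_config <- function(mua, spf, mus = NULL, mus_prime = NULL,
                             n_medium = 1.56, n_outside = 1.0, t_max = 300,
                             n_photons = 1e5, seed = 1, roulette_mfps = 100) {
  stopifnot(mua >= 0, t_max > 0, n_photons >= 1)
  if (inherits(spf, "inverse_cdf_table")) {
    tab <- spf
    g1 <- NA_real_
    mode <- 1L
    g <- 0
  } else if (inherits(spf, "sthg_params")) {
    tab <- NULL
    g1 <- spf$g
    mode <- 0L
    g <- spf$g
  } else if (inherits(spf, "spf_params")) {
    tab <- build_inverse_cdf(spf)
    g1 <- mean_cosine(spf)
    mode <- 1L
    g <- 0
  } else {
    stop("spf must be spf_params or an inverse_cdf_table")
  }
  if (is.null(mus)) {
    if (is.null(mus_prime)) stop("supply mus or mus_prime")
    if (is.na(g1)) {
      # table-only phase function: take g1 from the table's sample mean
      g1 <- mean(tab$cos_theta)
    }
    mus <- mus_prime / (1 - g1)
  }
  if (is.na(g1)) g1 <- mean(tab$cos_theta)
  if (is.null(mus_prime)) mus_prime <- mus * (1 - g1)
  stopifnot(mus >= 0)
  if (mus == 0 && mua == 0 && n_medium == n_outside) {
    # ballistic clear medium is allowed for slab geometries
  }
  structure(list(mua = mua, mus = mus, mus_prime = mus_prime, g1 = g1,
                 n_medium = n_medium, n_outside = n_outside, t_max = t_max,
                 n_photons = as.integer(n_photons), seed = seed,
                 spf_mode = mode, g = g, spf_table = tab,
                 roulette_mfps = roulette_mfps, spf = spf),
            class = "transport_config")
}

#' @export
print.transport_config <- function(x, ...) {
  cat(sprintf(
    "transport config: mua=%.3g mus=%.3g (mus'=%.3g, g1=%.3g) n=%g/%g t_max=%g ns, %g photons, seed %g\n",
    x$mua, x$mus, x$mus_prime, x$g1, x$n_medium, x$n_outside, x$t_max,
    x$n_photons, x$seed))
  invisible(x)
}

roulette_s0 <- function(config) {
  if (!is.finite(config$roulette_mfps) || config$mus_prime <= 0) return(-1)
  config$roulette_mfps / config$mus_prime
}

spf_table_vec <- function(config) {
  if (is.null(config$spf_table)) numeric(0) else config$spf_table$cos_theta
}

spf_table_dc <- function(config) {
  if (is.null(config$spf_table)) 1e-4 else config$spf_table$delta_c
}

totals_from <- function(res) {
  list(specular = res$specular, refl_top = res$refl_top,
       trans_bottom = res$trans_bottom, absorbed = res$absorbed,
       inflight = res$inflight, roulette_net = res$roulette_net,
       n_dropped = res$n_dropped, n_photons = res$n_photons)
}

#' Pencil-beam half-space transport
#'
#' Launches a pencil beam normally onto a semi-infinite homogeneous medium
#' and records every photon escaping back through the top surface: its exit
#' radius from the source axis, its time of flight (path length times
#' `n / c`) and its survival weight. This is the source run for the white
#' Monte Carlo record.
#'
#' @param config a [transport_config()].
#' @return data frame of exit records (`radius` mm, `time_of_flight` ns,
#'   `weight`), with the weight totals (`specular`, `refl_top`,
#'   `trans_bottom`, `absorbed`, `inflight`, `roulette_net`) and the
#'   configuration attached as attributes.
#' @export
propagate_pencil <- function(config) {
  stopifnot(inherits(config, "transport_config"))
  if (config$mus <= 0) stop("half-space transport requires mus > 0")
  res <- cpp_transport(config$mua, config$mus, config$n_medium,
                       config$n_outside, config$t_max, -1, config$n_photons,
                       config$seed, config$spf_mode, config$g,
                       spf_table_vec(config), spf_table_dc(config),
                       0L, 0, 0, 0, 0, 0, 0L, TRUE, roulette_s0(config))
  out <- data.frame(radius = res$radius, time_of_flight = res$time_of_flight,
                    weight = res$weight)
  attr(out, "totals") <- totals_from(res)
  attr(out, "config") <- config
  out
}

#' Finite-slab transport with reflectance/transmittance bookkeeping
#'
#' Simulates a beam incident on a slab of finite thickness with cyclic
#' lateral boundaries (when `lateral_period` is finite), and returns the
#' escaping-energy fractions. The weight ledger
#' `specular + R + T + A + inflight + roulette_net` equals 1 to numerical
#' round-off by construction.
#'
#' @param config a [transport_config()].
#' @param thickness slab thickness, mm.
#' @param beam_diameter uniform-disc source diameter, mm (0 for a pencil).
#' @param lateral_period cyclic lateral box size, mm (`NULL` for an
#'   unbounded slab).
#' @return list with `R` (diffuse reflectance), `T` (transmittance), `A`
#'   (absorbed fraction), `transflectance` (`1 - A`), `specular`,
#'   `inflight`, `roulette_net` and `ledger` (their sum plus `R + T + A`).
#' @export
simulate_slab <- function(config, thickness, beam_diameter = 1,
                          lateral_period = 2) {
  stopifnot(inherits(config, "transport_config"), thickness > 0)
  lp <- if (is.null(lateral_period)) 0 else lateral_period
  src <- if (beam_diameter > 0) 1L else 0L
  res <- cpp_transport(config$mua, config$mus, config$n_medium,
                       config$n_outside, config$t_max, thickness,
                       config$n_photons, config$seed, config$spf_mode,
                       config$g, spf_table_vec(config), spf_table_dc(config),
                       src, beam_diameter, 0, 0, lp, lp, 0L, FALSE,
                       roulette_s0(config))
  tot <- totals_from(res)
  ledger <- tot$specular + tot$refl_top + tot$trans_bottom + tot$absorbed +
    tot$inflight + tot$roulette_net
  list(R = tot$refl_top, T = tot$trans_bottom, A = tot$absorbed,
       transflectance = 1 - tot$absorbed, specular = tot$specular,
       inflight = tot$inflight, roulette_net = tot$roulette_net,
       ledger = ledger)
}

#' Spatial-frequency penetration depth
#'
#' Effective penetration depth of spatially modulated light,
#' `1 / sqrt(3 mua (mua + mus') + (2 pi fx)^2)`: the diffusion penetration
#' depth rolled off by the spatial frequency.
#'
#' @param mua,mus_prime optical properties, 1/mm.
#' @param fx spatial frequency, 1/mm.
#' @return penetration depth, mm.
#' @export
penetration_depth <- function(mua, mus_prime, fx) {
  1 / sqrt(3 * mua * (mua + mus_prime) + (2 * pi * fx)^2)
}

#' Direct simulation of sinusoidally patterned illumination
#'
#' Launch positions are drawn from the illumination pattern
#' `0.5 * (1 + cos(2 pi fx x + phase))` over a cyclic domain two pattern
#' periods long (1 mm wide, also cyclic), with the depth set to five
#' penetration depths; photons reaching the bottom face are counted as
#' transmitted. The surface exit profile along `x` is binned at 25 bins per
#' period and normalized to the mean illumination intensity, so that
#' three-phase demodulation of three such profiles returns the DC and AC
#' spatial-frequency reflectance directly.
#'
#' @param config a [transport_config()].
#' @param fx spatial frequency of the pattern, 1/mm (> 0).
#' @param phase pattern phase, radians.
#' @param bins_per_period surface binning resolution.
#' @return data frame with `x` (bin centers, mm) and `reflectance`
#'   (normalized exit profile); totals attached as an attribute.
#' @export
simulate_sfdi_pattern <- function(config, fx, phase = 0, bins_per_period = 25) {
  stopifnot(inherits(config, "transport_config"), fx > 0)
  lx <- 2 / fx
  depth <- 5 * penetration_depth(config$mua, config$mus_prime, fx)
  nb <- as.integer(2 * bins_per_period)
  res <- cpp_transport(config$mua, config$mus, config$n_medium,
                       config$n_outside, config$t_max, depth,
                       config$n_photons, config$seed, config$spf_mode,
                       config$g, spf_table_vec(config), spf_table_dc(config),
                       2L, 0, fx, phase, lx, 1, nb, FALSE,
                       roulette_s0(config))
  prof <- res$profile / res$n_photons * nb  # per mean illumination intensity
  x <- (seq_len(nb) - 0.5) * lx / nb
  out <- data.frame(x = x, reflectance = prof)
  attr(out, "totals") <- totals_from(res)
  attr(out, "fx") <- fx
  attr(out, "phase") <- phase
  out
}

#' DC/AC reflectance pair
#'
#' The unit of calibration and inversion: the demodulated DC and AC
#' reflectance at a stated spatial frequency.
#'
#' @param dc,ac DC and AC reflectance (scalars, or equal-shape arrays for
#'   per-pixel pairs).
#' @param fx spatial frequency, 1/mm.
#' @return An object of class `reflectance_pair`.
#' @export
reflectance_pair <- function(dc, ac, fx = NA_real_) {
  structure(list(dc = dc, ac = ac, fx = fx), class = "reflectance_pair")
}

#' @export
print.reflectance_pair <- function(x, ...) {
  cat(sprintf("reflectance pair at fx = %.3g /mm: DC = %.4g, AC = %.4g\n",
              x$fx, mean(x$dc), mean(x$ac)))
  invisible(x)
}

#' Three-phase demodulation
#'
#' Classic SFDI demodulation from three acquisitions with pattern phases 0,
#' 2 pi / 3 and 4 pi / 3:
#' `AC = (sqrt(2) / 3) * sqrt((P0 - P1)^2 + (P1 - P2)^2 + (P2 - P0)^2)`
#' evaluated pointwise and averaged over space, and `DC` the grand mean of
#' the three profiles. The identity is exact for any field of the form
#' `R0 + R1 cos(2 pi fx x + phi + phase_k)`.
#'
#' @param P0,P1,P2 reflectance profiles (vectors or matrices of identical
#'   shape) at the three phases.
#' @param fx spatial frequency carried into the result, 1/mm.
#' @return a [reflectance_pair()] of spatial means.
#' @export
demod_three_phase <- function(P0, P1, P2, fx = NA_real_) {
  p0 <- if (is.data.frame(P0)) P0$reflectance else P0
  p1 <- if (is.data.frame(P1)) P1$reflectance else P1
  p2 <- if (is.data.frame(P2)) P2$reflectance else P2
  if (length(p0) != length(p1) || length(p1) != length(p2)) {
    stop("profiles must have identical shape")
  }
  if (is.na(fx) && is.data.frame(P0)) fx <- attr(P0, "fx")
  ac <- (sqrt(2) / 3) * sqrt((p0 - p1)^2 + (p1 - p2)^2 + (p2 - p0)^2)
  reflectance_pair(dc = mean((p0 + p1 + p2) / 3), ac = mean(ac), fx = fx)
}

#' Run a three-phase patterned simulation and demodulate it
#'
#' Convenience wrapper running [simulate_sfdi_pattern()] at phases 0,
#' 2 pi / 3 and 4 pi / 3 (seeds offset deterministically) and demodulating
#' with [demod_three_phase()].
#'
#' @inheritParams simulate_sfdi_pattern
#' @return a [reflectance_pair()].
#' @export
simulate_sfdi_demodulated <- function(config, fx, bins_per_period = 25) {
  phases <- c(0, 2 * pi / 3, 4 * pi / 3)
  profs <- lapply(seq_along(phases), function(i) {
    cfg <- config
    cfg$seed <- config$seed + (i - 1) * 7919
    simulate_sfdi_pattern(cfg, fx, phases[i], bins_per_period)
  })
  demod_three_phase(profs[[1]], profs[[2]], profs[[3]], fx = fx)
}
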