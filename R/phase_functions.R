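#' Single-term Henyey-Greenstein phase function parameters
#'
#' The Henyey-Greenstein (HG) scattering phase function is the workhorse
#' single-parameter model of angular scattering in tissue optics. Its single
#' parameter `g` is the anisotropy, i.e. the mean cosine of the single-scatter
#' deflection angle.
#'
#' @param g anisotropy, dimensionless, strictly inside (-1, 1).
#' @return An object of class `c("sthg_params", "spf_params")`.
#' @seealso [tthg_params()], [eval_sthg()], [mean_cosine()]
#' @export
#' @examples
#' sthg_params(0.84)
sthg_params <- function(g) {
  stopifnot(is.numeric(g), length(g) == 1L, is.finite(g))
  if (abs(g) >= 1) {
    stop("anisotropy g must satisfy |g| < 1 (g = 1 is a singular density)")
  }
  structure(list(g = g), class = c("sthg_params", "spf_params"))
}

#' Two-term Henyey-Greenstein phase function parameters
#'
#' A weighted sum of a forward-scattering and a backward-scattering HG lobe:
#' `p(cos theta) = alpha * HG(gf) + (1 - alpha) * HG(gb)`. This captures
#' materials (such as zinc oxide scatterers in epoxy) whose strongly forward
#' lobe is accompanied by a small, nearly isotropic backscatter fraction that
#' a single HG term cannot represent.
#'
#' @param alpha forward-lobe fraction, in \[0, 1\].
#' @param gf forward anisotropy, in \[0, 1).
#' @param gb backward anisotropy, in (-1, 0\].
#' @return An object of class `c("tthg_params", "spf_params")`.
#' @seealso [mean_cosine()] for the overall anisotropy
#'   `g1 = alpha * gf + (1 - alpha) * gb`.
#' @export
#' @examples
#' zno <- tthg_params(alpha = 0.855, gf = 0.983, gb = 0)
#' mean_cosine(zno)
tthg_params <- function(alpha, gf, gb) {
  stopifnot(
    is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
    is.numeric(gf), length(gf) == 1L, is.finite(gf),
    is.numeric(gb), length(gb) == 1L, is.finite(gb)
  )
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (gf < 0 || gf >= 1) stop("gf must lie in [0, 1)")
  if (gb > 0 || gb <= -1) stop("gb must lie in (-1, 0]")
  structure(list(alpha = alpha, gf = gf, gb = gb),
            class = c("tthg_params", "spf_params"))
}

# scalar HG density per steradian; cos_theta may be a vector
hg_density <- function(g, cos_theta) {
  (1 / (4 * pi)) * (1 - g^2) / (1 + g^2 - 2 * g * cos_theta)^1.5
}

# closed-form HG CDF over cos theta, C(-1) = 0, C(1) = 1
hg_cdf <- function(g, x) {
  if (abs(g) < 1e-12) return((x + 1) / 2)
  (1 - g^2) / (2 * g) * (1 / sqrt(1 + g^2 - 2 * g * x) - 1 / (1 + g))
}

hg_family_cdf <- function(spf, x) {
  if (inherits(spf, "tthg_params")) {
    spf$alpha * hg_cdf(spf$gf, x) + (1 - spf$alpha) * hg_cdf(spf$gb, x)
  } else {
    hg_cdf(spf$g, x)
  }
}

#' Evaluate a single-term Henyey-Greenstein density
#'
#' Returns the probability density per steradian,
#' `p = (1 / 4 pi) (1 - g^2) / (1 + g^2 - 2 g cos theta)^(3/2)`.
#' Integrating `2 pi p` over `cos theta` in \[-1, 1\] gives 1.
#'
#' @param params an [sthg_params()] object (or a bare anisotropy value).
#' @param cos_theta cosine(s) of the scattering angle, each in \[-1, 1\].
#' @return density per steradian, same length as `cos_theta`.
#' @export
#' @examples
#' eval_sthg(sthg_params(0), 0.3)  # isotropic: 1 / (4 * pi)
eval_sthg <- function(params, cos_theta) {
  if (is.numeric(params)) params <- sthg_params(params)
  stopifnot(inherits(params, "sthg_params"))
  if (any(!is.finite(cos_theta)) || any(abs(cos_theta) > 1)) {
    stop("cos_theta must lie in [-1, 1]")
  }
  hg_density(params$g, cos_theta)
}

#' Evaluate a two-term Henyey-Greenstein density
#'
#' @param params a [tthg_params()] object.
#' @inheritParams eval_sthg
#' @return density per steradian, same length as `cos_theta`.
#' @export
eval_tthg <- function(params, cos_theta) {
  stopifnot(inherits(params, "tthg_params"))
  if (any(!is.finite(cos_theta)) || any(abs(cos_theta) > 1)) {
    stop("cos_theta must lie in [-1, 1]")
  }
  params$alpha * hg_density(params$gf, cos_theta) +
    (1 - params$alpha) * hg_density(params$gb, cos_theta)
}

#' Scattering phase function density
#'
#' Generic evaluator dispatching on the parameter class; see [eval_sthg()]
#' and [eval_tthg()].
#'
#' @inheritParams eval_sthg
#' @export
spf_density <- function(params, cos_theta) UseMethod("spf_density")

#' @export
spf_density.sthg_params <- function(params, cos_theta) eval_sthg(params, cos_theta)

#' @export
spf_density.tthg_params <- function(params, cos_theta) eval_tthg(params, cos_theta)

#' Overall anisotropy (mean scattering cosine)
#'
#' For a single HG term this is `g` itself; for a two-term HG it is the
#' closed form `g1 = alpha * gf + (1 - alpha) * gb`, which equals the first
#' moment of the density.
#'
#' @param params an `spf_params` object.
#' @return the anisotropy `g1`, dimensionless in (-1, 1).
#' @export
#' @examples
#' mean_cosine(tthg_params(0.855, 0.983, 0))  # 0.8405
mean_cosine <- function(params) UseMethod("mean_cosine")

#' @export
mean_cosine.sthg_params <- function(params) params$g

#' @export
mean_cosine.tthg_params <- function(params) {
  params$alpha * params$gf + (1 - params$alpha) * params$gb
}

#' @export
print.spf_params <- function(x, ...) {
  if (inherits(x, "sthg_params")) {
    cat(sprintf("stHG phase function: g = %.4g\n", x$g))
  } else {
    cat(sprintf("ttHG phase function: alpha = %.4g, gf = %.4g, gb = %.4g (g1 = %.4g)\n",
                x$alpha, x$gf, x$gb, mean_cosine(x)))
  }
  invisible(x)
}

#' Tabulate the inverse CDF of a scattering phase function
#'
#' Builds the numerical inverse cumulative distribution of `cos theta` for an
#' arbitrary phase function, in the form consumed by Monte Carlo transport
#' codes that accept user-defined scattering: the CDF is evaluated on a
#' fine regular cosine grid (step `cos_step`, running from
#' `cos theta = -1` upward) — exactly, via the closed-form lobe CDFs, for
#' Henyey-Greenstein-family parameter objects, or by trapezoid quadrature
#' for an arbitrary density function — then inverted by piecewise linear
#' interpolation onto the regular CDF sampling
#' `delta_c, 2 delta_c, ..., 1 - delta_c`.
#'
#' Densities that do not integrate to 1 over the sphere are renormalized;
#' a non-normalizable (non-finite or non-positive integral) density is an
#' error.
#'
#' @param spf an `spf_params` object, or a function of `cos theta` returning
#'   a density per steradian.
#' @param delta_c CDF sampling step, in (0, 0.1\].
#' @param cos_step cosine quadrature step used to accumulate the CDF.
#' @return An object of class `inverse_cdf_table` with fields `grid` (the CDF
#'   values), `cos_theta` (non-decreasing cosines) and `delta_c`.
#' @export
#' @examples
#' tab <- build_inverse_cdf(sthg_params(0.9), delta_c = 1e-3)
#' mean(sample_cos_theta(tab, runif(1e4)))  # close to 0.9
build_inverse_cdf <- function(spf, delta_c = 1e-4, cos_step = 1e-4) {
  stopifnot(delta_c > 0, delta_c <= 0.1, cos_step > 0)
  ct <- seq(-1, 1, by = cos_step)
  if (ct[length(ct)] < 1) ct <- c(ct, 1)
  if (inherits(spf, "spf_params")) {
    # HG-family CDFs have a closed form; trapezoid accumulation would
    # misweight the near-singular forward peak (the last cosine cell of a
    # gf = 0.983 lobe holds over 20% of the probability), so the exact
    # cell masses are used on the same grid
    cdf <- hg_family_cdf(spf, ct)
  } else if (is.function(spf)) {
    dens <- 2 * pi * spf(ct)  # density over cos theta
    if (any(!is.finite(dens)) || any(dens < 0)) {
      stop("phase function density must be finite and non-negative")
    }
    dct <- diff(ct)
    cdf <- c(0, cumsum(0.5 * (dens[-1] + dens[-length(dens)]) * dct))
  } else {
    stop("spf must be spf_params or a density function of cos theta")
  }
  total <- cdf[length(cdf)]
  if (!is.finite(total) || total <= 0) {
    stop("phase function density is not normalizable")
  }
  cdf <- cdf / total
  grid <- seq(delta_c, 1 - delta_c, by = delta_c)
  # cdf is non-decreasing; make strictly increasing for interpolation by
  # dropping duplicated values (flat spots carry zero probability)
  keep <- c(TRUE, diff(cdf) > 0)
  cos_tab <- approx(cdf[keep], ct[keep], xout = grid, rule = 2)$y
  cos_tab <- cummax(pmin(pmax(cos_tab, -1), 1))
  structure(list(grid = grid, cos_theta = cos_tab, delta_c = delta_c),
            class = "inverse_cdf_table")
}

#' Sample scattering cosines through an inverse-CDF table
#'
#' Maps uniform variates through the tabulated inverse CDF by linear
#' interpolation; values below the first or above the last tabulated CDF
#' value clamp to the table ends.
#'
#' @param table an [build_inverse_cdf()] result.
#' @param uniforms numeric vector of values in \[0, 1).
#' @return cosines in \[-1, 1\], monotone in `uniforms`.
#' @export
sample_cos_theta <- function(table, uniforms) {
  stopifnot(inherits(table, "inverse_cdf_table"))
  if (any(!is.finite(uniforms)) || any(uniforms < 0) || any(uniforms >= 1)) {
    stop("uniforms must lie in [0, 1)")
  }
  # fractional 1-based index into the regular CDF grid, matching the
  # transport kernel's interpolation exactly
  k <- uniforms / table$delta_c
  n <- length(table$cos_theta)
  k <- pmin(pmax(k, 1), n)
  k0 <- pmin(floor(k), n - 1)
  f <- k - k0
  table$cos_theta[k0] * (1 - f) + table$cos_theta[k0 + 1] * f
}

#' @export
print.inverse_cdf_table <- function(x, ...) {
  cat(sprintf("inverse CDF table: %d entries, delta_c = %g, cos range [%.4g, %.4g]\n",
              length(x$grid), x$delta_c, x$cos_theta[1],
              x$cos_theta[length(x$cos_theta)]))
  invisible(x)
}

#' Write / read phase-function parameters as flat key-value text
#'
#' @param params an `spf_params` object.
#' @param path file path.
#' @return `read_spf_params` returns the reconstructed `spf_params` object.
#' @export
write_spf_params <- function(params, path) {
  stopifnot(inherits(params, "spf_params"))
  lines <- if (inherits(params, "tthg_params")) {
    c(sprintf("alpha: %.17g", params$alpha),
      sprintf("gf: %.17g", params$gf),
      sprintf("gb: %.17g", params$gb))
  } else {
    sprintf("g: %.17g", params$g)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_spf_params
#' @export
read_spf_params <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ":\\s*")
  vals <- vapply(kv, function(x) as.numeric(x[2]), numeric(1))
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  if (all(c("alpha", "gf", "gb") %in% names(vals))) {
    tthg_params(vals[["alpha"]], vals[["gf"]], vals[["gb"]])
  } else if ("g" %in% names(vals)) {
    sthg_params(vals[["g"]])
  } else {
    stop("unrecognized phase-function parameter file")
  }
}

#' Write / read an inverse-CDF table as a two-column text table
#'
#' @param table an `inverse_cdf_table`.
#' @param path file path.
#' @export
write_inverse_cdf <- function(table, path) {
  stopifnot(inherits(table, "inverse_cdf_table"))
  df <- data.frame(cdf = table$grid, cos_theta = table$cos_theta)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_inverse_cdf
#' @export
read_inverse_cdf <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  dc <- df$cdf[1]
  structure(list(grid = df$cdf, cos_theta = df$cos_theta, delta_c = dc),
            class = "inverse_cdf_table")
}
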