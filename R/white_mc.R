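log_centers <- function(lo, hi, n) exp(seq(log(lo), log(hi), length.out = n))

# edges at geometric midpoints of log-spaced centers, extended geometrically
# at both ends
log_edges <- function(centers) {
  inner <- sqrt(centers[-1] * centers[-length(centers)])
  c(centers[1]^2 / inner[1], inner,
    centers[length(centers)]^2 / inner[length(inner)])
}

#' Bin pencil-beam exit records into a white Monte Carlo record
#'
#' Builds the bivariate histogram of escaped photon weight over exit radius
#' and time of flight, on logarithmically spaced bins. Log binning resolves
#' the sub-diffuse structure (tens of micrometres, hundreds of
#' femtoseconds) and the diffuse tail (centimetres, hundreds of
#' nanoseconds) in a single compact matrix; the same dynamic range on
#' linear grids would need more than a million times as many cells.
#' Out-of-range weight accumulates in guard counters that are excluded from
#' all transforms, so binned plus guard weight equals the total escaped
#' weight.
#'
#' @param records exit records from [propagate_pencil()].
#' @param n_bins number of bins per axis.
#' @param r_range radial bin-center range, mm.
#' @param t_range time-of-flight bin-center range, ns.
#' @param spf_label optional label naming the phase function used.
#' @return An object of class `wmc_record`: `counts` (radius x time weight
#'   histogram), `r_centers`, `t_centers`, `r_edges`, `t_edges`,
#'   `base_mus_prime`, `base_mua`, `n_medium`, `n_launched`, `guard`
#'   (out-of-range weight) and `totals`.
#' @export
bin_records <- function(records, n_bins = 750, r_range = c(1e-5, 150),
                        t_range = c(1e-7, 300), spf_label = NULL) {
  config <- attr(records, "config")
  totals <- attr(records, "totals")
  if (is.null(config)) stop("records must come from propagate_pencil()")
  r_centers <- log_centers(r_range[1], r_range[2], n_bins)
  t_centers <- log_centers(t_range[1], t_range[2], n_bins)
  r_edges <- log_edges(r_centers)
  t_edges <- log_edges(t_centers)
  ir <- findInterval(records$radius, r_edges)
  it <- findInterval(records$time_of_flight, t_edges)
  ok <- ir >= 1 & ir <= n_bins & it >= 1 & it <= n_bins
  counts <- matrix(0, n_bins, n_bins)
  if (any(ok)) {
    idx <- ir[ok] + (it[ok] - 1) * n_bins
    agg <- rowsum(records$weight[ok], idx)
    counts[as.integer(rownames(agg))] <- agg
  }
  structure(list(counts = counts, r_centers = r_centers,
                 t_centers = t_centers, r_edges = r_edges, t_edges = t_edges,
                 base_mus_prime = config$mus_prime, base_mua = config$mua,
                 n_medium = config$n_medium, n_launched = totals$n_photons,
                 guard = sum(records$weight[!ok]), totals = totals,
                 spf_label = spf_label %||%
                   class(config$spf)[1]),
            class = "wmc_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.wmc_record <- function(x, ...) {
  cat(sprintf(
    "white MC record [%s]: %dx%d log bins, base mus'=%g mua=%g n=%g, %g photons (guard %.3g)\n",
    x$spf_label, length(x$r_centers), length(x$t_centers), x$base_mus_prime,
    x$base_mua, x$n_medium, x$n_launched, x$guard))
  invisible(x)
}

#' Build a white Monte Carlo record in one call
#'
#' Runs the base pencil-beam simulation (essentially non-absorbing medium,
#' reduced scattering fixed at `base_mus_prime`) and bins the exit records.
#'
#' @param spf phase function (`spf_params` or `inverse_cdf_table`).
#' @param n_photons photons to launch.
#' @param seed transport RNG seed.
#' @param base_mus_prime base reduced scattering coefficient, 1/mm.
#' @param base_mua base absorption coefficient, 1/mm (effectively zero).
#' @param n_medium,t_max medium index and time cap (ns).
#' @param spf_label label stored on the record.
#' @param ... further arguments to [transport_config()].
#' @return a `wmc_record`.
#' @export
build_wmc <- function(spf, n_photons = 1e6, seed = 1, base_mus_prime = 10,
                      base_mua = 1e-8, n_medium = 1.56, t_max = 300,
                      spf_label = NULL, ...) {
  cfg <- transport_config(mua = base_mua, spf = spf,
                          mus_prime = base_mus_prime, n_medium = n_medium,
                          t_max = t_max, n_photons = n_photons, seed = seed,
                          ...)
  bin_records(propagate_pencil(cfg), spf_label = spf_label)
}

#' Merge white Monte Carlo records built from independent seeds
#'
#' @param records list of `wmc_record`s with identical binning and base
#'   properties.
#' @return a combined `wmc_record`.
#' @export
combine_wmc <- function(records) {
  stopifnot(length(records) >= 1)
  out <- records[[1]]
  for (r in records[-1]) {
    stopifnot(identical(dim(r$counts), dim(out$counts)),
              isTRUE(all.equal(r$base_mus_prime, out$base_mus_prime)))
    out$counts <- out$counts + r$counts
    out$n_launched <- out$n_launched + r$n_launched
    out$guard <- out$guard + r$guard
  }
  out
}

#' Rescale a white Monte Carlo record to arbitrary optical properties
#'
#' The white Monte Carlo trick: a change of reduced scattering by a factor
#' `beta = mus_prime / base_mus_prime` rescales all exit radii and times by
#' `1 / beta`; absorption is then applied through the Beer-Lambert law,
#' attenuating each cell by `exp(-mua * (c / n) * t_scaled)`. Summing over
#' time and dividing by the annular areas and launched photon count yields
#' the spatially resolved diffuse reflectance per unit area.
#'
#' @param wmc a `wmc_record`.
#' @param mua absorption coefficient, 1/mm (>= 0).
#' @param mus_prime reduced scattering coefficient, 1/mm (> 0).
#' @return An object of class `radial_reflectance`: `rho` (scaled radii,
#'   mm), `rd_per_area` (1/mm^2), `area` (scaled annulus areas, mm^2) and
#'   `total` (plane-integrated reflectance).
#' @export
apply_props <- function(wmc, mua, mus_prime) {
  stopifnot(inherits(wmc, "wmc_record"), mua >= 0, mus_prime > 0)
  beta <- mus_prime / wmc$base_mus_prime
  rho <- wmc$r_centers / beta
  t_scaled <- wmc$t_centers / beta
  att <- exp(-mua * (C_MM_NS / wmc$n_medium) * t_scaled)
  wsum <- as.vector(wmc$counts %*% att) / wmc$n_launched
  area <- pi * diff(wmc$r_edges^2) / beta^2
  structure(list(rho = rho, rd_per_area = wsum / area, area = area,
                 total = sum(wsum)),
            class = "radial_reflectance")
}

#' Order-zero Hankel transform of a radial reflectance profile
#'
#' Converts spatially resolved reflectance into spatial-frequency-domain
#' reflectance: `Rd(fx) = sum_i rd(rho_i) J0(2 pi fx rho_i) A_i` over the
#' log-spaced annuli (midpoint quadrature). At `fx = 0` this is the
#' plane-integrated total diffuse reflectance.
#'
#' @param profile a [apply_props()] result.
#' @param fx spatial frequency (may be a vector), 1/mm, >= 0.
#' @return `Rd(fx)`, dimensionless, same length as `fx`.
#' @export
hankel_rd <- function(profile, fx) {
  stopifnot(inherits(profile, "radial_reflectance"), all(fx >= 0))
  wa <- profile$rd_per_area * profile$area
  vapply(fx, function(f) sum(wa * besselJ(2 * pi * f * profile$rho, 0)),
         numeric(1))
}

#' Predict a DC/AC reflectance pair from a white Monte Carlo record
#'
#' @param wmc a `wmc_record`.
#' @param mua,mus_prime optical properties, 1/mm.
#' @param fx AC spatial frequency, 1/mm.
#' @return a [reflectance_pair()] with `dc = Rd(0)` and `ac = Rd(fx)`.
#' @export
predict_pair <- function(wmc, mua, mus_prime, fx) {
  prof <- apply_props(wmc, mua, mus_prime)
  rd <- hankel_rd(prof, c(0, fx))
  reflectance_pair(dc = rd[1], ac = rd[2], fx = fx)
}

#' Spatial-frequency reflectance at several frequencies
#'
#' @inheritParams predict_pair
#' @param fx vector of spatial frequencies, 1/mm.
#' @return `Rd(fx)` vector.
#' @export
predict_rd <- function(wmc, mua, mus_prime, fx) {
  hankel_rd(apply_props(wmc, mua, mus_prime), fx)
}

# Vectorized forward model over a property grid: for each mus' column the
# time dimension is collapsed against all mua attenuation vectors at once,
# then each requested frequency is a single inner product. Annular areas
# cancel between the per-area density and the quadrature weights.
forward_rd_grid <- function(wmc, mua_grid, mus_grid, fx) {
  nr <- length(wmc$r_centers)
  out <- array(NA_real_,
               c(length(mua_grid), length(mus_grid), length(fx)))
  cn <- C_MM_NS / wmc$n_medium
  for (j in seq_along(mus_grid)) {
    beta <- mus_grid[j] / wmc$base_mus_prime
    t_s <- wmc$t_centers / beta
    att <- exp(-outer(t_s * cn, mua_grid))      # t x mua
    P <- wmc$counts %*% att / wmc$n_launched    # r x mua
    rho <- wmc$r_centers / beta
    for (k in seq_along(fx)) {
      j0 <- if (fx[k] == 0) rep(1, nr) else besselJ(2 * pi * fx[k] * rho, 0)
      out[, j, k] <- as.vector(crossprod(j0, P))
    }
  }
  out
}

#' Build an inversion lookup table from a white Monte Carlo record
#'
#' Evaluates the forward model (DC and AC reflectance at `fx`) on a dense
#' logarithmic grid of absorption and reduced scattering, then inverts the
#' forward surface onto fixed log-spaced reflectance grids by barycentric
#' interpolation within each forward-grid quad (split into two triangles).
#' Reflectance nodes not covered by the forward surface, or covered by
#' physically ambiguous folds of it (candidate properties spreading more
#' than `ambiguity_tol` in log space), are flagged undetermined rather than
#' fabricated.
#'
#' @param wmc a `wmc_record`.
#' @param fx AC spatial frequency of the table, 1/mm.
#' @param mua_range,n_mua absorption sampling (log-spaced), 1/mm.
#' @param mus_range,n_mus reduced-scattering sampling (log-spaced), 1/mm.
#' @param dc_range,n_dc DC reflectance axis (log-spaced).
#' @param ac_range,n_ac AC reflectance axis (log-spaced).
#' @param ambiguity_tol log-space spread beyond which a node is flagged.
#' @return An object of class `inversion_lut` with `dc_grid`, `ac_grid`,
#'   `mua_surface`, `mus_prime_surface` (matrices, NA where undetermined),
#'   `flagged` (logical matrix, TRUE where a fold was detected), `fx` and
#'   `spf_label`.
#' @export
build_lut <- function(wmc, fx, mua_range = c(1e-4, 10), n_mua = 120,
                      mus_range = c(0.1, 10), n_mus = 120,
                      dc_range = c(0.001, 0.9), n_dc = 190,
                      ac_range = c(0.001, 0.7), n_ac = 170,
                      ambiguity_tol = log(1.10)) {
  stopifnot(inherits(wmc, "wmc_record"), fx > 0)
  mua_grid <- log_centers(mua_range[1], mua_range[2], n_mua)
  mus_grid <- log_centers(mus_range[1], mus_range[2], n_mus)
  fwd <- forward_rd_grid(wmc, mua_grid, mus_grid, c(0, fx))
  fwd[fwd <= 0] <- NA_real_  # Monte Carlo noise at vanishing reflectance
  ldc <- log(fwd[, , 1])
  lac <- log(fwd[, , 2])
  lmua <- matrix(log(mua_grid), n_mua, n_mus)
  lmus <- matrix(log(mus_grid), n_mua, n_mus, byrow = TRUE)

  dc_grid <- log_centers(dc_range[1], dc_range[2], n_dc)
  ac_grid <- log_centers(ac_range[1], ac_range[2], n_ac)
  lx <- log(dc_grid)
  ly <- log(ac_grid)

  sum_a <- sum_s <- cnt <- matrix(0, n_dc, n_ac)
  min_a <- min_s <- matrix(Inf, n_dc, n_ac)
  max_a <- max_s <- matrix(-Inf, n_dc, n_ac)

  fill_tri <- function(x, y, va, vs) {
    # barycentric assignment of all grid nodes inside triangle (x, y)
    i1 <- findInterval(min(x), lx) + 1L
    i2 <- findInterval(max(x), lx)
    j1 <- findInterval(min(y), ly) + 1L
    j2 <- findInterval(max(y), ly)
    if (i1 > i2 || j1 > j2) return()
    det <- (y[2] - y[3]) * (x[1] - x[3]) + (x[3] - x[2]) * (y[1] - y[3])
    if (!is.finite(det) || abs(det) < 1e-14) return()
    xi <- lx[i1:i2]
    yj <- ly[j1:j2]
    px <- rep(xi, times = length(yj))
    py <- rep(yj, each = length(xi))
    l1 <- ((y[2] - y[3]) * (px - x[3]) + (x[3] - x[2]) * (py - y[3])) / det
    l2 <- ((y[3] - y[1]) * (px - x[3]) + (x[1] - x[3]) * (py - y[3])) / det
    l3 <- 1 - l1 - l2
    eps <- -1e-9
    inside <- l1 >= eps & l2 >= eps & l3 >= eps
    if (!any(inside)) return()
    ii <- rep(i1:i2, times = length(yj))[inside]
    jj <- rep(j1:j2, each = length(xi))[inside]
    a <- l1[inside] * va[1] + l2[inside] * va[2] + l3[inside] * va[3]
    s <- l1[inside] * vs[1] + l2[inside] * vs[2] + l3[inside] * vs[3]
    idx <- cbind(ii, jj)
    sum_a[idx] <<- sum_a[idx] + a
    sum_s[idx] <<- sum_s[idx] + s
    cnt[idx] <<- cnt[idx] + 1
    min_a[idx] <<- pmin(min_a[idx], a)
    max_a[idx] <<- pmax(max_a[idx], a)
    min_s[idx] <<- pmin(min_s[idx], s)
    max_s[idx] <<- pmax(max_s[idx], s)
  }

  for (i in seq_len(n_mua - 1)) {
    for (j in seq_len(n_mus - 1)) {
      cx <- c(ldc[i, j], ldc[i + 1, j], ldc[i + 1, j + 1], ldc[i, j + 1])
      cy <- c(lac[i, j], lac[i + 1, j], lac[i + 1, j + 1], lac[i, j + 1])
      ca <- c(lmua[i, j], lmua[i + 1, j], lmua[i + 1, j + 1], lmua[i, j + 1])
      cs <- c(lmus[i, j], lmus[i + 1, j], lmus[i + 1, j + 1], lmus[i, j + 1])
      if (any(!is.finite(cx)) || any(!is.finite(cy))) next
      fill_tri(cx[c(1, 2, 3)], cy[c(1, 2, 3)], ca[c(1, 2, 3)], cs[c(1, 2, 3)])
      fill_tri(cx[c(1, 3, 4)], cy[c(1, 3, 4)], ca[c(1, 3, 4)], cs[c(1, 3, 4)])
    }
  }

  covered <- cnt > 0
  spread <- pmax(max_a - min_a, max_s - min_s)
  flagged <- covered & spread > ambiguity_tol
  mua_surface <- exp(sum_a / cnt)
  mus_surface <- exp(sum_s / cnt)
  mua_surface[!covered | flagged] <- NA_real_
  mus_surface[!covered | flagged] <- NA_real_
  # unphysical half-plane: AC cannot exceed DC for a scattering half-space
  unphys <- outer(dc_grid, ac_grid, function(d, a) a >= d)
  mua_surface[unphys] <- NA_real_
  mus_surface[unphys] <- NA_real_
  flagged <- flagged | unphys

  structure(list(dc_grid = dc_grid, ac_grid = ac_grid,
                 mua_surface = mua_surface, mus_prime_surface = mus_surface,
                 flagged = flagged, fx = fx, spf_label = wmc$spf_label),
            class = "inversion_lut")
}

#' @export
print.inversion_lut <- function(x, ...) {
  cat(sprintf(
    "inversion LUT [%s] at fx = %.3g /mm: %d x %d reflectance nodes (%.1f%% determined)\n",
    x$spf_label, length(x$dc_grid), length(x$ac_grid),
    100 * mean(is.finite(x$mua_surface))))
  invisible(x)
}

#' Export / import an inversion LUT as CSV grids
#'
#' Writes a long-format CSV (`dc`, `ac`, `mua`, `mus_prime`, `flagged`) with
#' `# key: value` metadata lines.
#'
#' @param lut an `inversion_lut`.
#' @param path file path.
#' @export
write_lut <- function(lut, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fx: %.17g", lut$fx), con)
  writeLines(sprintf("# spf_label: %s", lut$spf_label), con)
  df <- data.frame(dc = rep(lut$dc_grid, times = length(lut$ac_grid)),
                   ac = rep(lut$ac_grid, each = length(lut$dc_grid)),
                   mua = as.vector(lut$mua_surface),
                   mus_prime = as.vector(lut$mus_prime_surface),
                   flagged = as.vector(lut$flagged))
  write.table(format(df, digits = 10), con, sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- sub("^#\\s*(\\w+):\\s*", "", hdr)
  names(meta) <- sub("^#\\s*(\\w+):.*", "\\1", hdr)
  df <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                   sep = ",", strip.white = TRUE)
  dc_grid <- sort(unique(df$dc))
  ac_grid <- sort(unique(df$ac))
  shape <- c(length(dc_grid), length(ac_grid))
  structure(list(dc_grid = dc_grid, ac_grid = ac_grid,
                 mua_surface = matrix(df$mua, shape[1], shape[2]),
                 mus_prime_surface = matrix(df$mus_prime, shape[1], shape[2]),
                 flagged = matrix(as.logical(df$flagged), shape[1], shape[2]),
                 fx = as.numeric(meta[["fx"]]), spf_label = meta[["spf_label"]]),
            class = "inversion_lut")
}

#' Serialize a white Monte Carlo record as plain text
#'
#' Stores the non-empty histogram cells in long format (`ir`, `it`,
#' `weight`) under a `# key: value` metadata header carrying the binning and
#' base properties, so records can be rebuilt without rerunning transport.
#'
#' @param wmc a `wmc_record`.
#' @param path file path.
#' @export
write_wmc <- function(wmc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nb <- length(wmc$r_centers)
  meta <- c(n_bins = nb, r_lo = wmc$r_centers[1], r_hi = wmc$r_centers[nb],
            t_lo = wmc$t_centers[1], t_hi = wmc$t_centers[nb],
            base_mus_prime = wmc$base_mus_prime, base_mua = wmc$base_mua,
            n_medium = wmc$n_medium, n_launched = wmc$n_launched,
            guard = wmc$guard)
  writeLines(sprintf("# %s: %.17g", names(meta), meta), con)
  writeLines(sprintf("# spf_label: %s", wmc$spf_label), con)
  nz <- which(wmc$counts != 0, arr.ind = TRUE)
  writeLines("ir\tit\tweight", con)
  writeLines(sprintf("%d\t%d\t%.17g", nz[, 1], nz[, 2], wmc$counts[nz]), con)
  invisible(path)
}

#' @rdname write_wmc
#' @export
read_wmc <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  vals <- sub("^#\\s*[^:]+:\\s*", "", hdr)
  keys <- sub("^#\\s*([^:]+):.*", "\\1", hdr)
  meta <- as.list(vals)
  names(meta) <- keys
  num <- function(k) as.numeric(meta[[k]])
  nb <- as.integer(num("n_bins"))
  df <- read.table(text = lines[!grepl("^#", lines)], header = TRUE, sep = "\t")
  counts <- matrix(0, nb, nb)
  counts[cbind(df$ir, df$it)] <- df$weight
  r_centers <- log_centers(num("r_lo"), num("r_hi"), nb)
  t_centers <- log_centers(num("t_lo"), num("t_hi"), nb)
  structure(list(counts = counts, r_centers = r_centers,
                 t_centers = t_centers, r_edges = log_edges(r_centers),
                 t_edges = log_edges(t_centers),
                 base_mus_prime = num("base_mus_prime"),
                 base_mua = num("base_mua"), n_medium = num("n_medium"),
                 n_launched = num("n_launched"), guard = num("guard"),
                 totals = NULL, spf_label = meta[["spf_label"]]),
            class = "wmc_record")
}
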