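# Target phantom grid: 16 phantoms x 4 wavelength channels, with absorption
# and reduced scattering targets (1/mm) spanning diffuse to strongly
# sub-diffuse reduced albedos. Printed reduced albedos retained for
# cross-checking the recomputation.
phantom_grid_data <- function() {
  ch <- c("850nm", "625nm", "545nm", "395nm")
  mua <- list(
    `850nm` = rep(c(0.015, 0.05, 0.075, 0.1), each = 4),
    `625nm` = rep(c(0.03, 0.1, 0.15, 0.3), each = 4),
    `545nm` = rep(c(0.1, 0.3, 1.0, 2.5), each = 4),
    `395nm` = rep(c(0.5, 1.0, 2.5, 5.0), each = 4)
  )
  mus <- list(
    `850nm` = rep(c(0.35, 1.0, 1.5, 2.0), times = 4),
    `625nm` = rep(c(0.55, 1.4, 2.2, 3.0), times = 4),
    `545nm` = rep(c(0.8, 1.6, 2.6, 3.5), times = 4),
    `395nm` = rep(c(1.25, 2.5, 4.0, 5.5), times = 4)
  )
  albedo_printed <- list(
    `850nm` = c(0.96, 0.99, 0.99, 0.99, 0.88, 0.95, 0.97, 0.98,
                0.82, 0.93, 0.95, 0.96, 0.78, 0.91, 0.94, 0.95),
    `625nm` = c(0.95, 0.98, 0.99, 0.99, 0.85, 0.93, 0.96, 0.97,
                0.79, 0.90, 0.94, 0.95, 0.65, 0.82, 0.88, 0.91),
    `545nm` = c(0.89, 0.94, 0.96, 0.97, 0.73, 0.84, 0.90, 0.92,
                0.44, 0.62, 0.72, 0.78, 0.24, 0.39, 0.51, 0.58),
    `395nm` = c(0.71, 0.83, 0.89, 0.92, 0.56, 0.71, 0.80, 0.85,
                0.33, 0.50, 0.62, 0.69, 0.20, 0.33, 0.44, 0.52)
  )
  do.call(rbind, lapply(ch, function(w) {
    data.frame(phantom = 1:16, channel = w, mua = mua[[w]],
               mus_prime = mus[[w]], albedo_printed = albedo_printed[[w]])
  }))
}

#' Target phantom optical-property table
#'
#' The 16-phantom design grid (four absorption levels crossed with four
#' reduced-scattering levels) at the four imaging wavelength channels, with
#' the reduced albedo `alpha' = mus' / (mua + mus')` recomputed from the
#' target coefficients.
#'
#' @return data frame with columns `phantom` (1-16), `channel`, `mua`,
#'   `mus_prime` (1/mm), `reduced_albedo` (recomputed) and
#'   `albedo_printed` (two-decimal design-table value, for cross-checks).
#' @export
#' @examples
#' tab <- make_phantom_table()
#' subset(tab, phantom == 13 & channel == "395nm")
make_phantom_table <- function() {
  tab <- phantom_grid_data()
  tab$reduced_albedo <- tab$mus_prime / (tab$mua + tab$mus_prime)
  tab[c("phantom", "channel", "mua", "mus_prime", "reduced_albedo",
        "albedo_printed")]
}

#' Properties of the reference phantom
#'
#' The reference used for calibration has the optical properties of
#' phantom 11 (third absorption group, third scattering group) at the
#' requested channel.
#'
#' @param channel wavelength channel label.
#' @return one-row data frame with `mua` and `mus_prime`.
#' @export
reference_phantom_spec <- function(channel = "545nm") {
  tab <- make_phantom_table()
  row <- tab[tab$phantom == 11 & tab$channel == channel, ]
  if (nrow(row) != 1) stop("unknown channel: ", channel)
  row[c("mua", "mus_prime")]
}

#' Scene configuration for synthetic SFDI frames
#'
#' Describes how a synthetic patterned acquisition is rendered: pattern
#' frequency and phase, image geometry, a smooth multiplicative
#' illumination-gain field, exposure scaling and shot-like noise.
#'
#' @param fx pattern spatial frequency, 1/mm.
#' @param phase pattern phase, radians.
#' @param nx,ny image size in pixels.
#' @param pixel_pitch mm per pixel; the default maps a 62 mm field of view
#'   onto a 1440-pixel sensor row.
#' @param gain_amplitude fractional amplitude of the radially symmetric
#'   illumination nonuniformity.
#' @param noise_scale shot-like noise scale: the per-pixel standard
#'   deviation is `noise_scale * sqrt(intensity)`.
#' @param exposure exposure scaling, arbitrary units.
#' @param spf_label label of the phase function rendering the scene
#'   (`"tthg"` for unpolarized acquisitions, `"sthg"` variants for
#'   cross-polarized ones).
#' @param seed RNG seed for the noise.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(fx, phase = 0, nx = 128, ny = 96,
                         pixel_pitch = 62 / 1440, gain_amplitude = 0.15,
                         noise_scale = 0.005, exposure = 1,
                         spf_label = "tthg", seed = 1) {
  stopifnot(fx >= 0, exposure > 0, nx >= 8, ny >= 8)
  structure(list(fx = fx, phase = phase, nx = nx, ny = ny,
                 pixel_pitch = pixel_pitch, gain_amplitude = gain_amplitude,
                 noise_scale = noise_scale, exposure = exposure,
                 spf_label = spf_label, seed = seed),
            class = "scene_config")
}

scene_gain_field <- function(config) {
  x <- (seq_len(config$nx) - (config$nx + 1) / 2) / (config$nx / 2)
  y <- (seq_len(config$ny) - (config$ny + 1) / 2) / (config$ny / 2)
  1 - config$gain_amplitude * outer(y^2, x^2, `+`) / 2
}

render_frame <- function(pair, config, gain) {
  x_mm <- (seq_len(config$nx) - 0.5) * config$pixel_pitch
  pattern <- 0.5 * (pair$dc + pair$ac *
                      cos(2 * pi * config$fx * x_mm + config$phase))
  img <- config$exposure * gain * matrix(pattern, config$ny, config$nx,
                                         byrow = TRUE)
  if (config$noise_scale > 0) {
    img <- img + rnorm(length(img),
                       sd = config$noise_scale * sqrt(pmax(img, 0)))
  }
  img
}

#' Render a synthetic patterned SFDI scene
#'
#' Builds a patterned sample frame and a matching reference frame from the
#' white Monte Carlo forward model: each frame is
#' `exposure * gain(x, y) * 0.5 * (R_DC + R_AC cos(2 pi fx x + phase))`
#' plus seeded shot-like noise, where the (DC, AC) reflectance pair comes
#' from [predict_pair()] at the respective material's properties. The
#' ground truth is returned alongside the images.
#'
#' @param mua,mus_prime sample optical properties, 1/mm.
#' @param config a [scene_config()].
#' @param wmc the `wmc_record` rendering the scene (its phase function is
#'   the scene's true scattering behaviour).
#' @param ref_mua,ref_mus_prime reference-material properties (defaults:
#'   the reference phantom at 545 nm).
#' @return list with `sample` and `reference` image matrices, `truth`
#'   (sample and reference properties plus their predicted reflectance
#'   pairs) and `config`.
#' @export
render_scene <- function(mua, mus_prime, config, wmc,
                         ref_mua = NULL, ref_mus_prime = NULL) {
  stopifnot(inherits(config, "scene_config"), inherits(wmc, "wmc_record"))
  if (is.null(ref_mua) || is.null(ref_mus_prime)) {
    ref <- reference_phantom_spec("545nm")
    ref_mua <- ref_mua %||% ref$mua
    ref_mus_prime <- ref_mus_prime %||% ref$mus_prime
  }
  pair <- predict_pair(wmc, mua, mus_prime, config$fx)
  ref_pair <- predict_pair(wmc, ref_mua, ref_mus_prime, config$fx)
  gain <- scene_gain_field(config)
  with_seed(config$seed, {
    sample_img <- render_frame(pair, config, gain)
    reference_img <- render_frame(ref_pair, config, gain)
    list(sample = sample_img, reference = reference_img,
         truth = list(mua = mua, mus_prime = mus_prime, pair = pair,
                      ref_mua = ref_mua, ref_mus_prime = ref_mus_prime,
                      ref_pair = ref_pair),
         config = config)
  })
}

#' Process a rendered scene into an optical-property map
#'
#' The standard single-phase pipeline applied to a synthetic scene:
#' exposure normalization, Fourier demodulation of the sample and reference
#' frames, reference calibration against the predicted reference
#' reflectance, and LUT inversion.
#'
#' @param scene a [render_scene()] result.
#' @param lut inversion table to use (its phase function may deliberately
#'   differ from the one that rendered the scene).
#' @param wmc_ref record used to predict the reference reflectance; by
#'   default the prediction stored in the scene's truth is reused. For a
#'   reflectance-standard reference pass `rd_ref_pred`.
#' @param rd_ref_pred optional override for the predicted reference pair
#'   (e.g. a flat 0.99/0.99 reflectance standard).
#' @param mode demodulation filter mode.
#' @return a `property_map`.
#' @export
process_scene <- function(scene, lut, wmc_ref = NULL, rd_ref_pred = NULL,
                          mode = "notch") {
  cfg <- scene$config
  dem_s <- fourier_demod_single(scene$sample / cfg$exposure, cfg$fx,
                                cfg$pixel_pitch, mode = mode)
  dem_r <- fourier_demod_single(scene$reference / cfg$exposure, cfg$fx,
                                cfg$pixel_pitch, mode = mode)
  if (is.null(rd_ref_pred)) {
    rd_ref_pred <- if (is.null(wmc_ref)) {
      scene$truth$ref_pair
    } else {
      predict_pair(wmc_ref, scene$truth$ref_mua, scene$truth$ref_mus_prime,
                   cfg$fx)
    }
  }
  invert_map(calibrate(dem_s, dem_r, rd_ref_pred), lut)
}

#' Write / read a rendered frame as 16-bit grayscale TIFF
#'
#' Images are scaled by `max_value` into the 16-bit range on write and
#' rescaled on read; the exposure and pattern metadata travel in a plain
#' JSON-style text sidecar (`<path>.meta`). Requires the `tiff` package.
#'
#' @param image numeric matrix (a rendered frame).
#' @param path TIFF file path.
#' @param config the [scene_config()] the frame was rendered with.
#' @param max_value intensity mapped to the top of the 16-bit range.
#' @return `read_frame_tiff` returns a list with `image` and the sidecar
#'   metadata.
#' @export
write_frame_tiff <- function(image, path, config, max_value = max(image)) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF export")
  }
  stopifnot(is.matrix(image), max_value > 0)
  tiff::writeTIFF(pmin(pmax(image / max_value, 0), 1), path,
                  bits.per.sample = 16L)
  meta <- sprintf("{\"exposure\": %.17g, \"fx\": %.17g, \"pixel_pitch\": %.17g, \"max_value\": %.17g}",
                  config$exposure, config$fx, config$pixel_pitch, max_value)
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_frame_tiff
#' @export
read_frame_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF import")
  }
  meta_txt <- readLines(paste0(path, ".meta"))
  pick <- function(key) {
    as.numeric(sub(sprintf(".*\"%s\": ([-0-9.eE+]+).*", key), "\\1",
                   meta_txt))
  }
  img <- tiff::readTIFF(path) * pick("max_value")
  list(image = img, exposure = pick("exposure"), fx = pick("fx"),
       pixel_pitch = pick("pixel_pitch"))
}

#' Generate a synthetic goniometer measurement
#'
#' Emits the raw dataset a goniometer would record for a material with a
#' known two-term HG phase function: the true per-steradian density is
#' evaluated at the refraction-corrected angles, mapped back into detector
#' units by the solid angle and clear-sample transmission, contaminated
#' with a surface-scatter style angular offset and multiplicative noise.
#' The matching clear-sample angular scan is emitted alongside so the
#' reduction pipeline can undo the distortions.
#'
#' @param truth a [tthg_params()] object.
#' @param angles_meas detector angle grid, degrees (defaults to 10-degree
#'   steps over the unoccluded range including 0).
#' @param n_sample,n_det refractive indices.
#' @param clear_total_transmission clear-sample total transmission.
#' @param noise_sd multiplicative noise standard deviation (fractional).
#' @param surface_offset amplitude of the clear-sample angular background,
#'   detector units; concentrated at backward angles like surface
#'   scattering.
#' @param seed RNG seed.
#' @return list with `zno` (a [goniometry_dataset()]), `clear_angular`
#'   (aligned clear-sample scan), `clear_total_transmission` and `truth`.
#' @export
synth_goniometry <- function(truth,
                             angles_meas = c(seq(0, 60, 10), seq(120, 170, 10)),
                             n_sample = 1.556, n_det = 1,
                             clear_total_transmission = 0.92,
                             noise_sd = 0.02, surface_offset = 2e-5,
                             seed = 1) {
  stopifnot(inherits(truth, "tthg_params"))
  if (any(angles_meas > 60 & angles_meas < 120)) {
    stop("angle grid must exclude the occluded band (60, 120) degrees")
  }
  omega <- detector_solid_angle(8.2, 128)
  theta_scat <- refraction_correct(pmax(angles_meas, 1e-9), n_sample, n_det)
  p <- eval_tthg(truth, cos(theta_scat * pi / 180))
  clear_angular <- surface_offset * (1 - cos(angles_meas * pi / 180)) / 2
  clear_angular[angles_meas == 0] <- 0
  with_seed(seed, {
    # the instrument sweeps positive and negative detector angles; the two
    # mirrored scans are averaged, halving the noise variance
    one_sweep <- function() {
      p * omega * clear_total_transmission *
        (1 + rnorm(length(p), sd = noise_sd)) + clear_angular
    }
    raw <- (one_sweep() + one_sweep()) / 2
    list(zno = goniometry_dataset(angles_meas, raw, n_sample = n_sample,
                                  n_det = n_det),
         clear_angular = clear_angular,
         clear_total_transmission = clear_total_transmission,
         truth = truth)
  })
}
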