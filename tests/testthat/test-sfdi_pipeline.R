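sinusoid_image <- function(nx = 128, ny = 96, pitch = 0.2, periods = 16,
                           A = 2, m = 0.6, harmonics = 0) {
  fx <- periods / (nx * pitch)
  x <- (seq_len(nx) - 0.5) * pitch
  row <- A * (1 + m * cos(2 * pi * fx * x))
  if (harmonics > 0) {
    row <- row + A * harmonics * cos(4 * pi * fx * x)
  }
  list(img = matrix(rep(row, each = ny), ny, nx), fx = fx, pitch = pitch,
       A = A, m = m)
}

test_that("Fourier demodulation recovers flat and sinusoidal fields", {
  s <- sinusoid_image()
  flat <- fourier_demod_single(matrix(3, 64, 64), s$fx, s$pitch)
  expect_equal(mean(flat$m_dc), 3, tolerance = 1e-3)
  expect_lt(max(flat$m_ac), 0.01)

  d <- fourier_demod_single(s$img, s$fx, s$pitch)
  expect_lt(max(abs(d$m_dc - s$A)) / s$A, 0.01)
  expect_lt(max(abs(d$m_ac - s$A * s$m)) / (s$A * s$m), 0.01)

  da <- fourier_demod_single(s$img, s$fx, s$pitch, mode = "anisotropic")
  expect_lt(max(abs(da$m_dc - s$A)) / s$A, 0.01)
  expect_lt(max(abs(da$m_ac - s$A * s$m)) / (s$A * s$m), 0.02)
})

test_that("harmonic contamination is suppressed below one percent", {
  s <- sinusoid_image(harmonics = 0.1)
  d <- fourier_demod_single(s$img, s$fx, s$pitch)
  expect_lt(max(abs(d$m_ac - s$A * s$m)) / (s$A * s$m), 0.01)
  expect_lt(max(abs(d$m_dc - s$A)) / s$A, 0.01)
})

test_that("demodulation rejects unresolvable pattern frequencies", {
  img <- matrix(1, 32, 32)
  expect_error(fourier_demod_single(img, fx = 3, pixel_pitch = 0.2),
               "Nyquist")
  expect_error(fourier_demod_single(img, fx = 1.5, pixel_pitch = 0.2),
               "4 pixels")
})

test_that("calibration is a per-pixel ratio against the reference", {
  s <- sinusoid_image()
  dem <- fourier_demod_single(s$img, s$fx, s$pitch)
  # self-reference returns the predicted reflectance everywhere
  ref_pair <- reflectance_pair(0.55, 0.21, s$fx)
  cal <- calibrate(dem, dem, ref_pair)
  expect_equal(mean(cal$dc), 0.55, tolerance = 1e-9)
  expect_equal(mean(cal$ac), 0.21, tolerance = 1e-9)
  # plain arithmetic and scale invariance
  mk <- function(dc, ac) structure(list(m_dc = matrix(dc, 2, 2),
                                        m_ac = matrix(ac, 2, 2), fx = 1,
                                        pixel_pitch = 0.2, mode = "notch"),
                                   class = "demodulated_image")
  out <- calibrate(mk(0.5, 0.5), mk(0.25, 0.25), reflectance_pair(0.4, 0.4, 1))
  expect_equal(out$dc[1, 1], 0.8)
  k <- 3.7
  out2 <- calibrate(mk(0.5 * k, 0.5 * k), mk(0.25 * k, 0.25 * k),
                    reflectance_pair(0.4, 0.4, 1))
  expect_equal(out2$dc, out$dc)
  masked <- calibrate(mk(0.5, 0.5), mk(0, 0.25), reflectance_pair(0.4, 0.4, 1))
  expect_true(all(is.na(masked$dc)))
})

test_that("map inversion applies the undetermined-pixel rules", {
  lut <- fix$lut84_fx1
  pr <- predict_pair(fix$w84, 0.05, 1.0, 1.0)
  uniform <- reflectance_pair(matrix(pr$dc, 4, 4), matrix(pr$ac, 4, 4), 1.0)
  pm <- invert_map(uniform, lut)
  expect_false(any(pm$undetermined_mask))
  expect_lt(abs(mean(pm$mua_map) - 0.05) / 0.05, 0.02)
  expect_lt(abs(mean(pm$mus_prime_map) - 1.0), 0.02)
  # AC at or above DC cannot be inverted
  bad <- reflectance_pair(matrix(0.2), matrix(0.2 * 1.01), 1.0)
  expect_true(invert_map(bad, lut)$undetermined_mask[1])
  # DC below the grid floor
  low <- reflectance_pair(matrix(5e-4), matrix(1e-4), 1.0)
  expect_true(invert_map(low, lut)$undetermined_mask[1])
  expect_error(invert_map(reflectance_pair(matrix(0.3), matrix(0.1), 0.3),
                          lut), "frequency")
})

test_that("inverse Monte Carlo fitting recovers slab properties", {
  truth <- c(mua = 0.3, mus_prime = 1.6)
  gen <- transport_config(mua = truth[1], spf = sthg_params(0.84),
                          mus_prime = truth[2], n_photons = 2e5, seed = 99)
  st <- simulate_slab(gen, 1)
  fit <- inverse_mc_fit(c(st$R, st$T), "thin_RT", spf = sthg_params(0.84),
                        thickness = 1, n_photons = 2e4, seed = 7)
  expect_lt(abs(fit$mua - truth[1]) / truth[1], 0.05)
  expect_lt(abs(fit$mus_prime - truth[2]) / truth[2], 0.05)

  # zero-absorption truth pushes the estimate to the nonnegativity boundary
  gen0 <- transport_config(mua = 0, spf = sthg_params(0.84), mus_prime = 1.6,
                           n_photons = 1e5, seed = 45)
  s0 <- simulate_slab(gen0, 1)
  fit0 <- inverse_mc_fit(c(s0$R, s0$T), "thin_RT", spf = sthg_params(0.84),
                         thickness = 1, n_photons = 2e4, seed = 7,
                         init = c(0.05, 1.6))
  expect_lt(fit0$mua, 0.02)
})

test_that("both inverse-MC measurement modes agree on the same phantom", {
  truth <- c(0.3, 1.6)
  gen <- transport_config(mua = truth[1], spf = sthg_params(0.84),
                          mus_prime = truth[2], n_photons = 2e5, seed = 99)
  st <- simulate_slab(gen, 1)
  fit1 <- inverse_mc_fit(c(st$R, st$T), "thin_RT", spf = sthg_params(0.84),
                         thickness = 1, n_photons = 2e4, seed = 7)
  thick <- simulate_slab(
    transport_config(mua = truth[1], spf = sthg_params(0.84),
                     mus_prime = truth[2], n_photons = 1e5, seed = 98),
    17, beam_diameter = 4, lateral_period = 8)
  fit2 <- inverse_mc_fit(c(thick$R, st$transflectance),
                         "thick_R_transflectance", spf = sthg_params(0.84),
                         thickness = 1, n_photons = 2e4, seed = 7,
                         init = c(0.2, 2))
  expect_lt(abs(fit1$mua - fit2$mua) / truth[1], 0.12)
  expect_lt(abs(fit1$mus_prime - fit2$mus_prime) / truth[2], 0.12)
})
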