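test_that("refraction correction follows Snell's law on both branches", {
  expect_equal(refraction_correct(0, 1.556), 0)
  th60 <- refraction_correct(60, 1.556)
  expect_equal(th60, asin(sin(pi / 3) / 1.556) * 180 / pi)
  expect_gt(60 - th60, 25)  # compression exceeds 25 degrees
  th170 <- refraction_correct(170, 1.556)
  expect_equal(th170, 180 - asin(sin(170 * pi / 180) / 1.556) * 180 / pi)
  expect_gt(th170, 170)
  # monotone on each branch
  fwd <- refraction_correct(seq(5, 85, 5), 1.556)
  bwd <- refraction_correct(seq(95, 175, 5), 1.556)
  expect_true(all(diff(fwd) > 0))
  expect_true(all(diff(bwd) > 0))
  expect_error(refraction_correct(90, 1.556), "90")
})

test_that("refraction correction inverts the forward Snell distortion", {
  # the generator distorts by mapping detector angles through Snell's law;
  # applying the inverse mapping to the corrected angle must return the
  # detector angle on both branches
  snell_out <- function(theta_scat, n_sample, n_det = 1) {
    inner <- asin(pmin(n_sample / n_det * sin(pmin(theta_scat, 180 - theta_scat) *
                                                pi / 180), 1)) * 180 / pi
    ifelse(theta_scat < 90, inner, 180 - inner)
  }
  th <- c(5, 20, 40, 55, 125, 150, 170)
  expect_equal(snell_out(refraction_correct(th, 1.556), 1.556), th,
               tolerance = 1e-10)
})

test_that("detector solid angle uses the planar-disc approximation", {
  expect_equal(signif(detector_solid_angle(8.2, 128), 2), 3.2e-3)
  expect_lt(detector_solid_angle(1e-6, 128), 1e-16)
  # pi (d/2)^2 = D^2 gives exactly one steradian
  d <- 2 * 10 / sqrt(pi)
  expect_warning(omega <- detector_solid_angle(d, 10), "approximation")
  expect_equal(omega, 1)
})

test_that("normalization and background correction reduce raw scans", {
  ds <- goniometry_dataset(c(0, 10, 30, 130, 170), c(5, 4, 3, 1, 0.5))
  omega <- detector_solid_angle(8.2, 128)
  out <- normalize_and_correct(ds, 1, rep(0, 5))
  expect_equal(out$value, ds$intensity / omega)
  # perfect cancellation at a backward angle floors to zero with a flag
  out2 <- normalize_and_correct(ds, 0.9, c(0, 0, 0, 1, 0.6))
  expect_equal(out2$value[4], 0)
  expect_true(out2$floored[5])
  expect_false(any(out2$floored[1:3]))
  expect_error(normalize_and_correct(ds, 0.9, rep(0, 3)), "align")
  # synthetic scan with a known surface-scatter offset: correction removes it
  zno <- tthg_params(0.855, 0.983, 0)
  syn <- synth_goniometry(zno, noise_sd = 0, surface_offset = 5e-5, seed = 2)
  corr <- normalize_and_correct(syn$zno, syn$clear_total_transmission,
                                syn$clear_angular)
  truth <- eval_tthg(zno, cos(corr$angle_scat * pi / 180))
  expect_equal(corr$value[-1], truth[-1], tolerance = 1e-10)
})

test_that("single-lobe section fits recover known anisotropies", {
  th <- refraction_correct(seq(10, 60, 10), 1.556)
  vals <- 0.855 * eval_sthg(sthg_params(0.983), cos(th * pi / 180))
  fit <- fit_sthg_section(th, vals, "forward")
  expect_equal(fit$g, 0.983, tolerance = 1e-3)
  expect_equal(fit$s, 0.855, tolerance = 1e-3)
  thb <- refraction_correct(seq(120, 170, 10), 1.556)
  fitb <- fit_sthg_section(thb, rep(1 / (4 * pi) * 0.145, 6), "backward")
  expect_equal(fitb$g, 0, tolerance = 1e-3)
  expect_error(fit_sthg_section(th, rep(0, 6), "forward"), "positive")
})

test_that("lobe combination and optical-thickness bounds match closed forms", {
  expect_equal(combine_tthg(1, 1, 0.9, -0.1)$alpha, 0.5)
  comb <- combine_tthg(0.855, 0.145, 0.983, 0)
  expect_equal(round(mean_cosine(comb), 2), 0.84)
  expect_equal(combine_tthg(0.7, 0, 0.9, 0)$alpha, 1)
  expect_error(combine_tthg(0, 0, 0.9, 0), "zero")

  est <- estimate_optical_thickness(0.334, 0.8, 0.9, 0.33)
  expect_equal(round(est$mus_low, 2), 1.67)
  expect_equal(round(est$mus_high, 2), 3.34)
  expect_equal(round(est$mfp_low, 2), 0.55)
  expect_equal(round(est$mfp_high, 2), 1.10)
  eq <- estimate_optical_thickness(1, 0.85, 0.85, 0.5)
  expect_equal(eq$mus_low, eq$mus_high)
  expect_error(estimate_optical_thickness(1, 0.5, 1, 0.5))
})

test_that("full goniometry reduction recovers the generating parameters", {
  zno <- tthg_params(0.855, 0.983, 0)
  # noiseless round trip converges to the truth
  syn0 <- synth_goniometry(zno, noise_sd = 0, surface_offset = 0, seed = 1)
  fit0 <- fit_goniometry(syn0$zno, syn0$clear_total_transmission,
                         syn0$clear_angular)
  expect_equal(fit0$alpha, 0.855, tolerance = 0.01)
  expect_equal(fit0$gf, 0.983, tolerance = 2e-3)
  expect_equal(fit0$gb, 0, tolerance = 2e-3)
  # with refraction, solid angle, surface offset and 2% noise (seeded)
  syn <- synth_goniometry(zno, noise_sd = 0.02, surface_offset = 2e-5,
                          seed = 1)
  fit <- fit_goniometry(syn$zno, syn$clear_total_transmission,
                        syn$clear_angular)
  expect_lt(abs(fit$alpha - 0.855) / 0.855, 0.05)
  expect_lt(abs(fit$gf - 0.983), 0.01)
  expect_lt(abs(fit$gb - 0), 0.01)
})

test_that("fitted overall anisotropy is invariant to joint lobe rescaling", {
  g1a <- mean_cosine(combine_tthg(0.6, 0.2, 0.95, -0.05))
  g1b <- mean_cosine(combine_tthg(0.6 * 7.3, 0.2 * 7.3, 0.95, -0.05))
  expect_equal(g1a, g1b)
})

test_that("goniometry datasets round-trip through CSV", {
  zno <- tthg_params(0.855, 0.983, 0)
  syn <- synth_goniometry(zno, seed = 9)
  f <- tempfile(fileext = ".csv")
  write_goniometry(syn$zno, f)
  back <- read_goniometry(f)
  expect_equal(back$angles_meas, syn$zno$angles_meas)
  expect_equal(back$intensity, syn$zno$intensity)
  expect_equal(back$n_sample, 1.556)
})
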