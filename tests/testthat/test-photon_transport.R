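test_that("non-absorbing half-space returns nearly all photons by the time cap", {
  # analog transport (no roulette) so every exit record carries unit weight
  cfg <- transport_config(mua = 0, spf = sthg_params(0.84), mus_prime = 10,
                          n_medium = 1.56, n_outside = 1.56,
                          n_photons = 4e3, seed = 5, roulette_mfps = Inf)
  rec <- propagate_pencil(cfg)
  tot <- attr(rec, "totals")
  expect_gte(tot$refl_top, 0.99)
  expect_true(all(rec$weight == 1))
  expect_true(all(rec$radius >= 0))
  expect_true(all(rec$time_of_flight > 0 & rec$time_of_flight <= 300))
  expect_equal(tot$specular, 0)
})

test_that("pencil-beam reflectance agrees with an independent R implementation", {
  cfg <- transport_config(mua = 0.1, spf = sthg_params(0.84), mus_prime = 10,
                          n_medium = 1.56, n_outside = 1, n_photons = 3e4,
                          seed = 8)
  rec <- propagate_pencil(cfg)
  R_kernel <- attr(rec, "totals")$refl_top
  set.seed(31)
  orc <- oracle_mc(mua = 0.1, mus = 10 / (1 - 0.84), spf = list(g = 0.84),
                   n_medium = 1.56, n_outside = 1, thickness = Inf,
                   n_photons = 6e3)
  se <- sqrt(R_kernel * (1 - R_kernel) / 3e4 + orc$R * (1 - orc$R) / 6e3)
  expect_lt(abs(R_kernel - orc$R), 3 * se + 0.01)
})

test_that("slab transport reproduces ballistic and Beer-Lambert limits", {
  clear <- transport_config(mua = 0, spf = sthg_params(0), mus = 0,
                            n_medium = 1, n_outside = 1, n_photons = 2e3,
                            seed = 2)
  s <- simulate_slab(clear, 1)
  expect_equal(s$T, 1)
  expect_equal(s$ledger, 1, tolerance = 1e-12)

  bl <- transport_config(mua = 1, spf = sthg_params(0), mus = 0,
                         n_medium = 1, n_outside = 1, n_photons = 5e4,
                         seed = 3)
  sb <- simulate_slab(bl, 1)
  se <- sqrt(exp(-1) * (1 - exp(-1)) / 5e4)
  expect_lt(abs(sb$T - exp(-1)), 3 * se)
})

test_that("thin scattering slab R/T agree with the independent oracle", {
  zno <- tthg_params(0.855, 0.983, 0)
  mus <- 0.334 / (1 - mean_cosine(zno))
  cfg <- transport_config(mua = 0.01, spf = zno, mus = mus, n_medium = 1.556,
                          n_outside = 1, n_photons = 2e4, seed = 12)
  s <- simulate_slab(cfg, 0.33, beam_diameter = 0, lateral_period = NULL)
  set.seed(77)
  orc <- oracle_mc(mua = 0.01, mus = mus,
                   spf = list(alpha = 0.855, gf = 0.983, gb = 0),
                   n_medium = 1.556, n_outside = 1, thickness = 0.33,
                   n_photons = 1e4)
  seR <- sqrt(s$R * (1 - s$R) / 2e4 + orc$R * (1 - orc$R) / 1e4)
  seT <- sqrt(s$T * (1 - s$T) / 2e4 + orc$T * (1 - orc$T) / 1e4)
  expect_lt(abs(s$R - orc$R), 3 * seR + 0.005)
  expect_lt(abs(s$T - orc$T), 3 * seT + 0.005)
})

test_that("the weight ledger closes exactly", {
  for (cfg in list(
    transport_config(mua = 0.3, spf = sthg_params(0.84), mus_prime = 1.6,
                     n_photons = 5e3, seed = 4),
    transport_config(mua = 0.3, spf = sthg_params(0.84), mus_prime = 1.6,
                     n_photons = 5e3, seed = 4, roulette_mfps = Inf),
    transport_config(mua = 0.01, spf = tthg_params(0.855, 0.983, 0),
                     mus_prime = 2, n_medium = 1.56, n_photons = 5e3,
                     seed = 6))) {
    s <- simulate_slab(cfg, 0.8)
    expect_equal(s$ledger, 1, tolerance = 1e-9)
    expect_equal(s$transflectance, 1 - s$A)
  }
  # analog absorbing run: R + T + A (+ specular) alone must close
  cfg <- transport_config(mua = 0.5, spf = sthg_params(0.7), mus_prime = 1,
                          n_medium = 1.4, n_photons = 1e4, seed = 9,
                          roulette_mfps = Inf)
  s <- simulate_slab(cfg, 1)
  expect_equal(s$R + s$T + s$A + s$specular + s$inflight, 1,
               tolerance = 1e-9)
})

test_that("transport is deterministic per seed", {
  cfg <- transport_config(mua = 0.05, spf = sthg_params(0.84), mus_prime = 5,
                          n_photons = 2e3, seed = 123)
  r1 <- propagate_pencil(cfg)
  r2 <- propagate_pencil(cfg)
  expect_identical(r1$radius, r2$radius)
  expect_identical(r1$weight, r2$weight)
  cfg$seed <- 124
  r3 <- propagate_pencil(cfg)
  expect_false(identical(r1$radius, r3$radius))
})

test_that("total reflectance is anisotropy-neutral at matched reduced scattering", {
  # forward-lobe shape barely moves the diffuse-scale reflectance when mus'
  # is held fixed
  r84 <- vapply(fix$w84_batches, function(w) predict_rd(w, 0.1, 10, 0),
                numeric(1))
  cfg983 <- transport_config(mua = 1e-8, spf = sthg_params(0.983),
                             mus_prime = 10, n_medium = 1.56,
                             n_photons = 3e4, seed = 55)
  w983 <- bin_records(propagate_pencil(cfg983))
  r983 <- predict_rd(w983, 0.1, 10, 0)
  se <- sqrt(stats::var(r84) / length(r84) + stats::var(r84))
  expect_lt(abs(mean(r84) - r983), 3 * se)
})

test_that("backscatter lobe raises early counts and lowers the peak", {
  # ttHG vs stHG at equal mus': more escaped weight at sub-diffuse radii,
  # less at the distribution peak
  nr <- length(fix$wz$r_centers)
  early <- fix$wz$r_centers < 0.05
  peak <- fix$wz$r_centers > 0.3 & fix$wz$r_centers < 1
  wz_early <- sum(fix$wz$counts[early, ]) / fix$wz$n_launched
  w84_early <- sum(fix$w84$counts[early, ]) / fix$w84$n_launched
  wz_peak <- sum(fix$wz$counts[peak, ]) / fix$wz$n_launched
  w84_peak <- sum(fix$w84$counts[peak, ]) / fix$w84$n_launched
  expect_gt(wz_early, w84_early)
  expect_lt(wz_peak, w84_peak)
})

test_that("patterned-source profiles behave like the illumination field", {
  cfg <- transport_config(mua = 0.05, spf = sthg_params(0.84), mus_prime = 2,
                          n_photons = 4e4, seed = 71)
  # DC limit: at a vanishing spatial frequency the modulation passes
  # through unattenuated, so demodulated AC approaches DC
  dl <- simulate_sfdi_demodulated(cfg, fx = 0.02)
  expect_gt(dl$ac / dl$dc, 0.9)
  expect_lt(dl$ac / dl$dc, 1.05)
  # the exit profile tracks the illumination pattern shape
  prof <- simulate_sfdi_pattern(cfg, fx = 0.3, phase = 0.7)
  shape <- 1 + cos(2 * pi * 0.3 * prof$x + 0.7)
  expect_gt(stats::cor(prof$reflectance, shape), 0.95)
  # a phase shift translates the profile cyclically (in expectation): a
  # 2 pi / 5 shift is exactly five bins of the 25-bin-per-period profile
  prof2 <- simulate_sfdi_pattern(cfg, fx = 0.3, phase = 0.7 + 2 * pi / 5)
  shifted <- c(prof2$reflectance[46:50], prof2$reflectance[1:45])
  expect_gt(stats::cor(prof$reflectance, shifted), 0.9)
  # three-phase demodulation identity on analytic fields
  x <- seq(0, 2, length.out = 50)
  mk <- function(ph) 0.37 + 0.12 * cos(2 * pi * 1.0 * x + 0.4 + ph)
  dp <- demod_three_phase(mk(0), mk(2 * pi / 3), mk(4 * pi / 3), fx = 1)
  expect_equal(dp$dc, 0.37, tolerance = 1e-12)
  expect_equal(dp$ac, 0.12, tolerance = 1e-12)
  const <- demod_three_phase(rep(2, 9), rep(2, 9), rep(2, 9))
  expect_equal(const$dc, 2)
  expect_equal(const$ac, 0)
  expect_error(demod_three_phase(1:4, 1:3, 1:4), "shape")
})

test_that("noisy three-phase demodulation recovers the modulation", {
  cfg <- transport_config(mua = 0.01, spf = sthg_params(0.84), mus_prime = 5,
                          n_photons = 3e4, seed = 81)
  reps <- lapply(1:3, function(k) {
    c2 <- cfg
    c2$seed <- cfg$seed + k * 1000
    simulate_sfdi_demodulated(c2, fx = 0.3)
  })
  acs <- vapply(reps, function(r) r$ac, numeric(1))
  pred <- predict_rd(fix$w84, 0.01, 5, 0.3)
  se <- stats::sd(acs) / sqrt(3)
  expect_lt(abs(mean(acs) - pred), 3 * (se + 0.004))
})
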