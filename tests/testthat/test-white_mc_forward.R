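fake_records <- function(radius, tof, weight = rep(1, length(radius)),
                         n_photons = length(radius)) {
  out <- data.frame(radius = radius, time_of_flight = tof, weight = weight)
  cfg <- transport_config(mua = 1e-8, spf = sthg_params(0.84),
                          mus_prime = 10, n_medium = 1.56,
                          n_photons = n_photons, seed = 1)
  attr(out, "config") <- cfg
  attr(out, "totals") <- list(n_photons = n_photons)
  out
}

test_that("binning conserves weight and places single records correctly", {
  one <- bin_records(fake_records(1, 1))
  expect_equal(sum(one$counts != 0), 1)
  ij <- which(one$counts != 0, arr.ind = TRUE)
  expect_equal(one$r_centers[ij[1]], 1, tolerance = 0.02)
  expect_equal(one$t_centers[ij[2]], 1, tolerance = 0.03)

  raw <- propagate_pencil(transport_config(
    mua = 1e-8, spf = sthg_params(0.84), mus_prime = 10, n_medium = 1.56,
    n_photons = 2e4, seed = 501))
  binned <- bin_records(raw)
  expect_equal(sum(binned$counts) + binned$guard, sum(raw$weight),
               tolerance = 1e-9)
  expect_true(all(diff(binned$r_centers) > 0))
  expect_true(all(diff(log(binned$r_centers)) -
                    diff(log(binned$r_centers))[1] < 1e-9))
})

test_that("property scaling preserves the base distribution and photons", {
  w <- fix$w84
  base <- apply_props(w, 0, w$base_mus_prime)
  expect_equal(base$total, sum(w$counts) / w$n_launched, tolerance = 1e-12)
  expect_equal(base$rho, w$r_centers)
  # plane-integrated reflectance is invariant under scaling when mua = 0
  for (beta in c(0.5, 2)) {
    scaled <- apply_props(w, 0, w$base_mus_prime * beta)
    expect_equal(scaled$total, base$total, tolerance = 1e-12)
  }
})

test_that("absorption enters through the Beer-Lambert law cell by cell", {
  # a record concentrated at one time of flight: doubling mua must square
  # the attenuation factor
  w <- bin_records(fake_records(c(0.5, 0.5), c(2, 2), n_photons = 4))
  r0 <- apply_props(w, 0, 10)$total
  r1 <- apply_props(w, 0.05, 10)$total
  r2 <- apply_props(w, 0.10, 10)$total
  expect_equal(r1 / r0, exp(log(r2 / r0) / 2), tolerance = 1e-9)
  expect_equal(r2 / r0, (r1 / r0)^2, tolerance = 1e-9)
})

test_that("the scaling law matches rerunning transport at scaled properties", {
  # rescaling the base record to mus' = 5 or 20 must agree with fresh
  # simulations run natively at those properties
  for (mus_target in c(5, 20)) {
    pred <- vapply(fix$w84_batches,
                   function(w) predict_rd(w, 0.01, mus_target, 0.5),
                   numeric(1))
    direct <- vapply(1:3, function(k) {
      cfg <- transport_config(mua = 1e-8, spf = sthg_params(0.84),
                              mus_prime = mus_target, n_medium = 1.56,
                              n_photons = 4e4, seed = 900 + k + mus_target)
      predict_rd(bin_records(propagate_pencil(cfg)), 0.01, mus_target, 0.5)
    }, numeric(1))
    se <- sqrt(stats::var(pred) / 3 + stats::var(direct) / 3)
    expect_lt(abs(mean(pred) - mean(direct)), 3 * se)
  }
})

test_that("the order-zero Hankel transform matches a closed form", {
  # exponential profile: 2 pi integral rd(r) J0(2 pi fx r) r dr has the
  # closed form a / (a^2 + k^2)^(3/2) when rd(r) = (a / 2 pi) * exp(-a r)
  a <- 3
  rho <- exp(seq(log(1e-4), log(60), length.out = 4000))
  edges <- exp(c(log(rho[1]) - diff(log(rho))[1] / 2,
                 log(rho) + diff(log(rho))[1] / 2))
  prof <- structure(list(rho = rho,
                         rd_per_area = a^2 / (2 * pi) * exp(-a * rho),
                         area = pi * diff(edges^2),
                         total = NA),
                    class = "radial_reflectance")
  for (fx in c(0, 0.2, 0.7)) {
    k <- 2 * pi * fx
    expect_equal(hankel_rd(prof, fx), a^3 / (a^2 + k^2)^1.5,
                 tolerance = 5e-3)
  }
  # a point-like source is flat in spatial frequency
  delta <- bin_records(fake_records(c(2e-5, 2e-5), c(1e-3, 1e-3),
                                    n_photons = 2))
  pd <- apply_props(delta, 0, 10)
  rd <- hankel_rd(pd, c(0, 0.5, 1))
  expect_equal(rd[2] / rd[1], 1, tolerance = 1e-4)
  expect_equal(rd[3] / rd[1], 1, tolerance = 1e-3)
})

test_that("predicted pairs are physical across a property grid", {
  mua_g <- exp(seq(log(0.005), log(2), length.out = 10))
  mus_g <- exp(seq(log(0.3), log(8), length.out = 10))
  for (mua in mua_g) {
    for (mus in mus_g) {
      p <- predict_pair(fix$w84, mua, mus, 1.0)
      expect_gte(p$dc, p$ac)
    }
  }
  rd <- predict_rd(fix$w84, 0.05, 2, seq(0, 1, 0.1))
  expect_true(all(diff(rd) < 0))
})

test_that("LUT inversion round-trips the forward model within 2%", {
  lut <- fix$lut84_fx1
  for (pt in list(c(0.05, 1), c(0.5, 2), c(0.01, 5), c(1, 3))) {
    pr <- predict_pair(fix$w84, pt[1], pt[2], 1.0)
    pm <- invert_map(reflectance_pair(matrix(pr$dc), matrix(pr$ac), 1.0),
                     lut)
    expect_false(pm$undetermined_mask[1])
    expect_lt(abs(pm$mua_map[1] - pt[1]) / pt[1], 0.02)
    expect_lt(abs(pm$mus_prime_map[1] - pt[2]) / pt[2], 0.02)
  }
})

test_that("unphysical LUT nodes are flagged rather than filled", {
  lut <- fix$lut84_fx1
  i <- findInterval(0.01, lut$dc_grid)
  j <- findInterval(0.02, lut$ac_grid)  # AC > DC
  expect_true(lut$flagged[i, j])
  expect_true(is.na(lut$mua_surface[i, j]))
})

test_that("phase-function choice moves the LUT most at high AC/DC ratios", {
  l84 <- fix$lut84_fx1
  lz <- fix$lutz_fx1
  ratio <- outer(l84$dc_grid, l84$ac_grid, function(d, a) a / d)
  both <- is.finite(l84$mus_prime_surface) & is.finite(lz$mus_prime_surface)
  rel <- abs(log(l84$mus_prime_surface / lz$mus_prime_surface))
  hi <- both & ratio > 0.5 & ratio < 1
  lo <- both & ratio < 0.2
  expect_gt(mean(rel[hi]), mean(rel[lo]))
})

test_that("white MC records and LUTs round-trip through text files", {
  f <- tempfile(fileext = ".tsv")
  write_wmc(fix$w84_batches[[1]], f)
  back <- read_wmc(f)
  expect_equal(back$counts, fix$w84_batches[[1]]$counts)
  expect_equal(back$n_launched, fix$w84_batches[[1]]$n_launched)
  expect_equal(predict_rd(back, 0.05, 2, 0.5),
               predict_rd(fix$w84_batches[[1]], 0.05, 2, 0.5))
  fl <- tempfile(fileext = ".csv")
  write_lut(fix$lut84_fx1, fl)
  lback <- read_lut(fl)
  expect_equal(lback$fx, 1.0)
  expect_equal(lback$mua_surface, fix$lut84_fx1$mua_surface,
               tolerance = 1e-6)
})
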