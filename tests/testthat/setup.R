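# Shared fixtures, built once per test run. White Monte Carlo records are
# built in independent-seed batches so tests can estimate Monte Carlo
# standard errors from the batch spread.
zno_tthg <- tthg_params(alpha = 0.855, gf = 0.983, gb = 0)

wmc_batches <- function(spf, label, n_per = 5e4, k = 3, seed0 = 400) {
  lapply(seq_len(k), function(i) {
    build_wmc(spf, n_photons = n_per, seed = seed0 + 101 * i,
              spf_label = label)
  })
}

fix <- new.env()
fix$w84_batches <- wmc_batches(sthg_params(0.84), "sthg-low", seed0 = 400)
fix$w84 <- combine_wmc(fix$w84_batches)
fix$wz_batches <- wmc_batches(zno_tthg, "tthg", seed0 = 700)
fix$wz <- combine_wmc(fix$wz_batches)
fix$lut84_fx1 <- build_lut(fix$w84, fx = 1.0)
fix$lutz_fx1 <- build_lut(fix$wz, fx = 1.0)

# standard error of a per-record statistic from the batch spread
batch_se <- function(batches, stat) {
  v <- vapply(batches, stat, numeric(1))
  stats::sd(v) / sqrt(length(v))
}
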