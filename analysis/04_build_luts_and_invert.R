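#!/usr/bin/env Rscript
# Build inversion lookup tables from the white Monte Carlo records and
# check that forward prediction followed by LUT inversion returns the
# original optical properties.

library(sfdiopt)
dir.create("results", showWarnings = FALSE)

wz <- read_wmc("results/02_wmc_tthg.tsv")
wl <- read_wmc("results/02_wmc_sthg-low.tsv")

for (fx in c(0.3, 1.0)) {
  lut <- build_lut(wz, fx = fx)
  write_lut(lut, sprintf("results/04_lut_tthg_fx%g.csv", fx))
  cat(sprintf("ttHG LUT at fx = %.1f: %.1f%% of reflectance nodes determined\n",
              fx, 100 * mean(is.finite(lut$mua_surface))))
}

lut1 <- read_lut("results/04_lut_tthg_fx1.csv")
pts <- expand.grid(mua = c(0.02, 0.1, 0.5, 2), mus = c(0.5, 1.5, 3, 6))
pts$mua_hat <- pts$mus_hat <- NA_real_
for (k in seq_len(nrow(pts))) {
  pr <- predict_pair(wz, pts$mua[k], pts$mus[k], 1.0)
  pm <- invert_map(reflectance_pair(matrix(pr$dc), matrix(pr$ac), 1.0), lut1)
  pts$mua_hat[k] <- pm$mua_map[1]
  pts$mus_hat[k] <- pm$mus_prime_map[1]
}
pts$mua_err_pct <- 100 * abs(pts$mua_hat - pts$mua) / pts$mua
pts$mus_err_pct <- 100 * abs(pts$mus_hat - pts$mus) / pts$mus
write.csv(pts, "results/04_lut_roundtrip.csv", row.names = FALSE)
ok <- is.finite(pts$mua_err_pct)
cat(sprintf("LUT roundtrip: median error mua %.2f%%, mus' %.2f%% (%d/%d points in table)\n",
            median(pts$mua_err_pct[ok]), median(pts$mus_err_pct[ok]),
            sum(ok), nrow(pts)))
cat("wrote results/04_lut_roundtrip.csv\n")
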