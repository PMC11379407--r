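# sfdiopt

Modelling stack for **spatial frequency domain imaging (SFDI)** of turbid
media in the diffuse and sub-diffuse regimes, for researchers studying how
the assumed scattering phase function (SPF) and the polarization
configuration affect the accuracy of SFDI-derived optical properties.

SFDI projects sinusoidal patterns onto a sample and inverts the
spatial-frequency-dependent reflectance `Rd(fx)` into per-pixel maps of
the absorption coefficient `mua` and reduced scattering coefficient
`mus' = mus (1 - g1)`. At high spatial frequencies or strong absorption
the reflectance is dominated by photons that scattered only a few times,
and it becomes sensitive to the SPF's backscatter lobe — the sub-diffuse
regime. The package implements, end to end and without hardware:

- **Phase functions**: single- and two-term Henyey–Greenstein densities
  `p(cos t) = (1/4pi)(1-g^2)/(1+g^2-2g cos t)^(3/2)` (mixture weight
  `alpha`, lobes `gf`, `gb`, overall anisotropy
  `g1 = alpha gf + (1-alpha) gb`), with numerical inverse-CDF tabulation
  and sampling for arbitrary SPFs.
- **Goniometry reduction**: solid-angle normalization, clear-sample
  background subtraction, Snell refraction correction of detector angles,
  and weighted two-lobe fitting that yields `(alpha, gf, gb)`.
- **Photon transport**: a seeded compiled Monte Carlo kernel for
  half-spaces, slabs and sinusoidally patterned sources with cyclic
  boundaries; exact weight ledgers; unbiased path-stretching roulette for
  the heavy-tailed non-absorbing runs.
- **White Monte Carlo (wMC) forward model**: a log-binned exit
  radius × time-of-flight record at base properties, rescaled to arbitrary
  `(mua, mus')` by coordinate scaling plus Beer–Lambert attenuation, and
  transformed to `Rd(fx)` with an order-zero Hankel transform.
- **Inversion**: log-sampled lookup tables (DC × AC reflectance →
  properties) with flagged undetermined regions, single-phase
  Fourier-domain demodulation, reference calibration
  `Rd = (M/Mref) Rd_ref_pred`, and an inverse Monte Carlo fitter for
  ground-truth characterization.
- **Synthetic data and error analysis**: the 16-phantom design grid,
  rendered patterned scenes with gain/exposure/shot-like noise, synthetic
  goniometry, ROI statistics with the 2% undetermined-omission rule, MAPE,
  and the SPF × polarization error tables.

## Worked example

Fit a ZnO-like phase function from synthetic goniometry, build a white
Monte Carlo record, and invert a rendered scene:

```r
library(sfdiopt)

# 1. goniometry -> two-term Henyey-Greenstein fit
truth <- tthg_params(alpha = 0.855, gf = 0.983, gb = 0)   # g1 = 0.84
syn   <- synth_goniometry(truth, noise_sd = 0.02, surface_offset = 2e-5, seed = 1)
fit   <- fit_goniometry(syn$zno, syn$clear_total_transmission, syn$clear_angular)
fit
#> ttHG phase function: alpha = 0.8588, gf = 0.9834, gb = -4.5e-10 (g1 = 0.8446)

# 2. white Monte Carlo record and forward predictions
wz <- build_wmc(truth, n_photons = 1.5e5, seed = 21, spf_label = "tthg")
predict_pair(wz, mua = 0.3, mus_prime = 1.6, fx = 1.0)
#> reflectance pair at fx = 1 /mm: DC = 0.1447, AC = 0.04085

# 3. render a patterned scene, demodulate, calibrate, invert
lut <- build_lut(wz, fx = 1.0)
cfg <- scene_config(fx = 1.0, nx = 250, ny = 80, pixel_pitch = 0.2, seed = 5)
sc  <- render_scene(mua = 0.3, mus_prime = 1.6, cfg, wz)
pm  <- process_scene(sc, lut)
roi_stats(pm, "mus_prime")
#> ROI: mean 1.612 [q25 1.496, q75 1.72], 0.00% undetermined
```

The recovered map mean (1.61 mm⁻¹ against a ground truth of 1.6, with
noise and a vignetting gain field in the rendered frames) is typical:
matched-SPF closure errors stay inside a few percent. Processing the same
two-term-SPF scenes with a single-term (forward-only) lookup table instead
reproduces the characteristic mismatch signature — the scattering error
pivots around the reference material's `mus'` (2.6 mm⁻¹ here):

```r
#> mus'=0.8 -> 1.130 (rel err +41.2%)
#> mus'=2.6 -> 2.606 (rel err  +0.2%)
#> mus'=5.0 -> 3.914 (rel err -21.7%)
```

## Analysis workflow

The `analysis/` scripts run the study end to end at desk scale, writing
tables under `results/`:

| script | what it does |
|---|---|
| `01_fit_phase_function.R` | synthetic goniometry → corrected scan → ttHG fit |
| `02_build_white_mc.R` | wMC records for the ttHG / stHG-Low / stHG-High models |
| `03_validate_forward_model.R` | wMC vs direct patterned simulation, 10 frequencies × 2 absorption ratios |
| `04_build_luts_and_invert.R` | inversion LUTs and forward→inverse round trips |
| `05_phantom_accuracy_study.R` | matched vs mismatched SPF × polarization error tables |

Run them in order with `Rscript analysis/01_fit_phase_function.R` etc.
(scripts 03–05 read the records written by 02).

## Method vignette

`vignettes/sfdi-methods.Rmd` documents the models, the numerical choices
(binning, quadrature, interpolation, roulette, filter construction), the
precision limits of the goniometric fit, and what the synthetic closure
tests do and do not demonstrate.
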