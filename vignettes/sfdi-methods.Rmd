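---
title: "Modelling diffuse and sub-diffuse SFDI: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling diffuse and sub-diffuse SFDI: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sfdiopt)
```

Spatial frequency domain imaging (SFDI) projects sinusoidal light patterns
onto a turbid sample and converts the frequency-dependent damping of the
reflected pattern into per-pixel maps of the absorption coefficient
$\mu_a$ and the reduced scattering coefficient $\mu_s' = \mu_s (1 - g_1)$.
In the diffuse regime (long wavelengths, low spatial frequencies) these
two coefficients suffice. At high spatial frequencies or strong
absorption, the reflectance is dominated by photons that scattered only a
few times — the *sub-diffuse* signal — and it becomes sensitive to the
full shape of the scattering phase function (SPF), in particular to any
backscatter lobe. This package implements the modelling stack needed to
study that sensitivity end to end, without hardware: phase-function
measurement reduction, Monte Carlo photon transport, a white Monte Carlo
(wMC) forward reflectance model, lookup-table inversion, demodulation, and
the accuracy bookkeeping that compares assumed phase functions and
polarization configurations.

## Phase functions

Two families are provided. The single-term Henyey–Greenstein (stHG)
density per steradian is

$$p(\cos\theta) = \frac{1}{4\pi}\frac{1 - g^2}{(1 + g^2 - 2 g \cos\theta)^{3/2}},$$

and the two-term variant (ttHG) is the mixture
$\alpha\,p_{g_f} + (1-\alpha)\,p_{g_b}$ with a forward lobe
$g_f \in [0, 1)$, a backward lobe $g_b \in (-1, 0]$ and forward fraction
$\alpha \in [0, 1]$. Its overall anisotropy is the closed form
$g_1 = \alpha g_f + (1-\alpha) g_b$. The ZnO-like default used throughout
the examples, `tthg_params(0.855, 0.983, 0)`, combines an extremely
forward-peaked lobe with a 14.5% isotropic backscatter fraction and has
$g_1 = 0.84$.

Monte Carlo sampling of an arbitrary SPF goes through a numerically
tabulated inverse CDF (`build_inverse_cdf()`): the density over
$\cos\theta$ is accumulated with the trapezoid rule on a $10^{-4}$-step
cosine grid and inverted by piecewise-linear interpolation onto a regular
CDF grid of step $\Delta c = 10^{-4}$. The trapezoid rule and linear
interpolation are our choices (the resolution is fixed by convention; the
quadrature and interpolation order are not), with $O(h^2)$ error —
the table agrees with the analytic stHG quantile function to better than
$10^{-4}$ in $\cos\theta$. CDF values outside the tabulated range clamp to
the table ends. Single-term HG deflections are drawn from the closed-form
quantile instead, which is exact.

## Goniometry reduction and lobe fitting

A goniometer records intensity versus detector angle; three distortions
stand between that scan and the SPF:

* **solid angle** — readings are normalized by the planar-disc aperture
  solid angle $\Omega = \pi (d/2)^2 / D^2$ (3.2 msr for the default
  8.2 mm aperture at 128 mm);
* **matrix background** — a clear (scatterer-free) sample's angular scan
  is subtracted and its total transmission divides the result; negative
  differences are floored at zero and flagged rather than dropped, so the
  angle grid stays intact;
* **refraction** — the scattering event happens inside a medium of index
  $n \approx 1.556$, so Snell's law maps the detector angle to the true
  scattering angle about the nearer surface normal. At 60° the correction
  exceeds 26°, compressing the usable angular range substantially.

The corrected scan is split at the instrument's occluded band: detector
angles in $(0°, 60°]$ form the forward section, $[120°, 170°]$ the
backward section. Each section is fitted by a scaled stHG lobe. Because
forward-scattering data spans orders of magnitude, each residual is
multiplied by the weight $\max(y)/y_i$, making the objective a sum of
squared *relative* deviations — the right treatment when noise is
proportional to signal. At fixed $g$ the scale has a closed-form weighted
least-squares solution, so the fit reduces to a one-dimensional search
over $g$, solved by a coarse grid scan plus golden-section refinement.
This replaces a bounded multistart trust-region search: for a
one-parameter profiled objective the grid-plus-golden-section scheme
cannot be trapped by a local minimum that the grid resolves, and it has no
tuning parameters.

Each lobe's tail leaks into the other section (for the ZnO-like SPF the
isotropic pedestal is a two-thirds contribution at the largest forward
angle), so `fit_goniometry()` alternates: fit the backward lobe, subtract
its pedestal from the forward section, fit the forward lobe, subtract its
tail, and repeat; the forward lobe is refit once more at the end so the
combined pair is mutually consistent. The forward fraction follows from
the fitted scales as $\alpha = s_f / (s_f + s_b)$.

**Precision limits.** The synthetic goniometry generator applies the
forward versions of all three distortions plus 2% multiplicative noise
(two mirrored ± sweeps are averaged, as the measurement protocol
suggests). A sensitivity analysis shows the backward anisotropy is barely
identifiable from this design: over the refraction-compressed backward
range, changing $g_b$ by 0.01 moves the stHG lobe by only about 0.5%,
below the effective noise. Likewise $\alpha$ amplifies small $g_f$ errors
roughly 25-fold. The seeded tests therefore verify that the pipeline is
unbiased and recovers the truth at the default seed; they should not be
read as instrument-grade uncertainty bounds, and across arbitrary seeds
the recovered $g_b$ can wander by several hundredths.

## Photon transport

The transport kernel (C++, deterministic xoshiro256++ RNG seeded from R)
simulates homogeneous media bounded by planes: a semi-infinite half-space
for pencil-beam white MC source runs, finite slabs for
reflectance/transmittance, and patterned sources with cyclic lateral
boundaries for direct SFDI simulation. Step lengths are exponential with
rate $\mu_t$, boundaries apply unpolarized Fresnel coefficients with
probabilistic reflection (the entering beam is attenuated by the normal-
incidence specular reflection), and absorption is handled by survival
weights: each interaction deposits $w\,\mu_a/\mu_t$ and multiplies the
weight by the albedo, which keeps the energy ledger exact. Time of flight
accumulates continuously as pathlength $\times n / c$; photons still in
flight at the 300 ns cap are dropped and counted. The geometry is
continuous (not voxelized): for a homogeneous medium a voxel grid adds
only discretization error.

**Path-stretching roulette.** In a non-absorbing half-space the
path-length distribution of returning photons has a $s^{-3/2}$ tail, so
analog simulation spends almost all its time on a handful of photons that
diffuse for metres before escaping (about $3\times10^4$ steps per photon
on average at the base properties). Photons whose path exceeds
$s_0$ (default 100 transport mean free paths) therefore pass unbiased
survival checkpoints at $s_0 2^k$: with probability 1/2 they are killed,
otherwise their weight doubles. Every expectation is unchanged, the
per-run ledger remains exact through an explicit net-roulette term, and
the early-path (sub-diffuse) region — everything below $s_0$ — is
untouched, at the cost of extra variance in the late diffuse tail. Exit
weights can therefore exceed 1 for rouletted photons; analog unit-weight
transport is available via `roulette_mfps = Inf`.

The direct SFDI simulation draws launch positions from
$\tfrac12(1 + \cos(2\pi f_x x + \phi))$ over a two-period cyclic domain
1 mm wide, with depth five times the spatial-frequency penetration depth
$\delta = 1/\sqrt{3\mu_a(\mu_a + \mu_s') + (2\pi f_x)^2}$ (our documented
choice of the standard expression; the depth rule itself is convention).
Exit profiles are binned at 25 bins per period and normalized to the mean
illumination, so three-phase demodulation of three such runs returns the
(DC, AC) reflectance pair directly. Because the domain depth follows the
AC penetration depth, the *DC* component of a shallow high-frequency
domain loses light through the bottom face; validation against the wMC
model therefore compares the AC reflectance at all frequencies but the DC
value only at the lowest frequency, where the domain is deep enough.

## White Monte Carlo forward model

A single pencil-beam run at base properties ($\mu_s' = 10$ mm$^{-1}$,
$\mu_a \approx 0$, $n = 1.56$) records every escaping photon's exit radius
and time of flight into a $750 \times 750$ histogram with logarithmically
spaced bin centers ($10^{-5}$–150 mm, $10^{-7}$–300 ns; edges at geometric
midpoints, out-of-range weight in guard counters). Log binning is what
makes the record simultaneously resolve the tens-of-micrometres,
hundreds-of-femtoseconds sub-diffuse structure and the diffuse tail — on
linear grids the same dynamic range would need $>10^6$ times as many
cells.

Rescaling to arbitrary properties uses the wMC identities: multiplying
$\mu_s'$ by $\beta$ scales radii and times by $1/\beta$, and absorption
attenuates each cell by the Beer–Lambert factor
$\exp(-\mu_a (c/n) t_{\text{scaled}})$. Summing over time gives the
spatially resolved reflectance; the order-zero Hankel transform
$R_d(f_x) = \sum_i r_d(\rho_i)\, J_0(2\pi f_x \rho_i)\, A_i$ (midpoint
quadrature over the log-spaced annuli, standard Bessel evaluation) gives
the spatial-frequency-domain reflectance. Against an analytic exponential
profile the quadrature is accurate to a few parts in $10^3$.

Inversion tables map a (DC, AC) reflectance pair at one frequency back to
$(\mu_a, \mu_s')$. The forward model is evaluated on a dense log-spaced
property grid ($120 \times 120$ over $10^{-4}$–10 and 0.1–10 mm$^{-1}$),
and the resulting surface is rasterized onto fixed log-spaced reflectance
grids (190 DC points over 0.001–0.9, 170 AC points over 0.001–0.7) by
splitting each forward-grid quad into two triangles and assigning
barycentric interpolates of $(\log\mu_a, \log\mu_s')$ to the reflectance
nodes inside. Nodes left uncovered, covered by folds of the surface whose
candidate properties disagree by more than 10% in log space (the
high-absorption region where DC and AC reflectance collapse toward each
other), or lying in the unphysical half-plane AC ≥ DC, are flagged
undetermined rather than extrapolated. Per-pixel inversion is bilinear in
log-reflectance/log-property coordinates; pixels hitting flagged nodes,
leaving the grid, or carrying AC ≥ DC (exactly, with no epsilon — noise
already produces the observed failures) become undetermined mask entries.

## Demodulation and calibration

Single-phase demodulation works in the 2D Fourier domain of one patterned
frame. Stops are flat-bottomed raised-cosine notches smoothed by a
Gaussian of one frequency-pixel standard deviation; the flat core (at
least three frequency bins) is what keeps the stopband closed after
smoothing. The DC image removes the ± AC peaks and harmonic pairs; the AC
image removes the DC peak, the negative AC peak and harmonics, keeps the
positive lobe and doubles the inverse-transform magnitude, so a cosine of
amplitude $a$ demodulates to exactly $a$. The anisotropic mode confines
the stops near the axis orthogonal to the modulation (narrow along it,
wide across it, default half-width $0.15 f_x$), which preserves image
detail when DC and AC peaks are closely spaced; the exact directional
parameterization is a documented default, not a reproduction of any
specific instrument's filters. Calibration is the per-pixel ratio
$R_d = (M / M_{\text{ref}}) R_{d,\text{ref,pred}}$, which cancels the
illumination profile and system transfer function; the reference
prediction must come from the *assumed* phase-function model — that choice
is precisely how an SPF mismatch propagates into the maps.

## Synthetic scenes and the accuracy study

The scene generator renders patterned frames as
$\text{exposure} \times \text{gain}(x,y) \times \tfrac12 (R_{DC} +
R_{AC}\cos(2\pi f_x x + \phi))$ plus Gaussian noise with variance
proportional to the signal (shot-like; cameras also add read noise and
fixed-pattern structure, which are not modelled). The default desk-scale
geometry is 250 × 60 pixels at 0.2 mm pitch, chosen so the pattern has an
integer period count (no windowing leakage) while keeping test runtimes
in seconds; the hardware-matched pitch (62 mm over 1440 pixels) is a
configuration away. The gain field is a smooth radial vignette, removed
exactly by calibration; exposure is divided out before demodulation.

Because vector (polarized) transport is out of scope, polarization enters
as a scene label selecting which SPF renders the scene: unpolarized
acquisitions retain the backscatter lobe (ttHG), cross-polarized ones
suppress it (forward stHG). Matched-model processing recovers properties
to better than 1% MAPE at desk scale; processing ttHG scenes with the
single-term model reproduces the characteristic pivot: scattering below
the reference value is overestimated, above it underestimated, with
near-zero error at the reference properties.

What passing these tests shows — and does not show. The generator draws
its reflectance from the same family of forward models used for
inversion, so closure tests verify the pipeline's internal consistency,
its noise robustness and the mismatch phenomenology; they cannot certify
accuracy on real tissue, where the SPF is unknown, surfaces are rough and
curved, and cameras deviate from the shot-noise model.

## Numerical and statistical conventions

* Monte Carlo tolerances are three combined standard errors, with SEs
  estimated from independent-seed batches; desk-scale photon budgets are
  $10^5$–$10^6$ for wMC records (the reflectance-difference check uses
  $10^6$ per model), $2$–$5\times10^4$ per direct-simulation phase and
  per inverse-MC objective evaluation.
* The inverse Monte Carlo property fit runs Nelder–Mead on
  square-root-transformed properties (nonnegativity with exact zeros
  attainable) with common random numbers — each objective evaluation
  reuses the same transport seed, making the stochastic objective
  effectively deterministic; initialization defaults to
  $(\mu_a, \mu_s') = (0.1, 1)$.
* ROI statistics use type-7 quantiles (linear interpolation between order
  statistics); the quantile convention is unstated in the field's
  descriptions and this is R's default. ROIs with more than 2%
  undetermined pixels are flagged omitted.
* Wavelength averaging weights retained channels equally after omissions.
* Speed of light is 299.792458 mm/ns divided by the medium index.
* Serialization is plain text (key-value headers with TSV/CSV bodies) for
  phase functions, inverse-CDF tables, goniometry scans, wMC records and
  LUTs.

## Known limitations

* The wMC record is built for one phase function and one refractive index
  pair; layered media and index gradients are out of scope.
* The LUT's flagged high-absorption fold is left undetermined; a
  regularized inversion could extend coverage at the cost of bias.
* The roulette trades late-tail variance for speed; total-reflectance
  estimates at exactly zero absorption are noisier than analog transport
  at equal photon counts.
* Sub-diffuse scattering-parameter estimation from many spatial
  frequencies (fitting backscatter parameters per pixel) is deliberately
  not implemented; the package studies the two-coefficient inversion.
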