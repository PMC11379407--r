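Package: sfdiopt
Title: Diffuse and Sub-Diffuse Spatial Frequency Domain Imaging Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Modelling stack for spatial frequency domain imaging (SFDI) of
    turbid media in both the diffuse and sub-diffuse regimes. Provides
    single- and two-term Henyey-Greenstein scattering phase functions with
    numerical inverse-CDF sampling, goniometry reduction and phase-function
    fitting with refraction correction, a seeded Monte Carlo photon
    transport kernel (pencil beam, slabs, sinusoidally patterned sources
    with cyclic boundaries), a log-binned white Monte Carlo forward
    reflectance model with order-zero Hankel transforms, lookup-table
    optical-property inversion, Fourier-domain single-phase demodulation,
    inverse Monte Carlo property fitting, synthetic phantom scene and
    goniometry generators, and the accuracy-assessment statistics used to
    compare phase-function and polarization pairings.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
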