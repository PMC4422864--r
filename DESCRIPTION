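Package: atlasmsi
Title: Atlas-Registered MALDI Mass Spectrometry Imaging Analysis
Version: 0.1.0
Authors@R: person("MSI", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An anatomy-driven analysis pipeline for MALDI mass spectrometry
    imaging (MSI) of coronal brain sections: per-pixel spectral preprocessing
    (Gaussian smoothing, TopHat morphological baseline subtraction, TIC
    normalization), cross-sample m/z alignment on common peaks, global
    base-peak-spectrum feature extraction into image cubes, affine plus
    B-spline registration of sections to a reference atlas, region-of-interest
    paired hemisphere statistics with Benjamini-Hochberg FDR control, and
    adduct/PTM mass annotation. Includes a synthetic phantom study generator
    (toy atlas, deformed sections, Poisson spectra with planted
    group-by-hemisphere effects) so the whole pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    xml2,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
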