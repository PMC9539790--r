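Package: corrfret
Title: Correlative STORM and HomoFRET Anisotropy Image Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for correlated single-molecule localization
    microscopy (STORM) and homoFRET fluorescence-anisotropy imaging of
    membrane proteins. Computes G-factor-corrected pixel-wise anisotropy
    maps from polarized TIRF image pairs, reconstructs super-resolved
    localization tables from blinking-movie stacks (maximum-likelihood
    Gaussian PSF fitting with Mortensen precision estimates, precision and
    photon filtering, sub-nanometre duplicate merging, cross-correlation
    drift correction), segments and classifies localization clusters by
    Voronoi tessellation into nanocluster, microcluster and diffuse
    populations, and registers the two modalities so each nanoscale
    cluster carries its pixel-wise self-association (anisotropy) value.
    A synthetic microscopy simulator (two-state blinking emitters, Poisson
    shot noise, Gaussian read noise, linear stage drift, known per-pixel
    anisotropy) provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deldir,
    igraph,
    RANN,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
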