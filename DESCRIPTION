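Package: kvdosim
Title: Monte Carlo Dosimetry for Kilovoltage X-Ray Cabinet Irradiators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Desk-scale dosimetry simulator for preclinical kilovoltage x-ray
    cabinet irradiators and Cs-137 gamma cabinets. Generates analytic tungsten
    tube spectra and beam-quality indices (half-value layer, air-kerma rate),
    carries an element photon cross-section table with mixture-rule material
    coefficients, builds voxelized slab/film/shield phantoms, transports
    photons through them with a kerma-approximation Monte Carlo (history-by-
    history statistics), converts simulation output to absolute dose via
    air-kerma reference calibration, applies analytic off-axis filter-path
    corrections, and evaluates 3D dose distributions (depth dose, lateral
    profiles, FWHM, DVH, dose-to-water conversion, structured reports).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
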