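Package: cardiofib
Title: Coupled Cardiomyocyte-Myofibroblast Electrophysiology and Optical-Map Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates electrotonic coupling between a rabbit ventricular
    cardiomyocyte (Mahajan 2008 ionic model) and passive cardiac
    myofibroblasts connected through ohmic gap junctions, to study how
    senescent (large-capacitance) myofibroblasts in the infarct border zone
    prolong action potential duration and promote conduction block. Includes
    Boltzmann current-voltage fitting of fibroblast voltage-clamp records,
    volumetric capacitance extrapolation from culture to tissue, pacing and
    S1S2 premature-stimulus protocols with APD and conduction-failure
    readouts, analysis of fluorescence voltage-mapping movies (temporal
    polynomial filtering, activation/repolarization detection, APD maps,
    conduction-velocity maps, dominant-frequency maps), and seeded synthetic
    data generators with known ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    minpack.lm,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
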