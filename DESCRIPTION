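Package: magnetoadrenal
Title: Magnetothermal Adrenal Stimulation Modeling and Analysis Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analyzing magnetothermal stimulation of
    the adrenal gland with magnetic nanoparticles (MNPs). Includes a
    finite-difference solver for the Pennes bio-heat equation on an
    ellipsoidal gland with a fat shell, used to verify that MNP injections
    reach the TRPV1 activation threshold (42 C); calorimetric estimation of
    nanoparticle specific loss power (SLP); and the downstream physiology
    pipeline: Kalman-smoothing imputation and gamma-GLM comparison of
    stimulation-evoked heart-rate responses, ELISA calibration-curve
    quantification with beta-tail outlier screening and log-ratio tests for
    serum corticosterone and epinephrine, beta regression of normalized
    fear-conditioning freezing behavior, and elliptical zone mapping of
    nanoparticle deposits in adrenal histology. A seeded synthetic-cohort
    generator emulates every input modality so the full pipeline runs
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Rcpp,
    minpack.lm,
    fitdistrplus,
    jsonlite,
    png,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
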