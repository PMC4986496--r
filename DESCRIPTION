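Package: voxcalc
Title: Fraction-by-Fraction Dose Reconstruction and Rectal Dose-Surface
    Mapping for Helical Tomotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the dose actually delivered in each radiotherapy
    fraction from daily megavoltage CT images and the recorded couch shifts
    and roll.  Masks the planning kilovoltage CT outside the megavoltage scan
    circle and sums water-equivalent radiological path lengths from two
    Siddon-style ray traces, converts Hounsfield units to relative electron
    density with date- and machine-dependent linear calibrations, computes
    per-fraction dose cubes from a helical plan sinogram with a documented
    simplified beamlet model, auto-segments the rectum on daily images with a
    Chan-Vese level set seeded from the planning contour, and accumulates
    rectal dose-surface maps and generalized equivalent uniform dose across
    fractions.  Includes synthetic phantom generators (density-insert
    calibration phantom, pelvis phantom with ground-truth rectum) so the
    whole pipeline runs end-to-end without clinical data, and a minimal
    batch orchestrator that splits work into per-fraction jobs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
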