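Package: arcqa
Title: Arc-Therapy Delivery Verification with Rolled-Film Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pre-treatment verification of volumetric modulated arc therapy
    (VMAT) deliveries from linac log files with experimental feedback from
    radiochromic film rolled in a cylindrical phantom. Parses and discretizes
    time-stamped delivery logs into control-point sequences, computes
    per-control-point dose contributions per monitor unit with a deterministic
    divergent-beam engine, extracts unrolled film-scroll dose images from 3D
    dose grids, models film calibration and multichannel dosimetry, compares
    dose distributions with percent-difference and gamma-index metrics, solves
    a constrained least-squares monitor-unit adjustment against the film and
    ionization-chamber measurements, and reconstructs the experimentally
    adjusted 3D dose and dose-volume histograms. Includes a seeded generator
    of end-to-end synthetic scenarios with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    quadprog,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
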