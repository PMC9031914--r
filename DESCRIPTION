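Package: leafgasx
Title: Leaf Gas-Exchange and Chlorophyll-Fluorescence Analysis for
    Photosynthesis Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing leaf-level photosynthesis measurements:
    correction of rapid A-Ci response (RACiR) traces against empty-chamber
    artifacts, bilinear Farquhar-von Caemmerer-Berry (FvCB) fitting of A-Ci
    curves (Vcmax, Jmax), estimation of the CO2 compensation point and day
    respiration by the Laisk low-light slope-intersection method, variable-J
    mesophyll conductance, four-parameter non-rectangular hyperbola
    light-response fitting, photorespiration partitioning from paired
    normal-air and low-oxygen light curves, chlorophyll-fluorescence
    quenching analysis (qP, qN, NPQ, calculated Fo', dark-assessed qPd) with
    photoprotection-threshold detection, and xanthophyll/chlorophyll pigment
    indices. Includes a forward FvCB + fluorescence simulator with known
    ground truth for validating every fitting step, and a pipeline that runs
    the full analysis on simulated or instrument-exported data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
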