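Package: gaitdtw
Title: Walkability Assessment from Wearable IMU Gait Signals with Dynamic
    Time Warping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how walking surfaces affect gait stability from a
    lumbar-mounted inertial measurement unit (IMU). Tri-axial accelerometer
    and gyroscope recordings are collapsed to signal vector magnitude
    series, low-pass filtered, z-normalized and segmented into gait cycles;
    each cycle is scored by its Dynamic Time Warping distance to a
    reference cycle of its flooring-material and age-group stratum, and
    scores are aggregated by material, 200 m walking-distance bin and age
    group with one-way ANOVA and descriptive distribution summaries. A
    seeded synthetic gait simulator emulates a full study cohort so the
    pipeline is testable end to end without hardware.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
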