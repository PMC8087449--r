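Package: cf0
Title: Consonantal F0 Perturbation Analysis from Glottal Pulse Marks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement pipeline for consonantal perturbation of fundamental
    frequency (CF0, microprosody). Reads Praat PointProcess pulse marks and
    TextGrid segmentations, computes cycle-wise F0 with voice-break detection,
    spike trimming with an edge-exemption rule and triangular smoothing,
    resamples contours onto segment-normalized time under several alignment
    schemes, and measures baseline-relative perturbation statistics (closure
    duration, onset F0, F0 jump, F0 elbow, elbow jump, offset F0, and a
    five-point vowel time course) against nasal-onset baseline contours.
    Includes a synthetic corpus generator with known ground-truth perturbation
    parameters for validating every stage by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
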