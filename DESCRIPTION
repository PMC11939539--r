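Package: ridgewidth
Title: Semi-Automated CBCT Measurement of Alveolar Ridge Width Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies alveolar ridge width change after tooth extraction
    from paired cone-beam CT (CBCT) scans. Reads DICOM series, standardizes
    grey depth to 8 bit, crops and rigidly aligns baseline and follow-up
    volumes, expands a single user-drawn crestal line into a 15-position
    measurement grid (five mesio-distal offsets at three depth planes),
    measures ridge width at each position as the distance between the two
    outermost grey-value profile maxima (the cortical rims), and computes
    longitudinal change tables together with the reproducibility statistics
    used in socket-preservation research (intraclass correlation
    coefficients, Bland-Altman limits of agreement, one-way ANOVA with Tukey
    HSD, and noncentral-t sample-size calculation). A synthetic socket
    phantom with known per-position widths and a programmable resorption
    gradient provides ground-truth fixtures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
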