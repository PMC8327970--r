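Package: flucasym
Title: Fluctuating Asymmetry Analysis of Replicated Bilateral Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of fluctuating asymmetry (FA) in
    replicated left/right morphometric measurements, developed around a
    study of dental asymmetry in wild olive baboons. Implements the
    balanced sides-by-individuals mixed-model ANOVA that partitions
    directional asymmetry, individual size variation, nondirectional
    asymmetry and measurement error; the FA1, FA4a and FA10a indices and
    the ME3 repeatability descriptor; the confounder screening battery
    (directional asymmetry via skew, antisymmetry via platykurtosis,
    trait-size dependency, Grubbs outliers) with variable-elimination
    rules; replicate-subset measurement-error scans; and Levene-type
    tests of FA-index variance across groups. A synthetic-data generator
    with known asymmetry and error structure supports calibration and
    parameter-recovery testing, and a bundled table of published FA10a
    index values from the baboon study supports reanalysis of its
    group-level hypothesis tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite
Config/testthat/edition: 3
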