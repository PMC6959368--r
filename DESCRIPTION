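Package: aggkinetics
Title: Amyloid Aggregation Kinetics: Integrated Rate Laws, Half-Time
    Scaling and Global Model Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the kinetic analysis of amyloid self-assembly
    monitored by thioflavin-T fluorescence, 19F-NMR signal decay or
    circular dichroism. Implements the integrated rate laws for unseeded
    aggregation with primary nucleation, fibril-end elongation and
    single-step or saturating (multi-step, Michaelis-type) secondary
    nucleation; sigmoidal half-time extraction from raw traces;
    half-time versus monomer-concentration scaling (the exponent gamma);
    and global multi-concentration fitting with chi-squared model
    comparison. Includes seeded synthetic-data generators for plate-reader,
    19F-NMR and two-state CD experiments, and a small sequence toolbox
    (charge profiles, pairwise identity, Poisson-corrected distances,
    Neighbor-Joining trees) for solubility-tag engineering work.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
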