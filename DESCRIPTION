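Package: pkaprozone
Title: Prozone Equilibrium Model and Single-Cell Image Analysis for
    Induced Membrane PKA Translocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and analysis tools for experiments in which the
    regulatory subunit of protein kinase A (PKA-R) is acutely recruited to
    the plasma membrane by rapamycin-induced FKBP-FRB dimerization.
    Implements a six-microstate partition-function model of the membrane
    PKA compartment in which PKA-R acts as a bivalent linker of catalytic
    subunits and cAMP, producing a biphasic ("prozone") dependence of
    kinase activity on PKA-R abundance; dose-dependent translocation
    kinetics; a one-dimensional source-sink diffusion model of a
    microfluidic gradient device; single-cell image-analysis procedures
    for ratiometric FRET biosensors (threshold segmentation,
    dark-frame-corrected emission ratios, eroded-mask cytoplasmic
    intensity tracking, nuclear-centroid migration tracking, binned
    intracellular activity profiles, population statistics); and a seeded
    synthetic-microscopy generator with ground truth so that every
    analysis stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
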