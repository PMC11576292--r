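Package: mitoscreen
Title: Screening Mitochondrial Membrane Potential Dynamics of Microglia in
    Time-Lapse Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying mitochondrial membrane potential dynamics of
    microglia in two-channel (EGFP morphology / TMRE potentiometric) time-lapse
    recordings of acute brain slices. Provides a seeded synthetic-data generator
    that emulates the progressive three-state depolarization response of
    microglia to lipopolysaccharide and its pharmacological attenuation,
    morphology-channel segmentation of microglia into soma, branch and endfoot
    compartments, percent-change and rate-of-change trace kinetics with
    plateau-separated state detection, and the group-comparison statistics used
    to screen treatment effects per compartment and state.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
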