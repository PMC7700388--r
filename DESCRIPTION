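Package: memorient
Title: Orientation-State and Membrane-Structure Analysis for Peripheral
    Membrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory analysis for peripheral membrane proteins anchored to
    lipid bilayers, built around the orientation-state framework used for
    lipidated small GTPases such as KRas-4B. Provides readers and writers for
    multi-frame GRO and multi-model PDB coordinates, periodic minimum-image
    geometry, Kabsch superposition and RMSD, bilayer structural metrics (area
    per lipid, thickness, block-averaged errors), moiety insertion-depth
    profiles, radial distribution functions, orientation order parameters
    (z, Theta, Phi), two-dimensional conformational density maps with
    orientation-state classification, and a ground-truthed synthetic
    bilayer plus protein trajectory generator for validating every stage of
    the pipeline without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
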