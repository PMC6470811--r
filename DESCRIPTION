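Package: ptfluct
Title: Pressure and Temperature Effects on Protein Atomic Fluctuations
    from Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory analysis for quantifying how hydrostatic pressure and
    temperature change the internal dynamics of solvated proteins in molecular
    dynamics simulations. Computes block-averaged atomic mean-square
    fluctuations, the apparent protein volume per heavy atom from box-volume
    statistics and a pure-solvent reference, interior-water counts under a
    two-distance geometric rule, geometric hydrogen-bond populations and
    continuous-event lifetimes with pair-averaged summaries, the inverse
    fluctuation versus log-lifetime correlation dataset, and cross-condition
    comparison tables of percent and absolute changes. Includes synthetic
    trajectory generators (Ornstein-Uhlenbeck pseudo-proteins, telegraph
    hydrogen-bond occupancies, planted solvated scenes, Gaussian volume
    series) with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
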