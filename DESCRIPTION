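Package: smaggr
Title: Small-Molecule Aggregation Trajectory Analysis and Inhibition Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of molecular-dynamics trajectories of
    self-assembling small molecules (metabolite amyloids) and analysis of
    their inhibition by chemical chaperones. Detects center-of-mass
    contacts under periodic boundary conditions, extracts aggregates as
    connected components of the contact graph, computes pi-stacking angle
    distributions from least-squares ring planes, and measures geometric
    hydrogen-bond occupancy over combined metatrajectories. Fits sigmoidal
    Thioflavin-T aggregation kinetics, computes endpoint percent
    inhibition and the relative-concentration potency statistic (mM per 1%
    inhibition), and associates physicochemical descriptors with potency
    by rank correlation. Includes a synthetic trajectory and kinetics
    generator with recorded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    igraph,
    jsonlite,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
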