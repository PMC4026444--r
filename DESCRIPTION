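Package: FtDsPolarity
Title: Kinetic Modelling of Fat-Dachsous Planar Cell Polarity in a Cell Row
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic ODE model of the Fat (Ft), Dachsous (Ds) and
    Four-jointed (Fj) planar-cell-polarity module in a one-dimensional row
    of epithelial cells. Fj kinase activity, graded along the
    proximo-distal axis, phosphorylates Ft and Ds via Hill-function
    coupling; phosphorylated Ft binds unphosphorylated Ds of the
    neighbouring cell by mass action to form the intercellular Ft-Ds
    heterodimer. The package integrates the phosphorylation and edge
    heterodimer kinetics by an explicit forward-difference scheme, provides
    closed-form steady states and relaxation solutions, decomposes the
    steady-state sub-cellular asymmetry of the heterodimer into Ft- and
    Ds-polarity terms with a tunable weight factor, and runs a panel of
    in-silico perturbations (gradient flattening, kinase-dead mutants,
    weight-factor and parameter sweeps) with tabular, JSON and
    trapezoid-plot output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    ggplot2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'synthetic-data.R'
    'config.R'
    'model-core.R'
    'dynamics.R'
    'heterodimer.R'
    'experiments.R'
    'io.R'
    'plot.R'
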