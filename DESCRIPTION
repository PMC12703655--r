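Package: PoreFlux
Title: Selectivity-Filter Occupancy and Ion Permeation Analysis for
    Channel Trajectories
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-processing of molecular simulation trajectories of
    tetrameric potassium-channel pores. Defines the pore axis and the
    selectivity-filter ion binding sites (S1-S4, Scav) from the TVGYG
    backbone oxygens, assigns ions and water to sites per frame, encodes
    filter occupancy as four-letter state strings, labels frames by
    divalent-cation binding below the filter (F87 site, E92 glutamate
    ring), counts complete permeation events under an applied electric
    field and converts them to single-channel currents, and computes
    axial density profiles, gate distances and RMSD/RMSF flexibility
    metrics. Includes a continuous-time kinetic Monte Carlo generator of
    voltage-biased single-file ion-hopping trajectories with exact
    ground-truth logs, plus an exact stationary-distribution solver used
    as a validation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'PoreFlux-package.R'
    'kinetic-params.R'
    'trajectory-io.R'
    'kinetic-sim.R'
    'pore-model.R'
    'occupancy.R'
    'permeation.R'
    'profiles.R'
    'pipeline.R'
    'stationary.R'
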