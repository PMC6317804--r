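Package: PharmSafe3D
Title: Pharmacophore-Based 3D QSAR Modeling and Virtual Screening for
    Safety Pharmacology Profiling
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Ligand-based safety-profiling workflow for liability targets:
    common-pharmacophore hypothesis perception from active and inactive
    ligands, atom-based partial-least-squares QSAR on binary cube-occupancy
    descriptors, virtual screening with activity-threshold hit calling, and
    similarity-stratified interpretation of predictions. Includes bounded 3D
    conformer-ensemble preparation, typed pharmacophore site perception from
    editable SMARTS feature tables, radial fingerprints with Tanimoto
    similarity, leader clustering, train/test split strategies, confusion
    statistics, and a synthetic-data generator with planted pharmacophore
    geometries for fully self-contained validation. Chemistry primitives
    (SMILES parsing, conformer embedding, substructure matching,
    fingerprints) are delegated to RDKit through a bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on
    the PATH.
Config/testthat/edition: 3
RoxygenNote: 7.3.3
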