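Package: ShiftGNN
Title: 3D Graph Neural Networks for NMR Chemical Shift Prediction and
    Structure Elucidation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts per-atom 1H and 13C NMR chemical shifts from 3D
    molecular geometries with a message-passing graph neural network that
    uses radial-basis-expanded interatomic distances as continuous edge
    features and iterates edge-update, message-passing and node-update
    blocks. Supports the full surrounding workflow: reading SDF/SMILES/XYZ
    structures, shielding-to-shift empirical scaling, interquartile-range
    cleaning of paired computed/experimental shift tables, diversity
    sampling by farthest-neighbour selection on molecular fingerprints,
    two-stage transfer learning with parameter-group freezing,
    Boltzmann-weighted conformer-ensemble predictions, and structure
    elucidation by sorted-shift matching with misassignment detection and
    optimal reassignment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ChemmineR
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (obabel, obenergy) for SMILES input and
    conformer generation; not needed for SDF/XYZ workflows.
Config/testthat/edition: 3
biocViews: Cheminformatics, MachineLearning, Metabolomics
RoxygenNote: 7.3.3
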