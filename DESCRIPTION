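Package: cryoforge
Title: Voxel Labeling, Validation and HMM-Guided Backbone Tracing for
    Cryo-EM Density Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn a cryo-EM density volume plus an atomic model
    into standardized, voxel-labeled training data, and to turn per-voxel
    C-alpha and amino-acid probability volumes plus a protein sequence
    into a traced backbone model. Includes MRC2014 reading, writing and
    header validation; resampling to a uniform 1 Angstrom grid and
    percentile normalization into [0, 1]; four voxel labeling schemes
    (backbone atoms, C-alpha, amino-acid type, secondary structure) with
    coordinate/index round-trip verification; overlapping 32-voxel
    sub-grid tiling with central-core stitching; a hidden Markov model
    over candidate C-alpha voxels decoded by an injective beam Viterbi;
    chain-comparison metrics (RMSD, matching percentage, sequence
    identity); and a synthetic-data generator so every stage is testable
    without experimental maps or trained predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
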