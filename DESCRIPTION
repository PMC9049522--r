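Package: thermonet
Title: Stimulus-Driven and Resting-State fMRI Network Analysis with
    Synthetic BOLD Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for thermal-stimulation rodent fMRI studies:
    pseudo-randomized thermal stimulation protocols, a two-gamma rat
    hemodynamic response function, voxel-wise GLM with Benjamini-Hochberg
    FDR masking, atlas-ROI response metrics (activated volume, event-related
    time courses, response amplitudes, voxel-wise maximum-amplitude maps),
    graph-theoretical network construction (global regression, Fisher-z
    adjacency, k-standardization, small-world indices, Louvain communities),
    multi-seed resting-state connectivity, and permutation-based group
    statistics (network-based statistic, paired max-T tests, ANOVA with
    Tukey HSD). Ships a synthetic-phantom generator (atlases, 4D BOLD
    series with AR(1) noise, drift and planted effects) so the whole chain
    runs end-to-end without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
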