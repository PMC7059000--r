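Package: parcelfc
Title: Connectivity-Based Seed Parcellation and Group Resting-State
    Functional Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for connectivity-based parcellation of a seed region
    into functional subregions from resting-state BOLD fMRI, and for
    seed-based group functional-connectivity comparisons between a
    patient and a control cohort.  Includes a self-contained synthetic
    BOLD cohort generator with planted subregion and network structure,
    a volumetric preprocessing chain (volume discard, motion screening,
    framewise displacement, nuisance regression, band-pass filtering,
    Gaussian smoothing, left-right flipping), spectral clustering of
    connectivity profiles with maximum-probability-map aggregation, and
    voxel-wise group inference with false-discovery-rate and
    Monte-Carlo cluster-extent correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
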