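Package: scenersa
Title: Representational Similarity Analysis of Reinstated and Transformed
    Scene Memories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multivoxel representational similarity analysis (RSA)
    of episodic memory experiments in which objects are encoded against a
    small set of recurring scenes that carry high or low reward. The package
    computes encoding-retrieval similarity (reinstatement of scene-specific
    encoding patterns) and retrieval-retrieval similarity (convergence of
    retrieval patterns onto shared, transformed representations), applies
    the pair-exclusion rules appropriate to such designs, and performs
    group-level inference via contrast-score repeated-measures ANOVAs,
    within-subject label-permutation z-scores, and searchlight mapping with
    sign-flip max-statistic family-wise error control. A synthetic-data
    generator produces trial designs, behavioral outcomes, trial-wise voxel
    patterns and BOLD time series with planted reinstatement and convergence
    effects, so that every stage of the pipeline is verifiable without
    access to scanner data. Single-trial beta-series GLM estimation with a
    canonical double-gamma hemodynamic response is included for producing
    trial-wise t-maps from 4D volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
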