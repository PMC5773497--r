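Package: subfieldRSA
Title: Pattern-Similarity Analysis of Episodic and Spatial Context Coding
    in Hippocampal Subfields
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and inference pipeline for multivoxel
    pattern-similarity (representational similarity) analyses of
    hippocampal subfield data. Generates a two-house, twenty-video
    episodic/spatial encoding design with a four-run recognition test,
    simulates recognition behavior and trial-wise voxel patterns under
    integrative (pattern-completion-like), separative
    (pattern-separation-like) or null context-coding regimes, estimates
    single-trial betas with a two-regressor least-squares-single (LSS)
    GLM, builds between-run trial-pair Pearson similarity tables
    restricted to correctly recollected trials with correct spatial
    source memory, and tests context-coding effects with random-intercept
    linear mixed models compared by chi-squared likelihood-ratio tests.
    Includes trial-count-matched subsampling, influential-voxel dropping,
    and reaction-time covariate control analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    lme4,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
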