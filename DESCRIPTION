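Package: matecomp
Title: Male Quality and Male-Female Compatibility Across Episodes of Sexual Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference pipeline for partitioning reproductive
    outcomes in Drosophila melanogaster between intrinsic male genetic quality
    and male-female genotypic compatibility. Provides a synthetic diallel-cross
    generator with known additive, female, and interaction effects; composite
    fitness indices (combination-level compatibility w_ij, male quality w_i,
    female quality w_j) built from range-standardized trait means, David's
    scores and competitive paternity; stratified bootstrap confidence
    intervals; repeated-measures and bootstrapped Spearman correlations;
    selection of contrasting genotypes and enumeration of simultaneous and
    sequential competitive-mating rosters; and the mixed-model inference chain
    for mating success, sperm-ejection latency, relative sperm storage (S2),
    second-male paternity (P2), and post-remating offspring rate, including
    likelihood-ratio backward simplification and additive/nonadditive variance
    partitioning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmtest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
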