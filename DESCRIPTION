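Package: mrdoptim
Title: Adaptive Per-Region Parameter Optimization for Low-VAF ctDNA
    Variant Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Self-adaptive, per-genomic-region parameter optimization for
    two-stage (calling plus filtering) detection of very low variant
    allele frequency somatic mutations in circulating tumor DNA, as used
    for minimal-residual-disease monitoring. The detection pipeline is
    treated as a black box whose false-positive and false-negative rates
    form black-box constraints: an alternating direction method of
    multipliers (ADMM) loop decouples the gradient-free objective from
    the constraints, Bayesian optimization solves the optimality
    subproblem over a mixed discrete/continuous parameter space, a deep
    Q-learning agent adapts the constraint thresholds between rounds,
    and a small convolutional meta-model learns to recommend parameter
    configurations for new regions from region-level meta-features.
    Includes a cohort simulator emulating heterogeneous panel sequencing
    so the whole framework is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lhs,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
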