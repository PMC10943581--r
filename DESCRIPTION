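Package: ratioqtl
Title: Ratio Phenotype QTL Discovery with the P-Gain Statistic
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide association analysis of ratios between
    log-scale protein abundances (NPX-style), including shrinkage partial
    correlation networks to select candidate protein pairs, covariate-adjusted
    linear-model association with log-space p-values that remain accurate for
    astronomically small p, the p-gain statistic with Bonferroni calibration,
    discovery/replication workflows, distance-based signal pruning, cis/trans
    and novelty annotation, protein-interaction enrichment by resampling, and
    a synthetic-cohort generator implementing the underlying linear generative
    model so the whole pipeline can be exercised and validated without access
    to controlled biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
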