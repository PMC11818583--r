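Package: lipidAMOPLS
Title: ANOVA Multiblock Orthogonal PLS for Designed Lipidomics Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical analysis of untargeted lipidomics feature tables from
    two-factor designed experiments. Implements feature-quality filtering
    (missingness against blank signal, pooled-QC intensity and CV, zero IQR),
    probabilistic quotient normalization against the median pooled-QC
    spectrum, half-minimum imputation and unit-variance scaling; balanced
    two-way ANOVA decomposition of the data matrix into pure effect matrices
    with sum-of-squares shares; ANOVA multiblock orthogonal partial least
    squares (AMOPLS) on the effect blocks with block contributions, explained
    variance and permutation-based significance and model-dimension selection;
    and descriptive lipid-signature reporting (class compositions, log2 fold
    changes, chain-length shift tables). Includes a synthetic-data generator
    producing factorial lipidomics tables with known ground-truth effect
    structure, and a lipid shorthand-nomenclature parser.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
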