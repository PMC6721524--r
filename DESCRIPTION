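Package: plasmaZ
Title: Untargeted Plasma Tumor-Fraction Analysis via Chromosome-Arm
    Aneuploidy Z-Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for untargeted cell-free DNA
    (cfDNA) tumor-fraction assessment in liquid biopsies.  Implements the
    mFAST-SeqS chromosome-arm aneuploidy statistic (per-arm z-scores against
    a healthy reference panel, genome-wide z-score as the standardized sum
    of squared arm z-scores), a simplified grid-search tumor-fraction
    estimator from binned log2 copy-number ratios, a synthetic-data
    generator with known ground truth (Dirichlet-multinomial arm counts,
    diploid/tumor mixtures, longitudinal cohorts with survival and
    co-biomarkers), and the accompanying clinical statistics layer
    (Kaplan-Meier and log-rank with cutoff scan, Cox proportional hazards,
    random-intercept linear mixed models for serial scores, Spearman
    correlation matrices and exact contingency-table tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    nlme,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
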