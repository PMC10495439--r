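Package: pdl1ps
Title: Context-Dependent Predictiveness of PD-L1 for Immunotherapy Benefit
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how well PD-L1 expression predicts benefit from
    immune checkpoint inhibition and discovers transcriptomic modulators of
    that predictiveness. Implements the hazard-ratio-difference (HRD)
    statistic from DerSimonian-Laird random-effects pooling of trial-level
    subgroup hazard ratios, a cross-cancer Spearman screen of candidate
    genes against HRD, Cox proportional-hazards interaction ranking within
    treated cohorts, a linear predictiveness score with leave-one-out
    cross-validation that splits patients into Predictiveness-High and
    Predictiveness-Low groups, biomarker-stratified efficacy grids
    (hazard ratios, log-rank tests, objective response rates with
    Clopper-Pearson intervals and Fisher's exact tests), tumor
    microenvironment profiling (quantile normalization, mean-expression
    immune signatures, resampled hierarchical consensus clustering), and a
    synthetic-data generator with planted interaction effects for
    end-to-end parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    limma,
    fgsea,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
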