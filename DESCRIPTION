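Package: pulmolip
Title: Lung Tissue Lipidomics: Quantification, Panel Scoring and PLS Phenotype Regression
Version: 0.1.0
Authors@R: person("Pulmolip", "Maintainers", email = "maintainers@pulmolip.org", role = c("aut", "cre"))
Description: Analysis pipeline for shotgun-lipidomics screens of lung tissue:
    parsing of sum-composition lipid nomenclature, identification filtering by
    mass accuracy and blank ratio, internal-standard quantification, mol%
    normalization and presence filtering; selection of discriminative lipid
    panels with a signed log2 mean-centred score evaluated by ROC/AUC and the
    Mann-Whitney U test; hierarchical clustering and PCA of lipid profiles;
    NIPALS PLS2 regression of lipid predictors against histology scores and
    clinical covariates with patient-grouped 10-segment cross-validation and
    the Q2 >= 0.0975 significance rule; and a synthetic-cohort generator that
    reproduces the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
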