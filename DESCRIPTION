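Package: sdscore
Title: Structural Disruption Scores for Missense Variant Prioritization
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes sequence- and structure-derived residue features for
    missense variants (Grantham physico-chemical distance, deleteriousness and
    conservation call counts, relative solvent accessibility by Shrake-Rupley
    surface integration, stabilization-center contacts, stability and
    flexibility categorization), tests feature enrichment in known causal
    versus neutral variants with one-tailed Fisher's exact tests, aggregates
    deleterious-direction features into a 0-7 structural disruption score
    (SDS) per variant, and emits a ranked, filtered priority list. Includes a
    synthetic cohort and toy structure generator so the whole pipeline is
    testable without external predictors or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: VariantAnnotation, StructuralPrediction, Software
RoxygenNote: 7.3.3
Collate:
    'aa-data.R'
    'AllGenerics.R'
    'AllClasses.R'
    'grantham.R'
    'seqfeat.R'
    'peptide.R'
    'sasa.R'
    'structfeat.R'
    'enrichment.R'
    'sds.R'
    'synthetic.R'
    'io.R'
    'pipeline.R'
    'sdscore-package.R'
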