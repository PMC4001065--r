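# End-to-end convenience layer: annotation of derived columns, the full
# enrichment + scoring pipeline, and the bundled worked-example cohort.

#' Append derived feature columns to a cohort
#'
#' Adds per-variant derived measures to the annotation table: Grantham
#' distance, deleterious/conservation counts and coverage, Gly/Pro change,
#' burial class, secondary-structure group, stability, optimality,
#' dynamics and flexibility classes. Missing upstream annotations yield
#' missing derived values.
#'
#' @param cohort a \linkS4class{VariantCohort}.
#' @param config a \linkS4class{ThresholdConfig}.
#' @return the cohort with appended columns.
#' @export
annotateFeatures <- function(cohort, config = thresholdConfig()) {
  stopifnot(is(cohort, "VariantCohort"))
  v <- variantData(cohort)
  ann <- as.data.frame(v)
  dc <- deleteriousCount(ann)
  cc <- conservationCount(ann)
  v$grantham <- granthamDistance(ann$ref_aa, ann$alt_aa)
  v$del_count <- dc$count
  v$del_calls_available <- dc$n_calls
  v$cons_count <- cc$count
  v$gly_pro_change <- isGlyProChange(ann$ref_aa, ann$alt_aa)
  if ("rsa_percent" %in% colnames(ann))
    v$burial_class <- classifyBurial(ann$rsa_percent, config)
  if ("ss_code" %in% colnames(ann))
    v$ss_group <- groupSecondaryStructure(ann$ss_code)
  if ("ddg" %in% colnames(ann))
    v$stability_class <- classifyStability(ann$ddg, config)
  if ("gamma" %in% colnames(ann))
    v$optimality_class <- classifyOptimality(ann$gamma, config)
  dyn <- classifyDynamicsFlexibility(ann, config)
  v$dynamics_class_b <- dyn$dynamics_class_b
  v$dynamics_class_rmsf <- dyn$dynamics_class_rmsf
  v$flexibility_class <- dyn$flexibility_class
  initialize(cohort, variants = v)
}

#' Run the full prioritization pipeline
#'
#' Convenience wrapper chaining the stages: feature-vector construction,
#' enrichment testing of positive vs negative controls (when both classes
#' are present), scoring, priority filtering, tolerance partition,
#' flexible-site exclusion and final-priority assembly.
#'
#' The score is always computed over the canonical seven features; the
#' enrichment-selected set is reported alongside and does not change the
#' score.
#'
#' @param cohort a \linkS4class{VariantCohort}.
#' @param config a \linkS4class{ThresholdConfig}.
#' @param alpha per-feature significance level for enrichment.
#' @return list with \code{results} (\linkS4class{SdsResults}),
#'   \code{enrichment} (data.frame or NULL) and \code{selected} (list or
#'   NULL).
#' @export
runSdsPipeline <- function(cohort, config = thresholdConfig(),
                           alpha = config@alpha) {
  stopifnot(is(cohort, "VariantCohort"))
  cls <- as.character(classLabels(cohort))
  enrichment <- NULL
  selected <- NULL
  if (any(cls == "positive") && any(cls == "negative")) {
    fv <- buildFeatureVectors(cohort, config)
    enrichment <- featureEnrichment(fv, cls, alpha = alpha)
    selected <- selectDeleteriousFeatures(enrichment, alpha = alpha)
  }
  results <- scoreVariants(cohort, config)
  list(results = results, enrichment = enrichment, selected = selected)
}

#' Bundled worked-example cohort
#'
#' Loads the small annotation table shipped with the package: 14 candidate
#' missense case variants with precomputed predictor counts, RSA, ddG,
#' patch/domain membership, gene-level RVIS, a flexible-site percentile
#' and a literature-curation column. Re-scoring it demonstrates the whole
#' priority-list construction: all 14 variants reach the priority
#' threshold, 9 lie in high-tolerance genes and 5 in low-tolerance genes,
#' one high-tolerance variant is excluded for altering a highly flexible
#' site, and one low-tolerance variant is curated in, leaving 9 final
#' priority variants.
#'
#' @return a \linkS4class{VariantCohort} with 14 rows.
#' @examples
#' cohort <- workedExampleCohort()
#' sds(scoreVariants(cohort))
#' @export
workedExampleCohort <- function() {
  path <- system.file("extdata", "example_cohort.tsv", package = "sdscore",
                      mustWork = TRUE)
  readVariantTable(path)
}
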