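# Structural disruption score construction: the seven-flag feature vector,
# the 0-7 score, the priority filter, the gene-tolerance partition, the
# flexible-site exclusion, and the final priority list.

#' Build the feature flag vectors for a cohort
#'
#' Computes the seven deleterious-direction flags (high deleterious count,
#' large Grantham change, Gly/Pro change, buried site, protein patch,
#' protein domain, destabilizing) and the neutral-direction flags (highly
#' flexible site, highly dynamic site, fully conserved) for every variant.
#' All thresholds are boundary-inclusive. Flags whose upstream annotation
#' is missing come out \code{NA} (missing, not FALSE).
#'
#' The flexible/dynamic-site flags use empirical tail cutoffs derived from
#' the pooled values of all rows given here, falling back to the fixed
#' cutoffs in \code{config} when too few values are present.
#'
#' @param cohort a \linkS4class{VariantCohort} (or annotation data.frame
#'   including ref_aa/alt_aa columns).
#' @param config a \linkS4class{ThresholdConfig}.
#' @return data.frame of logical flag columns plus
#'   \code{n_missing_features} (count of NA deleterious-direction flags)
#'   and \code{del_count}/\code{cons_count} helper columns.
#' @export
buildFeatureVectors <- function(cohort, config = thresholdConfig()) {
  ann <- if (is(cohort, "VariantCohort")) variantData(cohort) else cohort
  ann <- as.data.frame(ann)
  n <- nrow(ann)
  col <- function(nm, mode = NA_real_) {
    if (nm %in% colnames(ann)) ann[[nm]] else rep(mode, n)
  }
  dc <- deleteriousCount(ann)
  cc <- conservationCount(ann)
  gr <- granthamDistance(ann$ref_aa, ann$alt_aa)
  asLogical <- function(x) {
    if (is.logical(x)) return(x)
    if (is.numeric(x)) return(x != 0)
    tolower(as.character(x)) %in% c("true", "yes", "1") |
      ifelse(is.na(x), NA, FALSE)
  }
  dyn <- classifyDynamicsFlexibility(ann, config)
  flexFlag <- dyn$flexibility_class == "conformationally_flexible"
  if ("flex_percentile" %in% colnames(ann)) {
    # precomputed pooled percentile of P(Flexible), 0-100 scale
    pct <- ann$flex_percentile
    flexFlag <- ifelse(is.na(pct), flexFlag, pct >= config@pflexTails[2])
  }
  fv <- data.frame(
    high_del_count = dc$count >= config@delCountMin,
    large_grantham = gr >= config@granthamMin,
    gly_pro_change = isGlyProChange(ann$ref_aa, ann$alt_aa),
    buried = col("rsa_percent") <= config@rsaBuriedMax,
    on_patch = asLogical(col("on_patch", NA)),
    in_domain = asLogical(col("in_domain", NA)),
    destabilizing = col("ddg") >= config@ddgNoChangeBand[2],
    highly_flexible_site = flexFlag,
    highly_dynamic_site = dyn$dynamics_class_b == "highly_dynamic",
    fully_conserved = cc$count == 3L
  )
  fv$n_missing_features <-
    as.integer(rowSums(is.na(fv[, .DELETERIOUS_FEATURES])))
  fv$del_count <- dc$count
  fv$cons_count <- cc$count
  attr(fv, "cutoffs") <- attr(dyn, "cutoffs")
  fv
}

#' Structural disruption score from feature flags
#'
#' The score is the number of TRUE deleterious-direction flags (0-7);
#' missing flags contribute nothing but are tallied separately.
#'
#' @param fv data.frame of flags as built by
#'   \code{\link{buildFeatureVectors}} (only the seven canonical columns
#'   are used; absent columns count as missing).
#' @return integer vector of scores.
#' @examples
#' fv <- data.frame(high_del_count = TRUE, large_grantham = TRUE,
#'                  buried = TRUE, in_domain = TRUE, destabilizing = TRUE)
#' computeSds(fv)  # 5
#' @export
computeSds <- function(fv) {
  fv <- as.data.frame(fv)
  have <- intersect(.DELETERIOUS_FEATURES, colnames(fv))
  if (!length(have)) return(rep(0L, nrow(fv)))
  as.integer(rowSums(fv[, have, drop = FALSE] == TRUE, na.rm = TRUE))
}

#' Partition variants by gene tolerance (RVIS)
#'
#' Genes with positive residual variation intolerance score carry more
#' common variation than expected (tolerant, "high"), negative scores mark
#' intolerant genes ("low"). An RVIS of exactly zero means "as expected"
#' and is classed high (logged when triggered); missing RVIS gives
#' \code{unknown}.
#'
#' @param rvis numeric vector of gene-level RVIS values.
#' @return factor with levels \code{high}, \code{low}, \code{unknown}.
#' @export
partitionByTolerance <- function(rvis) {
  out <- rep("unknown", length(rvis))
  out[!is.na(rvis) & rvis > 0] <- "high"
  out[!is.na(rvis) & rvis < 0] <- "low"
  zero <- !is.na(rvis) & rvis == 0
  if (any(zero)) {
    message(sprintf("partitionByTolerance: %d gene(s) with RVIS = 0 classed high (as-expected tie-break)",
                    sum(zero)))
    out[zero] <- "high"
  }
  factor(out, levels = c("high", "low", "unknown"))
}

#' Score a cohort and assemble the priority list
#'
#' Runs the whole scoring stage: builds the feature vectors, computes the
#' structural disruption score, applies the priority filter (score >=
#' \code{sdsPriorityMin}), partitions by gene tolerance, applies the
#' neutral-compatible exclusion (a priority variant altering a highly
#' flexible site is disregarded), and finalizes the priority list: a
#' variant is final priority when it is priority and not excluded and in a
#' high-tolerance gene, or priority in a low-tolerance gene whose curation
#' column says \code{likely}.
#'
#' @param cohort a \linkS4class{VariantCohort}.
#' @param config a \linkS4class{ThresholdConfig}.
#' @return an \linkS4class{SdsResults} object (original row order).
#' @export
scoreVariants <- function(cohort, config = thresholdConfig()) {
  stopifnot(is(cohort, "VariantCohort"))
  v <- variantData(cohort)
  fv <- buildFeatureVectors(cohort, config)
  sdsv <- computeSds(fv)
  priority <- sdsv >= config@sdsPriorityMin
  rvis <- if ("rvis" %in% colnames(v)) v$rvis else rep(NA_real_, nrow(v))
  tol <- partitionByTolerance(rvis)
  flex <- fv$highly_flexible_site
  excluded <- priority & !is.na(flex) & flex
  cur <- if ("epilepsy_curation" %in% colnames(v)) {
    tolower(as.character(v$epilepsy_curation))
  } else {
    message("scoreVariants: no curation column; low-tolerance branch contributes nothing to the final list")
    rep(NA_character_, nrow(v))
  }
  final <- (priority & !excluded & tol == "high") |
           (priority & tol == "low" & !is.na(cur) & cur == "likely")
  tb <- S4Vectors::DataFrame(
    v[, intersect(c(.REQUIRED_VARIANT_COLS, "nucleotide_change",
                    "rvis", "composite_score", "epilepsy_curation"),
                  colnames(v)), drop = FALSE],
    S4Vectors::DataFrame(fv[, c(.DELETERIOUS_FEATURES,
                                .NEUTRAL_FEATURES)]),
    sds = sdsv,
    priority = priority,
    tolerance_class = tol,
    excluded = excluded,
    final_priority = final,
    n_missing_features = fv$n_missing_features,
    del_count = fv$del_count,
    cons_count = fv$cons_count)
  new("SdsResults", table = tb, config = config,
      deleteriousFeatures = .DELETERIOUS_FEATURES,
      neutralFeatures = .NEUTRAL_FEATURES)
}

#' Step-wise correlation of the score with an external composite score
#'
#' Regresses an external composite deleteriousness score on the structural
#' disruption score (simple linear regression; R-squared and the two-tailed
#' p-value of the slope), first with the full seven-flag score and then
#' once per dropped component with the score recomputed on the remaining
#' six flags. Each drop row also reports how many variants' scores changed.
#'
#' @param results an \linkS4class{SdsResults}.
#' @param composite optional numeric vector; defaults to the
#'   \code{composite_score} column.
#' @return data.frame with columns \code{dropped_component} ("none" first),
#'   \code{r_squared}, \code{p}, \code{n_changed}, \code{n_used}.
#' @export
stepwiseCorrelation <- function(results, composite = NULL) {
  tb <- as.data.frame(sdsTable(results))
  if (is.null(composite)) {
    if (!"composite_score" %in% colnames(tb))
      stop("no composite_score column and no composite vector supplied")
    composite <- tb$composite_score
  }
  ok <- !is.na(composite)
  if (sum(ok) < 3L)
    stop("need composite scores for at least 3 variants")
  flags <- tb[, .DELETERIOUS_FEATURES, drop = FALSE]
  fitRow <- function(score, dropped, changed) {
    fit <- stats::lm(composite[ok] ~ score[ok])
    sm <- summary(fit)
    p <- if (nrow(sm$coefficients) < 2L) NA_real_ else
      sm$coefficients[2L, 4L]
    data.frame(dropped_component = dropped,
               r_squared = sm$r.squared, p = p,
               n_changed = changed, n_used = sum(ok),
               stringsAsFactors = FALSE)
  }
  full <- computeSds(flags)
  out <- fitRow(full, "none", 0L)
  for (f in .DELETERIOUS_FEATURES) {
    reduced <- computeSds(flags[, setdiff(.DELETERIOUS_FEATURES, f),
                                drop = FALSE])
    out <- rbind(out, fitRow(reduced, f, sum(reduced != full)))
  }
  rownames(out) <- NULL
  out
}
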