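# Statistical comparison of positive (causal) vs negative (neutral)
# variants: one-tailed Fisher's exact tests on categorical features,
# pooled-variance t-tests on continuous measures, and selection of the
# deleterious-direction feature set.

# Canonical deleterious-direction features, in reporting order.
.DELETERIOUS_FEATURES <- c("high_del_count", "large_grantham",
                           "gly_pro_change", "buried", "on_patch",
                           "in_domain", "destabilizing")
.NEUTRAL_FEATURES <- c("highly_flexible_site", "highly_dynamic_site",
                       "fully_conserved")

#' One-tailed Fisher's exact test on a 2x2 feature table
#'
#' Tests whether the proportion of feature-positive variants differs
#' between positive (causal) and negative (neutral) controls, in a
#' direction declared a priori. The table convention is \code{a} =
#' positives with the feature, \code{b} = positives without, \code{c} =
#' negatives with, \code{d} = negatives without.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param direction \code{"enriched_in_positive"} tests the feature more
#'   frequent among positives; \code{"enriched_in_negative"} the reverse.
#' @return the exact one-tailed p-value.
#' @examples
#' fisherOneTailed(10, 0, 0, 10)  # 1 / choose(20, 10)
#' @export
fisherOneTailed <- function(a, b, c, d,
                            direction = c("enriched_in_positive",
                                          "enriched_in_negative")) {
  direction <- match.arg(direction)
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == floor(counts)))
  if (all(counts == 0)) {
    message("fisherOneTailed: empty table; p = 1 by convention")
    return(1)
  }
  m <- matrix(c(a, b, c, d), nrow = 2L,
              dimnames = list(feature = c("present", "absent"),
                              class = c("positive", "negative")))
  alt <- if (direction == "enriched_in_positive") "greater" else "less"
  stats::fisher.test(m, alternative = alt)$p.value
}

#' Pooled-variance two-sample t-test
#'
#' Two-tailed unpaired t-test with pooled variance, degrees of freedom
#' n1 + n2 - 2 (the form implied by reporting df = n - 2).
#'
#' @param x,y numeric vectors (NA dropped), each with >= 2 values.
#' @return list with \code{t} (t ratio), \code{df} and \code{p}
#'   (two-tailed).
#' @export
ttestUnpaired <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 non-missing values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2L, p = 1))
    stop("zero pooled variance with unequal means")
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = as.integer(unname(ht$parameter)),
       p = ht$p.value)
}

#' Per-feature enrichment of positive vs negative variants
#'
#' Builds the 2x2 table for each binary feature flag and runs the
#' one-tailed Fisher's exact test in the feature's a-priori direction:
#' deleterious-direction features are tested for enrichment among
#' positives, neutral-direction features for enrichment among negatives.
#' Missing flags are excluded from the table of that feature.
#'
#' @param flags data.frame/\code{DataFrame} of logical feature columns.
#' @param class_label factor/character vector aligned with \code{flags}
#'   rows; only \code{positive} and \code{negative} rows enter the tables.
#' @param features character vector of columns to test (defaults to the
#'   canonical seven deleterious-direction flags plus the neutral-direction
#'   flags present in \code{flags}).
#' @param alpha per-feature significance level.
#' @return data.frame with columns \code{feature}, \code{a}, \code{b},
#'   \code{c}, \code{d}, \code{direction}, \code{p}, \code{significant}.
#' @export
featureEnrichment <- function(flags, class_label, features = NULL,
                              alpha = 0.05) {
  flags <- as.data.frame(flags)
  if (is.null(features))
    features <- intersect(c(.DELETERIOUS_FEATURES, .NEUTRAL_FEATURES),
                          colnames(flags))
  stopifnot(length(class_label) == nrow(flags))
  pos <- class_label == "positive"
  neg <- class_label == "negative"
  rows <- lapply(features, function(f) {
    fl <- flags[[f]]
    dir <- if (f %in% .NEUTRAL_FEATURES) "enriched_in_negative" else
      "enriched_in_positive"
    ok <- !is.na(fl)
    a <- sum(fl & pos & ok); b <- sum(!fl & pos & ok)
    cc <- sum(fl & neg & ok); d <- sum(!fl & neg & ok)
    p <- fisherOneTailed(a, b, cc, d, direction = dir)
    data.frame(feature = f, a = a, b = b, c = cc, d = d,
               direction = dir, p = p, significant = p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select the deleterious-direction feature set
#'
#' Returns the significantly positive-enriched features in canonical order
#' (high deleterious count, large Grantham change, Gly/Pro change, buried
#' site, protein patch, protein domain, reduced stability), and the
#' significantly negative-enriched (neutral-compatible) features
#' separately. Conservation is never part of the score; its direction is
#' only reported.
#'
#' @param enrichment the data.frame from \code{\link{featureEnrichment}}.
#' @param alpha per-feature significance level (re-applied to the stored
#'   p-values).
#' @return list with character vectors \code{deleterious} and
#'   \code{neutral}.
#' @export
selectDeleteriousFeatures <- function(enrichment, alpha = 0.05) {
  sig <- enrichment$p < alpha
  del <- enrichment$feature[sig &
    enrichment$direction == "enriched_in_positive"]
  neu <- enrichment$feature[sig &
    enrichment$direction == "enriched_in_negative"]
  del <- intersect(.DELETERIOUS_FEATURES, del)
  if (!length(del))
    warning("no significantly positive-enriched features; score undefined without the canonical fallback set")
  list(deleterious = del,
       neutral = intersect(.NEUTRAL_FEATURES, neu))
}

#' Canonical feature flag names
#' @return character vector of the seven deleterious-direction flags
#'   (\code{deleteriousFeatureNames}) or the neutral-direction flags
#'   (\code{neutralFeatureNames}).
#' @export
deleteriousFeatureNames <- function() .DELETERIOUS_FEATURES

#' @rdname deleteriousFeatureNames
#' @export
neutralFeatureNames <- function() .NEUTRAL_FEATURES
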