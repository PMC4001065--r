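#' Threshold configuration for feature categorization and scoring
#'
#' Holds every cutoff used to turn continuous annotations into the
#' categorical feature flags that enter the structural disruption score:
#' the deleterious-count and Grantham cutoffs, the burial cutoff on relative
#' solvent accessibility, the four-band folding free-energy change
#' classification, the sequence non-optimality cutoff, percentile settings
#' and fixed fallback cutoffs for the dynamics/flexibility tails, and the
#' score threshold defining priority variants.
#'
#' @slot delCountMin minimum number of deleterious predictor calls (of 6)
#'   for the high-deleterious-count flag.
#' @slot granthamMin minimum Grantham distance for the large-change flag.
#' @slot rsaBuriedMax maximum relative solvent accessibility (percent) of a
#'   buried residue; the boundary is inclusive.
#' @slot ddgNoChangeBand open interval of ddG (kcal/mol) treated as no
#'   stability change.
#' @slot ddgStrongStabilizingMax ddG at or below this is strongly
#'   stabilizing (kcal/mol).
#' @slot ddgStrongDestabilizingMin ddG at or above this is strongly
#'   destabilizing (kcal/mol); values from the upper no-change bound up to
#'   here are mildly destabilizing, and the destabilizing feature flag uses
#'   the upper no-change bound.
#' @slot gammaNonoptimalMax non-optimality Gamma (kcal/mol) at or below
#'   which a residue is called highly non-optimal.
#' @slot bfactorTails,rmsfTails,pflexTails lower/upper tail percentiles used
#'   to derive empirical cutoffs for normalized B-factor, normalized RMSF
#'   and P(Flexible).
#' @slot bfactorFallback,rmsfFallback,pflexFallback fixed (lower, upper)
#'   cutoffs used when too few values are available to derive empirical
#'   percentiles.
#' @slot flexibleSiteRigidMax P(Flexible) at or below which a site is
#'   conformationally rigid in the enrichment profiling sense.
#' @slot sdsPriorityMin minimum score for the priority list.
#' @slot alpha per-feature significance level for enrichment tests.
#' @slot minEmpiricalN minimum number of non-missing values required before
#'   empirical percentile cutoffs replace the fixed fallbacks.
#'
#' @export
setClass("ThresholdConfig",
  representation(
    delCountMin = "numeric",
    granthamMin = "numeric",
    rsaBuriedMax = "numeric",
    ddgNoChangeBand = "numeric",
    ddgStrongStabilizingMax = "numeric",
    ddgStrongDestabilizingMin = "numeric",
    gammaNonoptimalMax = "numeric",
    bfactorTails = "numeric",
    rmsfTails = "numeric",
    pflexTails = "numeric",
    bfactorFallback = "numeric",
    rmsfFallback = "numeric",
    pflexFallback = "numeric",
    flexibleSiteRigidMax = "numeric",
    sdsPriorityMin = "numeric",
    alpha = "numeric",
    minEmpiricalN = "numeric"
  ),
  prototype(
    delCountMin = 4,
    granthamMin = 100,
    rsaBuriedMax = 20,
    ddgNoChangeBand = c(-0.5, 0.5),
    ddgStrongStabilizingMax = -2,
    ddgStrongDestabilizingMin = 4,
    gammaNonoptimalMax = -5,
    bfactorTails = c(2.5, 97.5),
    rmsfTails = c(0.5, 99.5),
    pflexTails = c(2.5, 97.5),
    bfactorFallback = c(-0.537, 1.17),
    rmsfFallback = c(-0.607, 1.195),
    pflexFallback = c(0.158, 0.860),
    flexibleSiteRigidMax = 0.74,
    sdsPriorityMin = 4,
    alpha = 0.05,
    minEmpiricalN = 40
  )
)

setValidity("ThresholdConfig", function(object) {
  msg <- character()
  band <- object@ddgNoChangeBand
  if (length(band) != 2L || band[1] >= band[2])
    msg <- c(msg, "ddgNoChangeBand must be an ordered (lower, upper) pair")
  for (nm in c("bfactorTails", "rmsfTails", "pflexTails")) {
    tl <- slot(object, nm)
    if (length(tl) != 2L || tl[1] <= 0 || tl[1] >= 50 ||
        tl[2] <= 50 || tl[2] >= 100 || tl[1] >= tl[2])
      msg <- c(msg, sprintf("%s must be (lower, upper) with lower in (0,50) and upper in (50,100)", nm))
  }
  for (nm in c("bfactorFallback", "rmsfFallback", "pflexFallback")) {
    fb <- slot(object, nm)
    if (length(fb) != 2L || fb[1] >= fb[2])
      msg <- c(msg, sprintf("%s must be an ordered (lower, upper) pair", nm))
  }
  if (object@ddgStrongStabilizingMax >= band[1])
    msg <- c(msg, "strong-stabilizing cutoff must lie below the no-change band")
  if (object@ddgStrongDestabilizingMin <= band[2])
    msg <- c(msg, "strong-destabilizing cutoff must lie above the no-change band")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Construct a ThresholdConfig
#'
#' All arguments default to the cutoffs used throughout the package
#' (deleterious count >= 4, Grantham >= 100, RSA <= 20 percent buried,
#' destabilizing at ddG >= 0.5 kcal/mol, strongly destabilizing at >= 4,
#' Gamma <= -5 non-optimal, 2.5/97.5 percentile tails except 0.5/99.5 for
#' RMSF, priority at score >= 4).
#'
#' @param ... named slot overrides, e.g. \code{sdsPriorityMin = 5}.
#' @return a \linkS4class{ThresholdConfig} object.
#' @examples
#' thresholdConfig()
#' thresholdConfig(alpha = 0.01)
#' @export
thresholdConfig <- function(...) new("ThresholdConfig", ...)

#' @describeIn thresholdConfig build a config from a nested list, e.g. as
#'   read from a YAML configuration file; unknown keys are an error.
#' @param x a named list of slot values.
#' @export
thresholdConfigFromList <- function(x) {
  stopifnot(is.list(x))
  known <- slotNames("ThresholdConfig")
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown threshold config keys: ", paste(bad, collapse = ", "))
  x <- lapply(x, function(v) as.numeric(unlist(v)))
  do.call(new, c(list(Class = "ThresholdConfig"), x))
}

#' @export
setMethod("show", "ThresholdConfig", function(object) {
  cat("ThresholdConfig\n")
  cat(sprintf("  deleterious count >= %g; Grantham >= %g; buried RSA <= %g%%\n",
              object@delCountMin, object@granthamMin, object@rsaBuriedMax))
  cat(sprintf("  ddG: no change (%g, %g); strong stab <= %g; strong destab >= %g kcal/mol\n",
              object@ddgNoChangeBand[1], object@ddgNoChangeBand[2],
              object@ddgStrongStabilizingMax, object@ddgStrongDestabilizingMin))
  cat(sprintf("  Gamma non-optimal <= %g kcal/mol; priority SDS >= %g; alpha = %g\n",
              object@gammaNonoptimalMax, object@sdsPriorityMin, object@alpha))
})

#' Accessors for ThresholdConfig cutoffs
#' @param x a \linkS4class{ThresholdConfig}.
#' @return the numeric cutoff.
#' @name threshold-accessors
#' @export
delCountMin <- function(x) x@delCountMin
#' @rdname threshold-accessors
#' @export
granthamMin <- function(x) x@granthamMin
#' @rdname threshold-accessors
#' @export
rsaBuriedMax <- function(x) x@rsaBuriedMax
#' @rdname threshold-accessors
#' @export
sdsPriorityMin <- function(x) x@sdsPriorityMin


#' A cohort of missense variants with annotations
#'
#' Wraps a \link[S4Vectors]{DataFrame} with one row per missense variant.
#' The required columns are \code{gene_symbol}, \code{protein_position}
#' (1-based), \code{ref_aa}, \code{alt_aa} (one-letter codes, different from
#' each other) and \code{class_label} (one of \code{case}, \code{negative},
#' \code{positive}). Any number of annotation columns (predictor calls,
#' ddG, Gamma, normalized B-factor/RMSF, P(Flexible), RSA, patch/domain
#' membership, secondary structure, RVIS, ...) ride along. Missing values
#' are \code{NA} throughout and are distinct from zero/false.
#'
#' @slot variants a \code{DataFrame}, one row per variant.
#' @slot log character vector of reader/pipeline messages attached to this
#'   cohort (skipped cells, fallbacks, ...).
#' @slot metadata free-form list (e.g. generator ground truth, seeds).
#' @export
setClass("VariantCohort",
  representation(variants = "DataFrame", log = "character",
                 metadata = "list"),
  prototype(log = character(), metadata = list())
)

.REQUIRED_VARIANT_COLS <- c("gene_symbol", "protein_position",
                            "ref_aa", "alt_aa", "class_label")
.CLASS_LABELS <- c("case", "negative", "positive")

setValidity("VariantCohort", function(object) {
  v <- object@variants
  msg <- character()
  missing <- setdiff(.REQUIRED_VARIANT_COLS, colnames(v))
  if (length(missing))
    return(paste("missing required column(s):", paste(missing, collapse = ", ")))
  if (nrow(v)) {
    if (!all(toupper(v$ref_aa) %in% .AA1) || !all(toupper(v$alt_aa) %in% .AA1))
      msg <- c(msg, "ref_aa/alt_aa must be standard one-letter codes")
    if (any(toupper(v$ref_aa) == toupper(v$alt_aa)))
      msg <- c(msg, "ref_aa must differ from alt_aa (missense only)")
    if (!all(v$class_label %in% .CLASS_LABELS))
      msg <- c(msg, "class_label must be one of case/negative/positive")
    pos <- v$protein_position
    if (!is.numeric(pos) || any(is.na(pos)) || any(pos < 1) ||
        any(pos != floor(pos)))
      msg <- c(msg, "protein_position must be integer >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a VariantCohort from a data frame
#'
#' @param variants a \code{data.frame} or \code{DataFrame} with at least the
#'   required variant columns (see \linkS4class{VariantCohort}).
#' @param log optional character vector of provenance messages.
#' @param metadata optional free-form list.
#' @return a \linkS4class{VariantCohort}.
#' @examples
#' variantCohort(data.frame(
#'   gene_symbol = "ABCA6", protein_position = 1359, ref_aa = "C",
#'   alt_aa = "R", class_label = "case"))
#' @export
variantCohort <- function(variants, log = character(), metadata = list()) {
  if (is.data.frame(variants)) variants <- S4Vectors::DataFrame(variants)
  if (nrow(variants)) {
    variants$ref_aa <- toupper(variants$ref_aa)
    variants$alt_aa <- toupper(variants$alt_aa)
    variants$class_label <- tolower(as.character(variants$class_label))
  }
  new("VariantCohort", variants = variants, log = as.character(log),
      metadata = metadata)
}

#' Free-form metadata attached to a cohort
#' @param x a \linkS4class{VariantCohort}.
#' @return a list.
#' @export
cohortMetadata <- function(x) x@metadata

#' @describeIn variantCohort the underlying per-variant \code{DataFrame}.
#' @param x a \code{VariantCohort}.
#' @export
setMethod("variantData", "VariantCohort", function(x) x@variants)

#' @describeIn variantCohort factor of class labels (case/negative/positive).
#' @export
setMethod("classLabels", "VariantCohort", function(x) {
  factor(x@variants$class_label, levels = .CLASS_LABELS)
})

#' @export
setMethod("length", "VariantCohort", function(x) nrow(x@variants))

#' @export
setMethod("show", "VariantCohort", function(object) {
  v <- object@variants
  cat(sprintf("VariantCohort with %d variant(s) in %d gene(s)\n",
              nrow(v), length(unique(v$gene_symbol))))
  if (nrow(v)) {
    tab <- table(factor(v$class_label, levels = .CLASS_LABELS))
    cat(sprintf("  case: %d  negative: %d  positive: %d\n",
                tab[["case"]], tab[["negative"]], tab[["positive"]]))
    extra <- setdiff(colnames(v), .REQUIRED_VARIANT_COLS)
    if (length(extra))
      cat("  annotation columns:", paste(head(extra, 8), collapse = ", "),
          if (length(extra) > 8) "..." else "", "\n")
  }
  if (length(object@log))
    cat(sprintf("  %d log message(s); see cohortLog()\n", length(object@log)))
})

#' Reader/pipeline log attached to a cohort
#' @param x a \linkS4class{VariantCohort}.
#' @return character vector of messages.
#' @export
cohortLog <- function(x) x@log


#' A protein structure as a flat atom table
#'
#' Heavy-atom coordinates of one PDB model, kept in source numbering.
#' One row per atom with chain, residue number, residue name (3-letter),
#' atom name, element and Cartesian coordinates in Angstrom.
#'
#' @slot atoms a \code{data.frame} with columns \code{chain}, \code{resno},
#'   \code{resid}, \code{elety}, \code{elesy}, \code{x}, \code{y}, \code{z}.
#' @slot source character scalar describing provenance (file path or
#'   generator call).
#' @export
setClass("ProteinStructure",
  representation(atoms = "data.frame", source = "character"),
  prototype(source = NA_character_)
)

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  missing <- setdiff(need, colnames(a))
  if (length(missing))
    return(paste("atoms lacks column(s):", paste(missing, collapse = ", ")))
  msg <- character()
  if (nrow(a)) {
    if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z)))
      msg <- c(msg, "all coordinates must be finite")
    if (anyDuplicated(a[, c("chain", "resno", "elety")]))
      msg <- c(msg, "at most one atom per (chain, residue, atom name)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinStructure from an atom table
#'
#' @param atoms data.frame of atoms (see \linkS4class{ProteinStructure}).
#' @param source provenance string.
#' @return a \linkS4class{ProteinStructure}.
#' @export
proteinStructure <- function(atoms, source = NA_character_) {
  new("ProteinStructure", atoms = as.data.frame(atoms), source = source)
}

#' @describeIn proteinStructure the atom table.
#' @param x a \code{ProteinStructure}.
#' @export
setMethod("atomRecords", "ProteinStructure", function(x) x@atoms)

#' Residues present in a structure
#' @param x a \linkS4class{ProteinStructure}.
#' @return data.frame with one row per (chain, resno, resid).
#' @export
structureResidues <- function(x) {
  a <- atomRecords(x)
  unique(a[, c("chain", "resno", "resid")])
}

#' @export
setMethod("show", "ProteinStructure", function(object) {
  a <- object@atoms
  res <- unique(paste(a$chain, a$resno))
  cat(sprintf("ProteinStructure: %d atoms, %d residues, chain(s) %s\n",
              nrow(a), length(res),
              paste(sort(unique(a$chain)), collapse = ",")))
  if (!is.na(object@source)) cat("  source:", object@source, "\n")
})


#' Scored variants with structural disruption scores
#'
#' Result container produced by \code{\link{scoreVariants}}: the input
#' variant table augmented with the seven deleterious-direction feature
#' flags, the neutral-direction flags, the score (0-7), priority status,
#' gene tolerance class, flexible-site exclusion and final-priority flags.
#'
#' @slot table a \code{DataFrame}, one row per variant, original row order.
#' @slot config the \linkS4class{ThresholdConfig} used.
#' @slot deleteriousFeatures names of the seven deleterious-direction flags
#'   in canonical order.
#' @slot neutralFeatures names of the neutral-direction flags.
#' @export
setClass("SdsResults",
  representation(
    table = "DataFrame",
    config = "ThresholdConfig",
    deleteriousFeatures = "character",
    neutralFeatures = "character"
  )
)

setValidity("SdsResults", function(object) {
  tb <- object@table
  msg <- character()
  need <- c(object@deleteriousFeatures, "sds", "priority",
            "tolerance_class", "excluded", "final_priority",
            "n_missing_features")
  missing <- setdiff(need, colnames(tb))
  if (length(missing))
    return(paste("table lacks column(s):", paste(missing, collapse = ", ")))
  if (length(object@deleteriousFeatures) != 7L)
    msg <- c(msg, "exactly seven deleterious-direction features required")
  if (nrow(tb)) {
    if (any(tb$sds < 0 | tb$sds > 7))
      msg <- c(msg, "sds must lie in [0, 7]")
    flags <- as.data.frame(tb[, object@deleteriousFeatures])
    recount <- rowSums(flags == TRUE, na.rm = TRUE)
    if (!all(recount == tb$sds))
      msg <- c(msg, "sds must equal the number of TRUE deleterious flags")
    if (any(tb$final_priority & !tb$priority))
      msg <- c(msg, "final_priority must be a subset of priority")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SdsResults the full per-variant result table.
#' @param x an \code{SdsResults}.
#' @export
setMethod("sdsTable", "SdsResults", function(x) x@table)

#' @describeIn SdsResults integer vector of scores (0-7).
#' @export
setMethod("sds", "SdsResults", function(x) as.integer(x@table$sds))

#' @describeIn SdsResults logical final-priority flag per variant.
#' @export
setMethod("finalPriority", "SdsResults", function(x) x@table$final_priority)

#' @describeIn SdsResults canonical names of the seven deleterious-direction
#'   feature flags.
#' @export
setMethod("featureNames", "SdsResults", function(x) x@deleteriousFeatures)

#' @export
setMethod("length", "SdsResults", function(x) nrow(x@table))

#' @export
setMethod("show", "SdsResults", function(object) {
  tb <- object@table
  cat(sprintf("SdsResults with %d variant(s)\n", nrow(tb)))
  if (nrow(tb)) {
    cat("  score distribution: ")
    print(table(factor(tb$sds, levels = 0:7)))
    cat(sprintf("  priority (sds >= %g): %d;  excluded: %d;  final priority: %d\n",
                object@config@sdsPriorityMin, sum(tb$priority),
                sum(tb$excluded), sum(tb$final_priority)))
  }
})
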