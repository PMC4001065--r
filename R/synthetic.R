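# Synthetic cohort and toy structure generation: labelled variant tables
# with planted class-conditional feature enrichment, and idealized PDB
# coordinates, so every pipeline stage is testable without downloads.

#' Specification of a synthetic labelled cohort
#'
#' Defaults emulate the class-conditional contrasts of a causal-vs-neutral
#' variant study: positives carry each deleterious-direction feature with
#' probability 0.5 against 0.1 in negatives; flexible-site rates are
#' reversed (0.01 positives vs 0.08 negatives); predicted stability
#' changes are normal with a higher destabilizing mean for positives.
#' Default cohort sizes mirror a small exome candidate set (30 case, 1674
#' negative, 100 positive). Case variants are drawn from a blend
#' \code{caseBlend} of the way from the negative toward the positive
#' feature probabilities. Flags with a numeric threshold (destabilizing,
#' buried, flexible, large Grantham) are always derived from the drawn
#' value and the threshold, never sampled separately.
#'
#' @slot nCase,nNegative,nPositive cohort sizes.
#' @slot flagProbPos,flagProbNeg per-feature probability of each
#'   deleterious-direction flag in positives / negatives.
#' @slot flexProbPos,flexProbNeg probability of P(Flexible) >= 0.860.
#' @slot consProbPos,consProbNeg per-call probability of a conserved call.
#' @slot ddgMeanPos,ddgMeanNeg,ddgSd normal parameters for ddG (kcal/mol).
#' @slot rvisSd standard deviation of gene-level RVIS (mean 0).
#' @slot caseBlend blend factor in [0,1] for case-class probabilities.
#' @slot nGenes number of genes variants are distributed over.
#' @slot seed default random seed.
#' @export
setClass("SyntheticSpec",
  representation(
    nCase = "numeric", nNegative = "numeric", nPositive = "numeric",
    flagProbPos = "numeric", flagProbNeg = "numeric",
    flexProbPos = "numeric", flexProbNeg = "numeric",
    consProbPos = "numeric", consProbNeg = "numeric",
    ddgMeanPos = "numeric", ddgMeanNeg = "numeric", ddgSd = "numeric",
    rvisSd = "numeric", caseBlend = "numeric", nGenes = "numeric",
    seed = "numeric"
  ),
  prototype(
    nCase = 30, nNegative = 1674, nPositive = 100,
    flagProbPos = 0.5, flagProbNeg = 0.1,
    flexProbPos = 0.01, flexProbNeg = 0.08,
    consProbPos = 0.6, consProbNeg = 0.85,
    ddgMeanPos = 1.5, ddgMeanNeg = 0.3, ddgSd = 1.0,
    rvisSd = 0.5, caseBlend = 0.3, nGenes = 60,
    seed = 1
  )
)

setValidity("SyntheticSpec", function(object) {
  probs <- c(object@flagProbPos, object@flagProbNeg, object@flexProbPos,
             object@flexProbNeg, object@consProbPos, object@consProbNeg,
             object@caseBlend)
  msg <- character()
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "all probabilities must lie in [0, 1]")
  if (any(c(object@nCase, object@nNegative, object@nPositive) < 0))
    msg <- c(msg, "cohort sizes must be >= 0")
  if (object@nGenes < 1) msg <- c(msg, "nGenes must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticSpec constructor with named slot overrides.
#' @param ... slot overrides, e.g. \code{nCase = 200}.
#' @export
syntheticSpec <- function(...) new("SyntheticSpec", ...)

#' @export
setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %g case / %g negative / %g positive over %g genes\n",
              object@nCase, object@nNegative, object@nPositive,
              object@nGenes))
  cat(sprintf("  flag prob pos/neg: %g/%g; flexible pos/neg: %g/%g; ddG mean pos/neg: %g/%g\n",
              object@flagProbPos, object@flagProbNeg, object@flexProbPos,
              object@flexProbNeg, object@ddgMeanPos, object@ddgMeanNeg))
})

# Per-call probability q such that P(Binomial(size, q) >= hit) = target.
.solveCallProb <- function(target, size, hit) {
  if (target <= 0) return(0)
  if (target >= 1) return(1)
  stats::uniroot(function(q)
    stats::pbinom(hit - 1L, size, q, lower.tail = FALSE) - target,
    c(1e-9, 1 - 1e-9), tol = 1e-10)$root
}

# Beta(2, b) shape so that P(X >= cutoff) = target.
.solveBetaShape <- function(target, cutoff) {
  stats::uniroot(function(b)
    stats::pbeta(cutoff, 2, b, lower.tail = FALSE) - target,
    c(0.02, 500), tol = 1e-10)$root
}

# Ordered amino-acid pairs partitioned by (Grantham >= cutoff, Gly/Pro).
.aaPairPool <- function(granthamCutoff = 100) {
  pairs <- expand.grid(ref = .AA1, alt = .AA1, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  g <- granthamDistance(pairs$ref, pairs$alt) >= granthamCutoff
  gp <- isGlyProChange(pairs$ref, pairs$alt)
  split(pairs, paste0(as.integer(g), as.integer(gp)))
}

#' Generate a labelled synthetic cohort
#'
#' Draws a variant annotation table with the class-conditional feature
#' structure of \code{spec}; deterministic for a fixed seed. Every column
#' the scoring pipeline consumes is populated (predictor calls,
#' conservation calls, ddG, Gamma, normalized B-factor/RMSF, P(Flexible),
#' RSA, patch/domain, secondary structure, RVIS, a correlated external
#' composite score, and a curation column for case variants). The planted
#' ground-truth flags are kept in \code{cohortMetadata(x)$truth} for
#' parameter-recovery tests.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param seed integer seed; defaults to the spec's seed slot.
#' @return a \linkS4class{VariantCohort}.
#' @examples
#' cohort <- generateCohort(syntheticSpec(nCase = 5, nNegative = 50,
#'                                        nPositive = 10), seed = 7)
#' table(classLabels(cohort))
#' @export
generateCohort <- function(spec = syntheticSpec(), seed = spec@seed) {
  set.seed(as.integer(seed))
  n <- c(case = spec@nCase, negative = spec@nNegative,
         positive = spec@nPositive)
  N <- sum(n)
  cls <- rep(names(n), n)
  blend <- function(negV, posV)
    c(case = negV + spec@caseBlend * (posV - negV),
      negative = negV, positive = posV)[cls]
  pFlag <- blend(spec@flagProbNeg, spec@flagProbPos)
  pFlex <- blend(spec@flexProbNeg, spec@flexProbPos)
  pCons <- blend(spec@consProbNeg, spec@consProbPos)
  ddgMean <- blend(spec@ddgMeanNeg, spec@ddgMeanPos)

  genes <- sprintf("GENE%03d", seq_len(spec@nGenes))
  geneRvis <- stats::rnorm(spec@nGenes, 0, spec@rvisSd)
  gi <- sample.int(spec@nGenes, N, replace = TRUE)

  # deleterious / conservation calls
  qDel <- vapply(pFlag, .solveCallProb, numeric(1), size = 6L, hit = 4L)
  delCalls <- matrix(stats::runif(N * 6L) < qDel, N, 6L)
  consCalls <- matrix(stats::runif(N * 3L) < pCons, N, 3L)

  # planted binary flags
  planted <- data.frame(
    high_del_count = rowSums(delCalls) >= 4L,
    large_grantham = stats::runif(N) < pFlag,
    gly_pro_change = stats::runif(N) < pFlag,
    buried = stats::runif(N) < pFlag,
    on_patch = stats::runif(N) < pFlag,
    in_domain = stats::runif(N) < pFlag)

  # amino-acid pair consistent with the planted Grantham / GlyPro flags
  pool <- .aaPairPool()
  key <- paste0(as.integer(planted$large_grantham),
                as.integer(planted$gly_pro_change))
  ref <- character(N); alt <- character(N)
  for (k in unique(key)) {
    idx <- which(key == k)
    pick <- sample.int(nrow(pool[[k]]), length(idx), replace = TRUE)
    ref[idx] <- pool[[k]]$ref[pick]
    alt[idx] <- pool[[k]]$alt[pick]
  }

  # continuous values; thresholded flags derive from these draws
  ddg <- stats::rnorm(N, ddgMean, spec@ddgSd)
  rsa <- ifelse(planted$buried, stats::runif(N, 0, 20),
                stats::runif(N, 20.001, 100))
  bShape <- vapply(pFlex, .solveBetaShape, numeric(1), cutoff = 0.860)
  pflex <- stats::rbeta(N, 2, bShape)
  planted$destabilizing <- ddg >= 0.5
  planted$highly_flexible_site <- pflex >= 0.860

  truthSds <- rowSums(planted[, .DELETERIOUS_FEATURES])

  v <- data.frame(
    gene_symbol = genes[gi],
    transcript_id = sprintf("TX%05d", gi),
    protein_position = sample.int(200000L, N),
    ref_aa = ref, alt_aa = alt,
    class_label = cls,
    sift_call = ifelse(delCalls[, 1], "deleterious", "tolerated"),
    pp2_hdiv_call = ifelse(delCalls[, 2], "deleterious", "tolerated"),
    pp2_hvar_call = ifelse(delCalls[, 3], "deleterious", "tolerated"),
    lrt_call = ifelse(delCalls[, 4], "deleterious", "tolerated"),
    mutation_taster_call = ifelse(delCalls[, 5], "deleterious", "tolerated"),
    mutation_assessor_call = ifelse(delCalls[, 6], "deleterious", "tolerated"),
    gerp_call = ifelse(consCalls[, 1], "conserved", "not_conserved"),
    phylop_call = ifelse(consCalls[, 2], "conserved", "not_conserved"),
    siphy_call = ifelse(consCalls[, 3], "conserved", "not_conserved"),
    ddg = round(ddg, 4),
    gamma = round(stats::rnorm(N, -1, 2), 4),
    bfactor_norm = round(stats::rnorm(N, 0.3, 0.45), 4),
    rmsf_norm = round(stats::rnorm(N, 0.3, 0.45), 4),
    p_flexible = round(pflex, 4),
    rsa_percent = round(rsa, 2),
    ss_code = sample(.DSSP_CODES, N, replace = TRUE,
                     prob = c(0.04, 0.3, 0.01, 0.2, 0.1, 0.02, 0.08, 0.25)),
    on_patch = planted$on_patch,
    in_domain = planted$in_domain,
    sc_residue = stats::runif(N) < 0.1,
    disulfide_involved = stats::runif(N) < 0.02,
    rvis = round(geneRvis[gi], 3),
    composite_score = round(0.5 * truthSds + stats::rnorm(N, 0, 1), 4),
    epilepsy_curation = ifelse(
      cls == "case",
      sample(c("likely", "maybe", "less_likely", "no", "na"), N,
             replace = TRUE, prob = c(0.2, 0.2, 0.2, 0.3, 0.1)),
      "na"),
    stringsAsFactors = FALSE)

  variantCohort(v, metadata = list(truth = planted, seed = seed,
                                   spec = spec))
}

#' Generate an idealized toy structure
#'
#' Three kinds of small test structures with valid coordinates:
#' \code{"helix"} (ideal alpha-helix backbone, ~1.5 Angstrom rise and
#' ~100 degree twist per residue), \code{"extended"} (ideal beta-extended
#' backbone, ~3.4 Angstrom axial spacing), and \code{"shell"} (a single
#' alanine enclosed by a sphere of carbon dummy atoms, fully occluding
#' solvent). Residues are poly-alanine with backbone plus C-beta atoms.
#'
#' @param kind one of \code{"helix"}, \code{"extended"}, \code{"shell"}.
#' @param nResidues number of residues (>= 3 for chains; for
#'   \code{"shell"} the count of shell dummy atoms, default 400).
#' @param chain chain identifier.
#' @param shellRadius radius (Angstrom) of the shell of dummy atoms.
#' @return a \linkS4class{ProteinStructure}.
#' @examples
#' helix <- generateToyStructure("helix", 12)
#' @export
generateToyStructure <- function(kind = c("helix", "extended", "shell"),
                                 nResidues = 3, chain = "A",
                                 shellRadius = 5.5) {
  kind <- match.arg(kind)
  if (kind != "shell" && nResidues < 3)
    stop("chain structures need at least 3 residues")
  atoms <- switch(kind,
    helix = .buildPeptide(rep("A", nResidues), phi = -57, psi = -47,
                          chain = chain),
    extended = .buildPeptide(rep("A", nResidues), phi = -139, psi = 135,
                             chain = chain),
    shell = {
      nShell <- max(nResidues, 400L)
      core <- .buildPeptide("A", phi = -139, psi = 135, chain = chain)
      ctr <- colMeans(core[, c("x", "y", "z")])
      core$x <- core$x - ctr[1]
      core$y <- core$y - ctr[2]
      core$z <- core$z - ctr[3]
      sp <- spherePoints(nShell) * shellRadius
      shell <- data.frame(
        chain = chain, resno = seq_len(nShell) + 1L, resid = "ALA",
        elety = "C", elesy = "C",
        x = sp[, 1], y = sp[, 2], z = sp[, 3],
        stringsAsFactors = FALSE)
      rbind(core, shell)
    })
  proteinStructure(atoms,
                   source = sprintf("generateToyStructure(%s)", kind))
}
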