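# Sequence-level features: predictor call counts, Gly/Pro changes,
# disulfide involvement.

.DEL_CALL_COLS <- c("sift_call", "pp2_hdiv_call", "pp2_hvar_call",
                    "lrt_call", "mutation_taster_call",
                    "mutation_assessor_call")
.CONS_CALL_COLS <- c("gerp_call", "phylop_call", "siphy_call")

.countCalls <- function(ann, cols, hit, precomputed) {
  ann <- as.data.frame(ann)
  have <- intersect(cols, colnames(ann))
  if (length(have)) {
    calls <- ann[, have, drop = FALSE]
    hits <- Reduce(`+`, lapply(calls, function(x)
      as.integer(!is.na(x) & x == hit)))
    avail <- Reduce(`+`, lapply(calls, function(x) as.integer(!is.na(x))))
    # columns absent from the table count as missing calls
    data.frame(count = as.integer(hits), n_calls = as.integer(avail))
  } else if (precomputed %in% colnames(ann)) {
    data.frame(count = as.integer(ann[[precomputed]]),
               n_calls = rep(NA_integer_, nrow(ann)))
  } else {
    data.frame(count = rep(NA_integer_, nrow(ann)),
               n_calls = rep(NA_integer_, nrow(ann)))
  }
}

#' Count deleterious predictor calls per variant
#'
#' Counts how many of the six sequence-based predictors (SIFT, PolyPhen2
#' HumDiv, PolyPhen2 HumVar, LRT, MutationTaster, MutationAssessor) call a
#' variant deleterious. Missing calls contribute zero to the count (the
#' count is not renormalized); the number of available calls is returned
#' alongside so low-coverage variants can be filtered.
#'
#' When none of the per-predictor call columns is present but a precomputed
#' \code{del_count} column exists, that column is used and \code{n_calls}
#' is \code{NA}.
#'
#' @param ann a \code{data.frame}/\code{DataFrame} of annotations or a
#'   \linkS4class{VariantCohort}.
#' @return data.frame with integer columns \code{count} (0-6) and
#'   \code{n_calls} (calls available).
#' @export
deleteriousCount <- function(ann) {
  if (is(ann, "VariantCohort")) ann <- variantData(ann)
  .countCalls(ann, .DEL_CALL_COLS, "deleterious", "del_count")
}

#' Count conservation calls per variant
#'
#' Same convention as \code{\link{deleteriousCount}} for the three
#' conservation scores (GERP++, phyloP, SiPhy); maximum count 3. A
#' precomputed \code{cons_count} column is used when call columns are
#' absent.
#'
#' @inheritParams deleteriousCount
#' @return data.frame with integer columns \code{count} (0-3) and
#'   \code{n_calls}.
#' @export
conservationCount <- function(ann) {
  if (is(ann, "VariantCohort")) ann <- variantData(ann)
  .countCalls(ann, .CONS_CALL_COLS, "conserved", "cons_count")
}

#' Does a substitution involve glycine or proline?
#'
#' Glycine and proline have exceptional backbone conformational properties
#' (flexibility and rigidity respectively), so substitutions into or out of
#' either are flagged as likely structure-perturbing.
#'
#' @inheritParams granthamDistance
#' @return logical vector.
#' @examples
#' isGlyProChange("R", "G")  # TRUE
#' isGlyProChange("I", "T")  # FALSE
#' @export
isGlyProChange <- function(ref_aa, alt_aa) {
  ref <- .checkAA(ref_aa, "reference amino acid")
  alt <- .checkAA(alt_aa, "alternate amino acid")
  ref %in% c("G", "P") | alt %in% c("G", "P")
}

#' Does a substitution disturb a disulfide-bonded cysteine?
#'
#' A variant changes the disulfide pattern when it creates or removes a
#' cysteine at a position that participates in a disulfide bond. Bonded
#' positions are taken from a precomputed connectivity prediction when
#' supplied; otherwise, if a structure is given, a cysteine is considered
#' bonded when its S-gamma atom lies within \code{sgCutoff} of another
#' cysteine S-gamma. With neither source available the result for a
#' Cys-involving variant is \code{NA} (unknown, not FALSE).
#'
#' @param ref_aa,alt_aa one-letter codes of the substitution.
#' @param position 1-based protein position of the variant.
#' @param bondedCysPositions optional integer vector of residue positions
#'   predicted to be in disulfide bonds.
#' @param structure optional \linkS4class{ProteinStructure} used as a
#'   geometric fallback.
#' @param chain chain identifier used with \code{structure}.
#' @param sgCutoff maximum S-gamma/S-gamma distance (Angstrom) for a
#'   geometric disulfide call.
#' @return logical scalar, possibly \code{NA}.
#' @export
disulfideChange <- function(ref_aa, alt_aa, position,
                            bondedCysPositions = NULL,
                            structure = NULL, chain = NULL,
                            sgCutoff = 2.5) {
  ref <- .checkAA(ref_aa, "reference amino acid")
  alt <- .checkAA(alt_aa, "alternate amino acid")
  if (ref != "C" && alt != "C") return(FALSE)
  if (!is.null(bondedCysPositions))
    return(position %in% bondedCysPositions)
  if (!is.null(structure)) {
    bonded <- bondedCysteines(structure, chain = chain, sgCutoff = sgCutoff)
    return(position %in% bonded)
  }
  message(sprintf(
    "disulfideChange: no connectivity prediction or structure for Cys variant at position %d; result unknown",
    as.integer(position)))
  NA
}

#' Geometrically bonded cysteines in a structure
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param chain optional chain restriction.
#' @param sgCutoff maximum S-gamma pair distance (Angstrom), default 2.5.
#' @return integer vector of residue numbers whose S-gamma lies within
#'   \code{sgCutoff} of another cysteine S-gamma.
#' @export
bondedCysteines <- function(structure, chain = NULL, sgCutoff = 2.5) {
  a <- atomRecords(structure)
  sg <- a[a$resid == "CYS" & a$elety == "SG", , drop = FALSE]
  if (!is.null(chain)) sg <- sg[sg$chain == chain, , drop = FALSE]
  if (nrow(sg) < 2L) return(integer())
  xyz <- as.matrix(sg[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  diag(d) <- Inf
  sort(unique(sg$resno[apply(d <= sgCutoff, 1L, any)]))
}
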