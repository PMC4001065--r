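#' Grantham physico-chemical distance between amino acids
#'
#' Returns the Grantham (1974) distance for one or more pairs of one-letter
#' amino acid codes. The distance summarizes differences in side-chain
#' composition, polarity and molecular volume; substitutions with distance
#' >= 100 are conventionally treated as large physico-chemical changes.
#' The published 20x20 integer matrix is used verbatim (the matrix, not the
#' generating formula, is what downstream annotation tools cite);
#' \code{\link{granthamFromProperties}} recomputes it from the property
#' values as an independent cross-check.
#'
#' @param ref_aa,alt_aa one-letter amino acid codes (vectorized, case
#'   insensitive).
#' @return numeric vector of distances; 0 for identical residues.
#' @examples
#' granthamDistance("C", "R")  # 180
#' granthamDistance("R", "G")  # 125
#' @export
granthamDistance <- function(ref_aa, alt_aa) {
  ref <- .checkAA(ref_aa, "reference amino acid")
  alt <- .checkAA(alt_aa, "alternate amino acid")
  if (length(ref) != length(alt))
    stop("ref_aa and alt_aa must have the same length")
  .GRANTHAM_MATRIX[cbind(ref, alt)]
}

#' The published Grantham distance matrix
#'
#' @return a symmetric 20x20 numeric matrix with zero diagonal, rows and
#'   columns named by one-letter amino acid codes.
#' @export
granthamMatrix <- function() .GRANTHAM_MATRIX

#' Grantham distance recomputed from side-chain properties
#'
#' Evaluates the original composition/polarity/volume formula,
#' \eqn{D_{ij} = \rho [\alpha (c_i-c_j)^2 + \beta (p_i-p_j)^2 +
#' \gamma (v_i-v_j)^2]^{1/2}}, with the global scale \eqn{\rho} fixed so
#' the mean over the 190 unordered residue pairs equals 100. Because the
#' published matrix was rounded, entries agree with
#' \code{\link{granthamDistance}} only to within rounding; this function
#' exists as a cross-check, not as the primary implementation.
#'
#' @inheritParams granthamDistance
#' @return numeric vector of (unrounded) distances.
#' @export
granthamFromProperties <- function(ref_aa, alt_aa) {
  ref <- .checkAA(ref_aa, "reference amino acid")
  alt <- .checkAA(alt_aa, "alternate amino acid")
  p <- .GRANTHAM_PROPS
  rownames(p) <- p$aa
  raw <- function(a, b) {
    sqrt(.GRANTHAM_ALPHA * (p[a, "c"] - p[b, "c"])^2 +
         .GRANTHAM_BETA  * (p[a, "p"] - p[b, "p"])^2 +
         .GRANTHAM_GAMMA * (p[a, "v"] - p[b, "v"])^2)
  }
  rho <- .granthamRho()
  rho * raw(ref, alt)
}

.granthamRhoCache <- new.env(parent = emptyenv())

.granthamRho <- function() {
  if (!is.null(.granthamRhoCache$rho)) return(.granthamRhoCache$rho)
  p <- .GRANTHAM_PROPS
  idx <- which(upper.tri(matrix(0, 20, 20)), arr.ind = TRUE)
  d <- sqrt(.GRANTHAM_ALPHA * (p$c[idx[, 1]] - p$c[idx[, 2]])^2 +
            .GRANTHAM_BETA  * (p$p[idx[, 1]] - p$p[idx[, 2]])^2 +
            .GRANTHAM_GAMMA * (p$v[idx[, 1]] - p$v[idx[, 2]])^2)
  .granthamRhoCache$rho <- 100 / mean(d)
  .granthamRhoCache$rho
}
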