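# Solvent-accessible surface area by Shrake-Rupley numerical integration
# and relative solvent accessibility (RSA) normalization.

#' Quasi-uniform points on the unit sphere
#'
#' Deterministic golden-spiral (Fibonacci) point set used to sample atom
#' surfaces during Shrake-Rupley integration.
#'
#' @param n number of points.
#' @return an \code{n x 3} matrix of unit vectors.
#' @export
spherePoints <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere (default radius 1.4 Angstrom, water) over each atom:
#' the atom surface is sampled at \code{nPoints} quasi-uniform points on a
#' sphere of radius vdW + probe, and the accessible area is the fraction of
#' points not inside any neighboring atom's expanded sphere.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param probe probe radius in Angstrom.
#' @param nPoints points per atom; accuracy improves roughly as 1/sqrt(n).
#' @param radii named per-element vdW radius table (Angstrom).
#' @return numeric vector of areas (Angstrom^2), one per atom row.
#' @export
atomSASA <- function(structure, probe = 1.4, nPoints = 960,
                     radii = .VDW_RADII) {
  a <- atomRecords(structure)
  natom <- nrow(a)
  if (!natom) return(numeric())
  xyz <- as.matrix(a[, c("x", "y", "z")])
  r <- unname(radii[a$elesy])
  r[is.na(r)] <- .VDW_DEFAULT
  re <- r + probe
  sp <- spherePoints(nPoints)
  d2 <- as.matrix(dist(xyz))^2
  areas <- numeric(natom)
  for (i in seq_len(natom)) {
    nb <- which(d2[i, ] < (re[i] + re)^2)
    nb <- nb[nb != i]
    pts <- sweep(sp * re[i], 2L, xyz[i, ], "+")
    covered <- rep(FALSE, nPoints)
    for (j in nb) {
      dj <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
            (pts[, 3] - xyz[j, 3])^2
      covered <- covered | dj < re[j]^2
      if (all(covered)) break
    }
    areas[i] <- 4 * pi * re[i]^2 * mean(!covered)
  }
  areas
}

#' Per-residue solvent-accessible surface area
#'
#' @inheritParams atomSASA
#' @return data.frame with columns \code{chain}, \code{resno}, \code{resid},
#'   \code{sasa} (Angstrom^2).
#' @export
residueSASA <- function(structure, probe = 1.4, nPoints = 960,
                        radii = .VDW_RADII) {
  a <- atomRecords(structure)
  areas <- atomSASA(structure, probe = probe, nPoints = nPoints,
                    radii = radii)
  key <- paste(a$chain, a$resno, sep = "\r")
  agg <- rowsum(areas, key, reorder = FALSE)
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             resid = a$resid[first], sasa = as.numeric(agg[, 1]),
             stringsAsFactors = FALSE)
}

.rsaRefCache <- new.env(parent = emptyenv())

#' Maximum-accessibility reference for RSA normalization
#'
#' The RSA of residue X is its accessible area as a percentage of that of
#' the central X in an Alanine-X-Alanine tripeptide. Two references are
#' available: \code{"tien2013"}, the published theoretical maxima of Tien
#' et al. (2013), appropriate for full-side-chain structures; and
#' \code{"computed"}, the area of the central residue of an ideal extended
#' Ala-X-Ala tripeptide built by the package's own geometry engine
#' (backbone plus C-beta), appropriate for the backbone-only toy structures
#' the package generates, for which it makes RSA = 100 exact by
#' construction.
#'
#' @param aa one-letter residue code(s).
#' @param ref \code{"tien2013"} or \code{"computed"}.
#' @param probe,nPoints passed to \code{\link{atomSASA}} for the computed
#'   reference.
#' @return numeric vector of reference areas (Angstrom^2).
#' @export
maxAccReference <- function(aa, ref = c("tien2013", "computed"),
                            probe = 1.4, nPoints = 960) {
  ref <- match.arg(ref)
  aa <- .checkAA(aa)
  if (ref == "tien2013") return(unname(.MAX_ACC_TIEN2013[aa]))
  vapply(aa, function(x) {
    key <- sprintf("%s_%d_%g", x, nPoints, probe)
    if (is.null(.rsaRefCache[[key]])) {
      tri <- proteinStructure(
        .buildPeptide(c("A", x, "A"), phi = -139, psi = 135),
        source = "ideal extended Ala-X-Ala")
      rs <- residueSASA(tri, probe = probe, nPoints = nPoints)
      .rsaRefCache[[key]] <- rs$sasa[rs$resno == 2L]
    }
    .rsaRefCache[[key]]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Relative solvent accessibility of residues in a structure
#'
#' Computes residue SASA in the context of the whole structure and divides
#' by the Ala-X-Ala reference maximum for the residue type, times 100.
#' Values may exceed 100 for unusually extended conformations and are
#' reported uncapped. Residues absent from the structure yield \code{NA}
#' with a message (such variants are later reported unscorable for
#' burial).
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param chain chain identifier.
#' @param resno residue number(s) in source PDB numbering.
#' @param ref normalization reference, see \code{\link{maxAccReference}}.
#' @inheritParams atomSASA
#' @return numeric vector of RSA percentages, \code{NA} where the residue
#'   is absent.
#' @export
computeRSA <- function(structure, chain, resno,
                       ref = c("tien2013", "computed"),
                       probe = 1.4, nPoints = 960) {
  ref <- match.arg(ref)
  rs <- residueSASA(structure, probe = probe, nPoints = nPoints)
  rs <- rs[rs$chain == chain, , drop = FALSE]
  idx <- match(resno, rs$resno)
  out <- rep(NA_real_, length(resno))
  hit <- !is.na(idx)
  if (any(!hit)) {
    message(sprintf("computeRSA: residue(s) %s absent from chain %s; RSA missing",
                    paste(resno[!hit], collapse = ","), chain))
  }
  if (any(hit)) {
    aa1 <- .AA3[rs$resid[idx[hit]]]
    known <- !is.na(aa1)
    vals <- rep(NA_real_, sum(hit))
    if (any(known)) {
      vals[known] <- 100 * rs$sasa[idx[hit]][known] /
        maxAccReference(aa1[known], ref = ref, probe = probe,
                        nPoints = nPoints)
    }
    out[hit] <- vals
  }
  out
}
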