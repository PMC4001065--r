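# Ideal-geometry peptide backbone construction by internal-coordinate
# placement (natural extension reference frame). Used by the toy-structure
# generator and by the computed RSA normalization reference.

# Standard backbone geometry (Angstrom, degrees).
.BB <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
  b_c_o = 1.231, b_ca_cb = 1.521,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.8, a_c_ca_cb = 110.1,
  omega = 180
)

.deg <- pi / 180

# Place atom D given positions of A, B, C, the C-D bond length, the B-C-D
# angle and the A-B-C-D dihedral (degrees).
.placeAtom <- function(a, b, c, bond, angle, dihedral) {
  theta <- angle * .deg
  chi <- dihedral * .deg
  d2 <- bond * c(-cos(theta), sin(theta) * cos(chi), sin(theta) * sin(chi))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  m <- cbind(bc, m2, n)
  as.numeric(c + m %*% d2)
}

# Build an idealized backbone (N, CA, C, O and CB except for Gly) for a
# one-letter sequence at fixed (phi, psi). Returns a ProteinStructure
# atom table.
.buildPeptide <- function(sequence, phi, psi, chain = "A") {
  sequence <- .checkAA(sequence)
  n <- length(sequence)
  stopifnot(n >= 1)
  g <- .BB
  atoms <- vector("list", n)
  # residue 1 seeds the frame in the xy-plane
  N <- c(0, 0, 0)
  CA <- c(g$b_n_ca, 0, 0)
  a1 <- (180 - g$a_n_ca_c) * .deg
  C <- CA + g$b_ca_c * c(cos(a1), sin(a1), 0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      prev <- atoms[[i - 1L]]
      N <- .placeAtom(prev$N, prev$CA, prev$C, g$b_c_n, g$a_ca_c_n, psi)
      CA <- .placeAtom(prev$CA, prev$C, N, g$b_n_ca, g$a_c_n_ca, g$omega)
      C <- .placeAtom(prev$C, N, CA, g$b_ca_c, g$a_n_ca_c, phi)
    }
    O <- .placeAtom(N, CA, C, g$b_c_o, g$a_ca_c_o, psi + 180)
    res <- list(N = N, CA = CA, C = C, O = O)
    if (sequence[i] != "G") {
      res$CB <- .placeAtom(N, C, CA, g$b_ca_cb, g$a_c_ca_cb, 122.6)
    }
    atoms[[i]] <- res
  }
  aa3 <- names(.AA3)[match(sequence, .AA3)]
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    at <- atoms[[i]]
    data.frame(
      chain = chain, resno = i, resid = aa3[i],
      elety = names(at),
      elesy = substr(names(at), 1L, 1L),
      x = vapply(at, `[`, numeric(1), 1L),
      y = vapply(at, `[`, numeric(1), 2L),
      z = vapply(at, `[`, numeric(1), 3L),
      stringsAsFactors = FALSE
    )
  }))
  rownames(rows) <- NULL
  rows
}
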