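# Amino-acid tables and physical constants used across the package.

#' @keywords internal
.AA1 <- c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
          "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W")

.AA3 <- c(SER = "S", ARG = "R", LEU = "L", PRO = "P", THR = "T",
          ALA = "A", VAL = "V", GLY = "G", ILE = "I", PHE = "F",
          TYR = "Y", CYS = "C", HIS = "H", GLN = "Q", ASN = "N",
          LYS = "K", ASP = "D", GLU = "E", MET = "M", TRP = "W")

# Grantham (1974) amino-acid side-chain properties:
# composition (c), polarity (p), molecular volume (v).
.GRANTHAM_PROPS <- data.frame(
  aa = .AA1,
  c = c(1.42, 0.65, 0.00, 0.39, 0.71, 0.00, 0.00, 0.74, 0.00, 0.00,
        0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0.00, 0.13),
  p = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
        6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
  v = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
        136, 55, 96, 85, 56, 119, 54, 83, 105, 170),
  stringsAsFactors = FALSE
)

# Property weights from the original derivation; the global scale factor is
# fixed at run time so the mean over the 190 unordered pairs equals 100.
.GRANTHAM_ALPHA <- 1.833
.GRANTHAM_BETA  <- 0.1018
.GRANTHAM_GAMMA <- 0.000399

# Published 20x20 Grantham distance matrix, upper triangle by row in the
# order of .AA1 (S R L P T A V G I F Y C H Q N K D E M W).
.GRANTHAM_UPPER <- c(
  # S vs R L P T A V G I F Y C H Q N K D E M W
  110, 145,  74,  58,  99, 124,  56, 142, 155, 144, 112,  89,  68,  46, 121,  65,  80, 135, 177,
  # R
  102, 103,  71, 112,  96, 125,  97,  97,  77, 180,  29,  43,  86,  26,  96,  54,  91, 101,
  # L
   98,  92,  96,  32, 138,   5,  22,  36, 198,  99, 113, 153, 107, 172, 138,  15,  61,
  # P
   38,  27,  68,  42,  95, 114, 110, 169,  77,  76,  91, 103, 108,  93,  87, 147,
  # T
   58,  69,  59,  89, 103,  92, 149,  47,  42,  65,  78,  85,  65,  81, 128,
  # A
   64,  60,  94, 113, 112, 195,  86,  91, 111, 106, 126, 107,  84, 148,
  # V
  109,  29,  50,  55, 192,  84,  96, 133,  97, 152, 121,  21,  88,
  # G
  135, 153, 147, 159,  98,  87,  80, 127,  94,  98, 127, 184,
  # I
   21,  33, 198,  94, 109, 149, 102, 168, 134,  10,  61,
  # F
   22, 205, 100, 116, 158, 102, 177, 140,  28,  40,
  # Y
  194,  83,  99, 143,  85, 160, 122,  36,  37,
  # C
  174, 154, 139, 202, 154, 170, 196, 215,
  # H
   24,  68,  32,  81,  40,  87, 115,
  # Q
   46,  53,  61,  29, 101, 130,
  # N
   94,  23,  42, 142, 174,
  # K
  101,  56,  95, 110,
  # D
   45, 160, 181,
  # E
  126, 152,
  # M
   67
)

.buildGranthamMatrix <- function() {
  m <- matrix(0, 20, 20, dimnames = list(.AA1, .AA1))
  k <- 1L
  for (i in seq_len(19L)) {
    for (j in seq.int(i + 1L, 20L)) {
      m[i, j] <- m[j, i] <- .GRANTHAM_UPPER[k]
      k <- k + 1L
    }
  }
  m
}

.GRANTHAM_MATRIX <- .buildGranthamMatrix()

# Van der Waals radii per element (Angstrom), used for stabilization-center
# contact detection and as Shrake-Rupley atom radii.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
.VDW_DEFAULT <- 1.70

# Theoretical maximum accessible surface areas (A^2) per residue from the
# Tien et al. (2013) tripeptide calculation, used as the published option for
# RSA normalization.
.MAX_ACC_TIEN2013 <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  E = 223.0, Q = 225.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
)

.DSSP_CODES <- c("G", "H", "I", "E", "T", "B", "S", "C")

.checkAA <- function(aa, arg = "amino acid") {
  aa <- toupper(as.character(aa))
  bad <- !(aa %in% .AA1)
  if (any(bad)) {
    stop(sprintf("non-standard %s code(s): %s", arg,
                 paste(unique(aa[bad]), collapse = ", ")), call. = FALSE)
  }
  aa
}
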