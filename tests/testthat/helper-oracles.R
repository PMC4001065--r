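# Independent oracles used to cross-check the package implementations.
# These deliberately reimplement each quantity by a different route.

# Monte-Carlo solvent-accessible surface area: uniformly random points on
# each expanded atom sphere (independent of the deterministic golden-spiral
# integration used by the package).
oracleSASA <- function(structure, probe = 1.4, nPoints = 12000,
                       seed = 1234) {
  set.seed(seed)
  a <- atomRecords(structure)
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
  r <- unname(radii[a$elesy])
  r[is.na(r)] <- 1.70
  re <- r + probe
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(a)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    u <- matrix(stats::rnorm(nPoints * 3), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * re[i], 2, xyz[i, ], "+")
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (re[i] + re)^2 & seq_len(n) != i)
    acc <- rep(TRUE, nPoints)
    for (j in nb) {
      dj <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
            (pts[, 3] - xyz[j, 3])^2
      acc <- acc & dj >= re[j]^2
    }
    areas[i] <- 4 * pi * re[i]^2 * mean(acc)
  }
  key <- paste(a$chain, a$resno)
  res <- rowsum(areas, key, reorder = FALSE)
  data.frame(chain = a$chain[!duplicated(key)],
             resno = a$resno[!duplicated(key)],
             sasa = as.numeric(res[, 1]))
}

# Exact one-tailed Fisher p by enumeration of all tables with the same
# margins, using hypergeometric point masses assembled from choose().
oracleFisher <- function(a, b, c, d, direction = "enriched_in_positive") {
  nPos <- a + b; nPresent <- a + c; N <- a + b + c + d
  if (N == 0) return(1)
  kmin <- max(0, nPos + nPresent - N)
  kmax <- min(nPos, nPresent)
  k <- kmin:kmax
  pk <- choose(nPresent, k) * choose(N - nPresent, nPos - k) /
    choose(N, nPos)
  if (direction == "enriched_in_positive") sum(pk[k >= a]) else
    sum(pk[k <= a])
}

# Textbook pooled-variance two-sample t statistic.
oracleTTest <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Simple linear regression by the normal equations.
oracleRegression <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b1 <- sxy / sxx
  b0 <- mean(y) - b1 * mean(x)
  res <- y - b0 - b1 * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  se <- sqrt(sum(res^2) / (length(x) - 2) / sxx)
  tval <- b1 / se
  list(r_squared = r2, p = 2 * pt(-abs(tval), length(x) - 2))
}

# Exhaustive residue-pair contact scan (distance criterion only), the
# stabilization-center oracle.
oracleSCPairs <- function(structure, minSeqSep = 10, slack = 1.0) {
  a <- atomRecords(structure)
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
  r <- unname(radii[a$elesy]); r[is.na(r)] <- 1.70
  out <- character()
  for (ch in unique(a$chain)) {
    idx <- which(a$chain == ch)
    resnos <- sort(unique(a$resno[idx]))
    for (ii in seq_along(resnos)) {
      for (jj in seq_along(resnos)) {
        if (jj <= ii) next
        ri <- resnos[ii]; rj <- resnos[jj]
        if (abs(rj - ri) < minSeqSep) next
        ai <- idx[a$resno[idx] == ri]; aj <- idx[a$resno[idx] == rj]
        contact <- FALSE
        for (p in ai) for (q in aj) {
          dpq <- sqrt((a$x[p] - a$x[q])^2 + (a$y[p] - a$y[q])^2 +
                      (a$z[p] - a$z[q])^2)
          if (dpq < r[p] + r[q] + slack) { contact <- TRUE; break }
        }
        if (contact) out <- c(out, paste(ch, ri, rj))
      }
    }
  }
  sort(out)
}

# Random rigid-body motion (proper rotation + translation).
randomRigidMotion <- function(structure, seed = 99) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- rnorm(3, 0, 20)
  a <- atomRecords(structure)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% q
  a$x <- xyz[, 1] + shift[1]
  a$y <- xyz[, 2] + shift[2]
  a$z <- xyz[, 3] + shift[3]
  proteinStructure(a, source = "rigid motion")
}

# A small two-strand fixture with long-range residue contacts: an extended
# strand and a translated copy 11 residues downstream, 4.5 A away.
twoStrandFixture <- function() {
  e <- atomRecords(generateToyStructure("extended", 6))
  e2 <- e
  e2$resno <- e2$resno + 11L
  e2$y <- e2$y + 4.5
  proteinStructure(rbind(e, e2), source = "two-strand fixture")
}

# Minimal well-formed variant annotation table written to a temp file.
writeVariantFixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
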