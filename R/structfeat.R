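# Structure-derived categorization: burial, secondary-structure grouping,
# stabilization centers, stability / optimality / dynamics classes.

#' Classify burial from relative solvent accessibility
#'
#' Residues with RSA at or below the cutoff (default 20 percent) are
#' buried; the boundary is inclusive.
#'
#' @param rsa_percent numeric vector of RSA percentages.
#' @param config a \linkS4class{ThresholdConfig}.
#' @return factor with levels \code{buried}, \code{exposed}; \code{NA} where
#'   RSA is missing.
#' @examples
#' classifyBurial(c(2.05, 20, 50))
#' @export
classifyBurial <- function(rsa_percent, config = thresholdConfig()) {
  out <- ifelse(is.na(rsa_percent), NA_character_,
                ifelse(rsa_percent <= config@rsaBuriedMax,
                       "buried", "exposed"))
  factor(out, levels = c("buried", "exposed"))
}

#' Group DSSP secondary-structure codes
#'
#' The 3-, 4- and 5-turn helices (G, H, I) are grouped jointly as helices;
#' extended strand (E) stays alone; T and B (hydrogen-bonding patterns too
#' short for proper secondary structure) are grouped; S (bend) and C (coil)
#' stay alone.
#'
#' @param ss_code character vector of DSSP letters (G,H,I,E,T,B,S,C).
#' @return factor with levels \code{GHI}, \code{E}, \code{TB}, \code{S},
#'   \code{C}; \code{NA} passes through.
#' @export
groupSecondaryStructure <- function(ss_code) {
  ss <- toupper(as.character(ss_code))
  ok <- is.na(ss) | ss %in% .DSSP_CODES
  if (!all(ok))
    stop("invalid DSSP code(s): ", paste(unique(ss[!ok]), collapse = ", "))
  map <- c(G = "GHI", H = "GHI", I = "GHI", E = "E",
           T = "TB", B = "TB", S = "S", C = "C")
  factor(unname(map[ss]), levels = c("GHI", "E", "TB", "S", "C"))
}

#' Classify folding free-energy change (ddG)
#'
#' Four-band categorization of predicted stability change: no change inside
#' the open band (-0.5, 0.5) kcal/mol, mildly stabilizing down to -2
#' (inclusive boundary at -0.5), strongly stabilizing at or below -2,
#' mildly destabilizing from 0.5 (inclusive) up to 4, strongly destabilizing
#' at or above 4.
#'
#' @param ddg numeric vector (kcal/mol, positive = destabilizing).
#' @param config a \linkS4class{ThresholdConfig}.
#' @return factor with levels \code{strong_stabilizing},
#'   \code{mild_stabilizing}, \code{no_change}, \code{mild_destabilizing},
#'   \code{strong_destabilizing}; \code{NA} propagates.
#' @examples
#' classifyStability(c(1.64, -0.41, 4))
#' @export
classifyStability <- function(ddg, config = thresholdConfig()) {
  lo <- config@ddgNoChangeBand[1]
  hi <- config@ddgNoChangeBand[2]
  ss <- config@ddgStrongStabilizingMax
  sd <- config@ddgStrongDestabilizingMin
  out <- rep(NA_character_, length(ddg))
  out[!is.na(ddg) & ddg >= sd] <- "strong_destabilizing"
  out[!is.na(ddg) & ddg >= hi & ddg < sd] <- "mild_destabilizing"
  out[!is.na(ddg) & ddg > lo & ddg < hi] <- "no_change"
  out[!is.na(ddg) & ddg > ss & ddg <= lo] <- "mild_stabilizing"
  out[!is.na(ddg) & ddg <= ss] <- "strong_stabilizing"
  factor(out, levels = c("strong_stabilizing", "mild_stabilizing",
                         "no_change", "mild_destabilizing",
                         "strong_destabilizing"))
}

#' Classify sequence non-optimality (Gamma)
#'
#' Gamma sums the stabilizing ddG values over all possible mutations at a
#' position; a very negative Gamma marks a residue kept for function rather
#' than stability, typically near catalytic or ligand-binding sites.
#'
#' @param gamma numeric vector (kcal/mol).
#' @param config a \linkS4class{ThresholdConfig}.
#' @return factor with levels \code{normal}, \code{highly_nonoptimal}.
#' @export
classifyOptimality <- function(gamma, config = thresholdConfig()) {
  out <- ifelse(is.na(gamma), NA_character_,
                ifelse(gamma <= config@gammaNonoptimalMax,
                       "highly_nonoptimal", "normal"))
  factor(out, levels = c("normal", "highly_nonoptimal"))
}

#' Detect stabilization-center residue pairs
#'
#' A stabilization-center candidate is a pair of residues in the same chain
#' at least \code{minSeqSep} apart in sequence with at least one heavy-atom
#' pair in van der Waals contact, i.e. inter-atomic distance below the sum
#' of the two vdW radii plus \code{contactSlack} (1.0 Angstrom by default,
#' the original long-range-contact definition). The mutual-contact-fraction
#' and conservation refinements of dedicated servers are not applied;
#' precomputed stabilization-center columns can be consumed instead.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param minSeqSep minimum |residue number| separation (default 10).
#' @param contactSlack Angstrom added to the sum of vdW radii.
#' @param radii named per-element vdW radius table.
#' @return list with \code{pairs} (data.frame chain, resno_i, resno_j,
#'   min_dist, with resno_i < resno_j) and \code{residues} (sorted unique
#'   residue numbers in at least one pair, per chain as a data.frame).
#' @export
detectStabilizationCenters <- function(structure, minSeqSep = 10,
                                       contactSlack = 1.0,
                                       radii = .VDW_RADII) {
  a <- atomRecords(structure)
  pairs <- list()
  for (ch in unique(a$chain)) {
    aa <- a[a$chain == ch, , drop = FALSE]
    xyz <- as.matrix(aa[, c("x", "y", "z")])
    r <- unname(radii[aa$elesy])
    r[is.na(r)] <- .VDW_DEFAULT
    d <- as.matrix(dist(xyz))
    cutoff <- outer(r, r, "+") + contactSlack
    sep <- abs(outer(aa$resno, aa$resno, "-"))
    hit <- which(d < cutoff & sep >= minSeqSep & upper.tri(d),
                 arr.ind = TRUE)
    if (nrow(hit)) {
      ri <- pmin(aa$resno[hit[, 1]], aa$resno[hit[, 2]])
      rj <- pmax(aa$resno[hit[, 1]], aa$resno[hit[, 2]])
      dd <- d[hit]
      key <- paste(ri, rj)
      best <- tapply(dd, key, min)
      uk <- !duplicated(key)
      ord <- order(ri[uk], rj[uk])
      pairs[[ch]] <- data.frame(
        chain = ch,
        resno_i = ri[uk][ord], resno_j = rj[uk][ord],
        min_dist = as.numeric(best[key[uk]])[ord],
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(chain = character(), resno_i = integer(),
               resno_j = integer(), min_dist = numeric())
  rownames(pairs) <- NULL
  res <- unique(data.frame(
    chain = rep(pairs$chain, 2L),
    resno = c(pairs$resno_i, pairs$resno_j)))
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  rownames(res) <- NULL
  list(pairs = pairs, residues = res)
}

#' Empirical tail cutoffs from a pooled score distribution
#'
#' Returns the requested lower/upper percentiles (linear interpolation
#' between order statistics) of the pooled values; classification then
#' flags values at or below the lower cutoff or at or above the upper one.
#' With fewer than \code{minN} non-missing values the supplied fixed
#' fallback cutoffs are returned instead, with a message.
#'
#' @param values numeric vector (NA allowed).
#' @param lowerPct,upperPct tail percentiles, e.g. 2.5 and 97.5.
#' @param fallback numeric (lower, upper) fixed cutoffs used when data are
#'   too few; \code{NULL} to error instead.
#' @param minN minimum non-missing values for empirical derivation.
#' @return named numeric vector \code{c(lower = ..., upper = ...)}.
#' @export
deriveEmpiricalThresholds <- function(values, lowerPct, upperPct,
                                      fallback = NULL, minN = 40) {
  v <- values[!is.na(values)]
  if (length(v) < minN) {
    if (is.null(fallback))
      stop(sprintf("only %d non-missing values (< %d) and no fallback cutoffs",
                   length(v), minN))
    message(sprintf(
      "deriveEmpiricalThresholds: only %d non-missing values (< %d); using fixed fallback cutoffs",
      length(v), minN))
    return(c(lower = fallback[1], upper = fallback[2]))
  }
  q <- stats::quantile(v, probs = c(lowerPct, upperPct) / 100,
                       type = 7, names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Tail classification of dynamics and flexibility scores
#'
#' Flags residues in the extreme tails of the pooled distributions of
#' normalized B-factor, normalized RMSF and P(Flexible). Boundaries are
#' inclusive: at or below the lower cutoff is highly rigid (conformationally
#' rigid for P(Flexible)), at or above the upper cutoff is highly dynamic
#' (conformationally flexible).
#'
#' @param ann data.frame/\code{DataFrame} with columns \code{bfactor_norm},
#'   \code{rmsf_norm}, \code{p_flexible} (any may be absent), or a
#'   \linkS4class{VariantCohort}.
#' @param config a \linkS4class{ThresholdConfig}; supplies tail percentiles
#'   and fixed fallbacks.
#' @param cutoffs optional named list with elements \code{bfactor},
#'   \code{rmsf}, \code{pflex}, each \code{c(lower, upper)}; when absent the
#'   cutoffs are derived from the pooled column values.
#' @return data.frame with factor columns \code{dynamics_class_b},
#'   \code{dynamics_class_rmsf} (levels normal/highly_rigid/highly_dynamic)
#'   and \code{flexibility_class} (levels normal/conformationally_rigid/
#'   conformationally_flexible), plus the cutoffs used as an attribute
#'   \code{"cutoffs"}.
#' @export
classifyDynamicsFlexibility <- function(ann, config = thresholdConfig(),
                                        cutoffs = NULL) {
  if (is(ann, "VariantCohort")) ann <- variantData(ann)
  ann <- as.data.frame(ann)
  n <- nrow(ann)
  col <- function(nm) if (nm %in% colnames(ann)) ann[[nm]] else
    rep(NA_real_, n)
  bf <- col("bfactor_norm"); rm <- col("rmsf_norm"); pf <- col("p_flexible")
  if (is.null(cutoffs)) {
    cutoffs <- list(
      bfactor = deriveEmpiricalThresholds(bf, config@bfactorTails[1],
        config@bfactorTails[2], config@bfactorFallback, config@minEmpiricalN),
      rmsf = deriveEmpiricalThresholds(rm, config@rmsfTails[1],
        config@rmsfTails[2], config@rmsfFallback, config@minEmpiricalN),
      pflex = deriveEmpiricalThresholds(pf, config@pflexTails[1],
        config@pflexTails[2], config@pflexFallback, config@minEmpiricalN))
  }
  tailClass <- function(x, cut, levs) {
    out <- rep(NA_character_, length(x))
    ok <- !is.na(x)
    out[ok] <- levs[1]
    out[ok & x <= cut[1]] <- levs[2]
    out[ok & x >= cut[2]] <- levs[3]
    factor(out, levels = levs)
  }
  res <- data.frame(
    dynamics_class_b = tailClass(bf, cutoffs$bfactor,
      c("normal", "highly_rigid", "highly_dynamic")),
    dynamics_class_rmsf = tailClass(rm, cutoffs$rmsf,
      c("normal", "highly_rigid", "highly_dynamic")),
    flexibility_class = tailClass(pf, cutoffs$pflex,
      c("normal", "conformationally_rigid", "conformationally_flexible")))
  attr(res, "cutoffs") <- cutoffs
  res
}
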