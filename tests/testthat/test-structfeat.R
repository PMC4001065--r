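test_that("burial classification is boundary-inclusive at 20 percent", {
  cls <- classifyBurial(c(2.05, 20, 50, NA))
  expect_identical(as.character(cls), c("buried", "buried", "exposed", NA))
})

test_that("secondary-structure codes group as GHI/E/TB/S/C", {
  expect_identical(as.character(groupSecondaryStructure(
    c("G", "H", "I", "E", "T", "B", "S", "C"))),
    c("GHI", "GHI", "GHI", "E", "TB", "TB", "S", "C"))
  expect_error(groupSecondaryStructure("Z"), "invalid")
})

test_that("stability bands follow the four-level ddG categorization", {
  got <- classifyStability(c(1.64, -0.41, 4, 0.5, -0.5, -2, -3, 0, 3.99))
  expect_identical(as.character(got), c(
    "mild_destabilizing", "no_change", "strong_destabilizing",
    "mild_destabilizing", "mild_stabilizing", "strong_stabilizing",
    "strong_stabilizing", "no_change", "mild_destabilizing"))
  expect_true(is.na(classifyStability(NA_real_)[1]))
})

test_that("stability/burial/optimality are gapless monotone step functions", {
  ddg <- seq(-6, 8, length.out = 100000)
  cls <- classifyStability(ddg)
  expect_false(anyNA(cls))
  # class index is non-decreasing in ddg and visits every band once
  expect_true(all(diff(as.integer(cls)) >= 0))
  expect_identical(nlevels(droplevels(cls)), 5L)
  rsa <- seq(0, 120, length.out = 50000)
  bcl <- classifyBurial(rsa)
  expect_false(anyNA(bcl))
  expect_true(all(diff(as.integer(bcl)) >= 0))
  gam <- seq(-12, 3, length.out = 50000)
  ocl <- classifyOptimality(gam)
  expect_false(anyNA(ocl))
  expect_true(all(diff(as.integer(ocl)) <= 0))
})

test_that("optimality flags Gamma at or below -5 kcal/mol", {
  got <- classifyOptimality(c(-5.2, -4.14, 0, -5))
  expect_identical(as.character(got),
                   c("highly_nonoptimal", "normal", "normal",
                     "highly_nonoptimal"))
})

test_that("empirical thresholds match a sort-and-interpolate oracle", {
  v <- 1:1000
  got <- deriveEmpiricalThresholds(v, 2.5, 97.5)
  # linear interpolation between order statistics
  h <- function(p) { x <- 1 + p * 999; lo <- floor(x); lo + (x - lo) }
  expect_equal(unname(got), c(h(0.025), h(0.975)))
  # degenerate constant input: both cutoffs collapse to the constant
  const <- deriveEmpiricalThresholds(rep(3.3, 100), 2.5, 97.5)
  expect_equal(unname(const), c(3.3, 3.3))
  # large uniform sample sits near the nominal quantiles
  set.seed(11)
  u <- runif(10000)
  gu <- deriveEmpiricalThresholds(u, 2.5, 97.5)
  expect_lt(abs(gu[["lower"]] - 0.025), 0.01)
  expect_lt(abs(gu[["upper"]] - 0.975), 0.01)
})

test_that("too few values fall back to the fixed cutoffs with a message", {
  expect_message(
    got <- deriveEmpiricalThresholds(rnorm(10), 2.5, 97.5,
                                     fallback = c(-0.537, 1.17)),
    "fallback")
  expect_equal(unname(got), c(-0.537, 1.17))
  expect_error(deriveEmpiricalThresholds(rnorm(10), 2.5, 97.5), "fallback")
})

test_that("tail flags are boundary-inclusive at the fixed cutoffs", {
  ann <- data.frame(bfactor_norm = c(-0.60, -0.537, 0, 1.17, 2),
                    rmsf_norm = c(-0.607, 0, 0, 1.195, 0),
                    p_flexible = c(0.1, 0.158, 0.5, 0.860, 0.90))
  cfg <- thresholdConfig()
  got <- classifyDynamicsFlexibility(ann, cfg, cutoffs = list(
    bfactor = cfg@bfactorFallback, rmsf = cfg@rmsfFallback,
    pflex = cfg@pflexFallback))
  expect_identical(as.character(got$dynamics_class_b),
    c("highly_rigid", "highly_rigid", "normal", "highly_dynamic",
      "highly_dynamic"))
  expect_identical(as.character(got$dynamics_class_rmsf),
    c("highly_rigid", "normal", "normal", "highly_dynamic", "normal"))
  expect_identical(as.character(got$flexibility_class),
    c("conformationally_rigid", "conformationally_rigid", "normal",
      "conformationally_flexible", "conformationally_flexible"))
})

test_that("empirical tail coverage is within 1/n of nominal", {
  set.seed(23)
  for (n in c(200, 1000)) {
    v <- rnorm(n)
    cut <- deriveEmpiricalThresholds(v, 2.5, 97.5)
    lo <- mean(v <= cut[["lower"]])
    hi <- mean(v >= cut[["upper"]])
    expect_lte(abs(lo - 0.025), 1 / n + 1e-12)
    expect_lte(abs(hi - 0.025), 1 / n + 1e-12)
  }
})

test_that("stabilization centers need >= 10 residue separation and contact", {
  mk <- function(sep, gap) {
    proteinStructure(data.frame(
      chain = "A", resno = c(1, 1 + sep), resid = "ALA",
      elety = "CB", elesy = "C", x = c(0, gap), y = 0, z = 0))
  }
  # 3.0 A apart with carbon radii 1.7 + 1.7 + 1.0 slack = 4.4 -> contact
  hit <- detectStabilizationCenters(mk(12, 3.0))
  expect_identical(nrow(hit$pairs), 1L)
  expect_identical(hit$pairs$resno_j - hit$pairs$resno_i, 12)
  expect_identical(hit$residues$resno, c(1, 13))
  # same geometry, too close in sequence
  expect_identical(nrow(detectStabilizationCenters(mk(5, 3.0))$pairs), 0L)
  # far apart in space
  expect_identical(nrow(detectStabilizationCenters(mk(12, 20))$pairs), 0L)
})

test_that("stabilization-center detection matches the exhaustive scan and is rigid-motion invariant", {
  s <- twoStrandFixture()
  det <- detectStabilizationCenters(s)
  expect_gt(nrow(det$pairs), 0L)
  got <- sort(paste(det$pairs$chain, det$pairs$resno_i, det$pairs$resno_j))
  expect_identical(got, oracleSCPairs(s))
  moved <- randomRigidMotion(s)
  det2 <- detectStabilizationCenters(moved)
  got2 <- sort(paste(det2$pairs$chain, det2$pairs$resno_i,
                     det2$pairs$resno_j))
  expect_identical(got2, got)
  # a straight helix offers no contacts at >= 10 residue separation
  helix <- generateToyStructure("helix", 30)
  expect_identical(nrow(detectStabilizationCenters(helix)$pairs), 0L)
  expect_identical(oracleSCPairs(helix), character())
})
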