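test_that("cohort generation is byte-deterministic for a fixed seed", {
  spec <- syntheticSpec(nCase = 10, nNegative = 50, nPositive = 20)
  p1 <- tempfile(); p2 <- tempfile()
  writeVariantTable(generateCohort(spec, seed = 42), p1)
  writeVariantTable(generateCohort(spec, seed = 42), p2)
  expect_identical(readLines(p1), readLines(p2))
  p3 <- tempfile()
  writeVariantTable(generateCohort(spec, seed = 43), p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("invalid specifications are rejected", {
  expect_error(syntheticSpec(flagProbPos = 1.2), "probabilities")
  expect_error(syntheticSpec(nCase = -1), "sizes")
})

test_that("thresholded flags derive from the drawn continuous values", {
  cohort <- generateCohort(syntheticSpec(nCase = 20, nNegative = 200,
                                         nPositive = 50), seed = 3)
  v <- as.data.frame(variantData(cohort))
  truth <- cohortMetadata(cohort)$truth
  # destabilizing/buried flags are consequences of the drawn values
  expect_identical(unname(truth$destabilizing), unname(v$ddg >= 0.5))
  expect_identical(unname(truth$buried), unname(v$rsa_percent <= 20))
  # the amino-acid pair realizes the planted Grantham and Gly/Pro flags
  expect_identical(unname(truth$large_grantham),
                   unname(granthamDistance(v$ref_aa, v$alt_aa) >= 100))
  expect_identical(unname(truth$gly_pro_change),
                   unname(isGlyProChange(v$ref_aa, v$alt_aa)))
  # call columns reproduce the planted high-deleterious-count flag
  expect_identical(unname(truth$high_del_count),
                   unname(deleteriousCount(v)$count >= 4))
  # every pipeline column is populated
  need <- c("ddg", "gamma", "bfactor_norm", "rmsf_norm", "p_flexible",
            "rsa_percent", "ss_code", "on_patch", "in_domain", "rvis",
            "composite_score")
  expect_true(all(need %in% colnames(v)))
})

test_that("positives carry a higher score burden than negatives", {
  cohort <- generateCohort(syntheticSpec(nCase = 30, nNegative = 1000,
                                         nPositive = 150), seed = 8)
  suppressMessages(res <- scoreVariants(cohort))
  cls <- classLabels(cohort)
  gap <- mean(sds(res)[cls == "positive"]) -
         mean(sds(res)[cls == "negative"])
  expect_gte(gap, 2)
})

test_that("toy structures have the advertised idealized geometry", {
  helix <- generateToyStructure("helix", 20)
  ca <- subset(atomRecords(helix), elety == "CA")
  span <- sqrt(sum((unlist(ca[20, c("x", "y", "z")]) -
                    unlist(ca[1, c("x", "y", "z")]))^2))
  # ~1.5 A rise per residue along the helical axis
  expect_equal(span / 19, 1.56, tolerance = 0.08)
  ext <- generateToyStructure("extended", 10)
  cae <- subset(atomRecords(ext), elety == "CA")
  d <- sqrt(sum((unlist(cae[10, c("x", "y", "z")]) -
                 unlist(cae[1, c("x", "y", "z")]))^2))
  # extended chain: ~3.4 A axial spacing between consecutive residues
  expect_gt(d / 9, 3.1)
  expect_lt(d / 9, 3.9)
  # consecutive CA-CA distances are the standard ~3.8 A in both
  dca <- sqrt(rowSums((cae[-1, c("x", "y", "z")] -
                       cae[-10, c("x", "y", "z")])^2))
  expect_true(all(abs(dca - 3.8) < 0.15))
  expect_error(generateToyStructure("helix", 2), "at least 3")
})

test_that("null cohorts keep per-feature false selection near alpha", {
  # class-balanced null: every feature independent of the label
  spec <- syntheticSpec(nCase = 0, nNegative = 250, nPositive = 250,
                        flagProbPos = 0.3, flagProbNeg = 0.3,
                        flexProbPos = 0.05, flexProbNeg = 0.05,
                        ddgMeanPos = 0.3, ddgMeanNeg = 0.3,
                        consProbPos = 0.8, consProbNeg = 0.8)
  nrun <- 300
  hits <- matrix(FALSE, nrun, 7,
                 dimnames = list(NULL, deleteriousFeatureNames()))
  for (i in seq_len(nrun)) {
    cohort <- generateCohort(spec, seed = 5000 + i)
    suppressMessages(fv <- buildFeatureVectors(cohort))
    enr <- featureEnrichment(fv, as.character(classLabels(cohort)))
    del <- enr[match(deleteriousFeatureNames(), enr$feature), ]
    hits[i, ] <- del$significant
  }
  rate <- colMeans(hits)
  expect_true(all(rate >= 0.02 & rate <= 0.09))
})
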