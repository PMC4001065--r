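.bundleRow <- function(...) {
  base <- data.frame(gene_symbol = "G1", protein_position = 1,
                     ref_aa = "A", alt_aa = "V", class_label = "case",
                     stringsAsFactors = FALSE)
  args <- list(...)
  for (nm in names(args)) base[[nm]] <- args[[nm]]
  base
}

test_that("feature vectors reproduce the worked high-score examples", {
  # ABCA6 C1359R: 6/6 deleterious, Grantham 180, RSA 2.05, in domain,
  # ddG 1.64, no patch, no Gly/Pro
  a <- .bundleRow(ref_aa = "C", alt_aa = "R", del_count = 6,
                  rsa_percent = 2.05, on_patch = FALSE, in_domain = TRUE,
                  ddg = 1.64)
  suppressMessages(fv <- buildFeatureVectors(a))
  flags <- unlist(fv[1, deleteriousFeatureNames()])
  expect_identical(flags[flags %in% TRUE],
    setNames(rep(TRUE, 5), c("high_del_count", "large_grantham", "buried",
                             "in_domain", "destabilizing")))
  expect_identical(computeSds(fv), 5L)

  # ABHD14A R227G: 0/6 deleterious, Grantham 125, R>G, in domain, ddG 0.87
  b <- .bundleRow(ref_aa = "R", alt_aa = "G", del_count = 0,
                  rsa_percent = NA, on_patch = FALSE, in_domain = TRUE,
                  ddg = 0.87)
  suppressMessages(fvb <- buildFeatureVectors(b))
  expect_identical(computeSds(fvb), 4L)
  expect_true(all(unlist(fvb[1, c("large_grantham", "gly_pro_change",
                                  "in_domain", "destabilizing")])))

  # nothing annotated: all flags missing except the sequence-only ones
  n <- .bundleRow(ref_aa = "A", alt_aa = "V")
  suppressMessages(fvn <- buildFeatureVectors(n))
  expect_identical(fvn$n_missing_features, 5L)  # Grantham/GlyPro always known
  expect_identical(computeSds(fvn), 0L)
})

test_that("the score counts TRUE deleterious-direction flags only", {
  fv <- data.frame(high_del_count = TRUE, large_grantham = TRUE,
                   buried = TRUE, in_domain = TRUE, destabilizing = TRUE,
                   highly_flexible_site = TRUE)
  expect_identical(computeSds(fv), 5L)
  expect_identical(computeSds(data.frame(x = 1)), 0L)
  empty <- data.frame(high_del_count = NA, large_grantham = NA)
  expect_identical(computeSds(empty), 0L)
})

test_that("flipping one flag raises the score by exactly 1 and never demotes", {
  set.seed(13)
  cfg <- thresholdConfig()
  for (i in 1:40) {
    flags <- as.list(sample(c(TRUE, FALSE, NA), 7, replace = TRUE))
    names(flags) <- deleteriousFeatureNames()
    fv <- as.data.frame(flags)
    base <- computeSds(fv)
    off <- which(!(unlist(fv) %in% TRUE))
    if (!length(off)) next
    j <- sample(rep(off, 2), 1)
    fv2 <- fv
    fv2[[j]] <- TRUE
    expect_identical(computeSds(fv2), base + 1L)
    expect_gte(computeSds(fv2), sdsPriorityMin(cfg) * (base >= sdsPriorityMin(cfg)))
  }
})

test_that("gene tolerance partitions on the sign of RVIS", {
  expect_identical(as.character(partitionByTolerance(c(0.26, -0.45, NA))),
                   c("high", "low", "unknown"))
  expect_message(z <- partitionByTolerance(0), "tie-break")
  expect_identical(as.character(z), "high")
})

test_that("flexible-site exclusion only prunes the priority list", {
  cohort <- workedExampleCohort()
  suppressMessages(res <- scoreVariants(cohort))
  tb <- sdsTable(res)
  # the one flagged flexible-site variant is excluded
  expect_identical(tb$gene_symbol[tb$excluded], "PALB2")
  # a non-priority record with the flexible flag is not "excluded"
  v <- as.data.frame(variantData(cohort))
  v$del_count <- 0
  v$ddg <- 0
  v$in_domain <- FALSE
  v$rsa_percent <- 50
  low <- variantCohort(v)
  suppressMessages(res2 <- scoreVariants(low))
  expect_false(any(sdsTable(res2)$excluded))
})

test_that("the final list combines tolerance, exclusion and curation", {
  cohort <- workedExampleCohort()
  suppressMessages(res <- scoreVariants(cohort))
  tb <- sdsTable(res)
  expect_identical(sum(tb$final_priority), 9L)
  # without curated low-tolerance entries only high-tolerance rows remain
  v <- as.data.frame(variantData(cohort))
  v$epilepsy_curation <- "na"
  suppressMessages(res2 <- scoreVariants(variantCohort(v)))
  tb2 <- sdsTable(res2)
  expect_identical(sum(tb2$final_priority), 8L)
  expect_true(all(tb2$tolerance_class[tb2$final_priority] == "high"))
  # curation column absent: low-tolerance branch contributes nothing
  v$epilepsy_curation <- NULL
  expect_message(res3 <- scoreVariants(variantCohort(v)), "curation")
  expect_identical(sum(sdsTable(res3)$final_priority), 8L)
  # empty input stays empty
  empty <- variantCohort(as.data.frame(variantData(cohort))[0, ])
  suppressMessages(res4 <- scoreVariants(empty))
  expect_identical(length(res4), 0L)
})

test_that("re-scoring a round-tripped cohort is idempotent", {
  cohort <- generateCohort(syntheticSpec(nCase = 20, nNegative = 100,
                                         nPositive = 30), seed = 17)
  res1 <- scoreVariants(cohort)
  path <- tempfile(fileext = ".tsv")
  writeVariantTable(cohort, path)
  res2 <- scoreVariants(readVariantTable(path))
  expect_identical(sds(res2), sds(res1))
  expect_identical(sdsTable(res2)$final_priority,
                   sdsTable(res1)$final_priority)
})

test_that("step-wise correlation matches the normal-equations oracle", {
  cohort <- generateCohort(syntheticSpec(nCase = 0, nNegative = 40,
                                         nPositive = 20), seed = 19)
  res <- scoreVariants(cohort)
  sw <- stepwiseCorrelation(res)
  expect_identical(sw$dropped_component,
                   c("none", deleteriousFeatureNames()))
  ref <- oracleRegression(sds(res),
                          as.data.frame(sdsTable(res))$composite_score)
  expect_equal(sw$r_squared[1], ref$r_squared, tolerance = 1e-10)
  expect_equal(sw$p[1], ref$p, tolerance = 1e-10)
  expect_true(all(sw$n_changed[-1] >= 0))

  # composite equal to the score itself: perfect fit (R warns that the
  # fit is exact, which is the point here)
  perfect <- suppressWarnings(stepwiseCorrelation(res, composite = sds(res)))
  expect_equal(perfect$r_squared[1], 1, tolerance = 1e-12)
  expect_lt(perfect$p[1], 1e-12)

  # too few paired values
  expect_error(stepwiseCorrelation(res, composite = c(1, 2, rep(NA, length(res) - 2))),
               "at least 3")
})
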