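test_that("one-tailed Fisher p matches closed forms and conventions", {
  # the single most-extreme table: p is one point mass
  expect_equal(fisherOneTailed(10, 0, 0, 10), 1 / choose(20, 10))
  # equal proportions cannot be enriched
  expect_gte(fisherOneTailed(5, 5, 5, 5), 0.5)
  # empty table -> 1 by convention, with a message
  expect_message(p <- fisherOneTailed(0, 0, 0, 0), "convention")
  expect_identical(p, 1)
})

test_that("Fisher p equals brute-force enumeration on random tables", {
  set.seed(101)
  for (i in 1:60) {
    tb <- rpois(4, 4)
    for (dir in c("enriched_in_positive", "enriched_in_negative")) {
      expect_equal(fisherOneTailed(tb[1], tb[2], tb[3], tb[4], dir),
                   oracleFisher(tb[1], tb[2], tb[3], tb[4], dir),
                   tolerance = 1e-12)
    }
  }
})

test_that("pooled t-test follows the textbook formula with df = n - 2", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  y <- c(2.0, 2.9, 1.1, 0.7, 3.3, 2.8)
  got <- ttestUnpaired(x, y)
  ref <- oracleTTest(x, y)
  expect_equal(got$t, ref$t, tolerance = 1e-10)
  expect_identical(got$df, 9L)
  expect_equal(got$p, ref$p, tolerance = 1e-10)
  # identical samples: t = 0, p = 1
  same <- ttestUnpaired(x, x)
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  # constant equal samples hit the zero-variance convention
  z <- ttestUnpaired(rep(2, 5), rep(2, 4))
  expect_identical(z$t, 0)
  expect_identical(z$p, 1)
  # a three-pooled-SD shift is overwhelming at large n
  set.seed(5)
  expect_lt(ttestUnpaired(rnorm(200), rnorm(200, 3))$p, 1e-4)
})

test_that("feature enrichment recovers planted contrasts and directions", {
  cohort <- generateCohort(syntheticSpec(nCase = 0, nNegative = 1000,
                                         nPositive = 200), seed = 21)
  suppressMessages(fv <- buildFeatureVectors(cohort))
  enr <- featureEnrichment(fv, as.character(classLabels(cohort)))
  expect_identical(nrow(enr), 10L)
  # margins add up to the tested cohort sizes
  expect_true(all(enr$a + enr$b <= 200))
  expect_true(all(enr$c + enr$d <= 1000))
  expect_true(all(enr$p > 0 & enr$p <= 1))
  sel <- selectDeleteriousFeatures(enr)
  expect_identical(sel$deleterious, deleteriousFeatureNames())
})

test_that("feature selection is invariant to row order", {
  cohort <- generateCohort(syntheticSpec(nCase = 10, nNegative = 400,
                                         nPositive = 100), seed = 31)
  suppressMessages(fv <- buildFeatureVectors(cohort))
  cls <- as.character(classLabels(cohort))
  sel1 <- selectDeleteriousFeatures(featureEnrichment(fv, cls))
  set.seed(1)
  perm <- sample(nrow(fv))
  sel2 <- selectDeleteriousFeatures(featureEnrichment(fv[perm, ], cls[perm]))
  expect_identical(sel1, sel2)
})

test_that("with no class contrast the deleterious set is usually empty", {
  spec <- syntheticSpec(nCase = 0, nNegative = 300, nPositive = 300,
                        flagProbPos = 0.2, flagProbNeg = 0.2,
                        flexProbPos = 0.05, flexProbNeg = 0.05,
                        ddgMeanPos = 0.3, ddgMeanNeg = 0.3,
                        consProbPos = 0.8, consProbNeg = 0.8)
  hits <- 0L
  for (seed in 1:10) {
    cohort <- generateCohort(spec, seed = seed)
    suppressMessages(fv <- buildFeatureVectors(cohort))
    enr <- featureEnrichment(fv, as.character(classLabels(cohort)))
    sel <- suppressWarnings(selectDeleteriousFeatures(enr))
    hits <- hits + length(sel$deleterious)
  }
  # 70 feature tests at alpha = 0.05: false selections should be few
  expect_lte(hits, 10L)
})
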