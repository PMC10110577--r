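pH0 <- 0.000115
pW0 <- 0.046

test_that("theoretical ratios at zero enrichment are the natural ratios", {
  comp <- oracleFixtures()[[2]]
  nat <- isoValues(naturalIsotopeDistribution(comp))
  n <- comp@nExchangeable
  expect_equal(theoreticalRatio("A1/A0", 0, nat, n), nat[2] / nat[1])
  expect_equal(theoreticalRatio("A2/A1", 0, nat, n), nat[3] / nat[2])
  expect_equal(theoreticalRatio(c(2, 0), 0, nat, n), nat[3] / nat[1])
})

test_that("theoretical ratios equal convolution-oracle ratios", {
  comp <- oracleFixtures()[[1]]  # GG-like, N_EH = 4
  nat <- isoValues(naturalIsotopeDistribution(comp))
  o <- isoValues(oracleLabeledDistribution(comp, 0.02))
  expect_equal(theoreticalRatio("A1/A0", 0.02, nat, 4), o[2] / o[1],
               tolerance = 1e-9)
  expect_equal(theoreticalRatio("A2/A1", 0.02, nat, 4), o[3] / o[2],
               tolerance = 1e-9)
})

test_that("closed-form A2/A1 ratio is consistent with the generic path", {
  for (comp in oracleFixtures()[c(1, 3, 5)]) {
    nat <- isoValues(naturalIsotopeDistribution(comp))
    n <- comp@nExchangeable
    for (px in c(0.001, 0.01, 0.03, 0.045)) {
      expect_equal(closedFormRatioA2A1(px, nat, n),
                   theoreticalRatio("A2/A1", px, nat, n),
                   tolerance = 1e-10)
    }
  }
})

test_that("pair and full-profile estimators invert noiseless data", {
  # real peptide compositions spanning N_EH from ~2 to ~40
  ladder <- c("LIK", "AVK", "AAGK", "AEFVEVTK", "HLVDEPQNLIK",
              "AAAAAAAAAAK")
  pxGrid <- seq(0, 0.045, by = 0.005)
  for (s in ladder) {
    comp <- peptideComposition(s)
    neh <- nExchangeable(comp)
    nat <- isoValues(naturalIsotopeDistribution(comp))
    for (px in pxGrid) {
      prof <- isoValues(labeledIsotopomerRias(nat, px, neh)) * 5e5
      for (pair in c("A1/A0", "A2/A0", "A2/A1")) {
        ij <- switch(pair, "A1/A0" = c(2, 1), "A2/A0" = c(3, 1),
                     "A2/A1" = c(3, 2))
        est <- estimateEnrichmentFromPair(prof[ij[1]], prof[ij[2]], pair,
                                          nat, neh)
        expect_lt(abs(enrichment(est) - px), 1e-5)
      }
      full <- estimateEnrichmentFullProfile(prof, nat, neh)
      expect_lt(abs(enrichment(full) - px), 1e-5)
    }
  }
})

test_that("unlabeled profiles give zero enrichment with zero residual", {
  comp <- oracleFixtures()[[2]]
  nat <- isoValues(naturalIsotopeDistribution(comp))
  est <- estimateEnrichmentFromPair(nat[2], nat[1], "A1/A0", nat,
                                    comp@nExchangeable)
  expect_lt(enrichment(est), 1e-7)
  expect_lt(est@objectiveResidual, 1e-9)
  full <- estimateEnrichmentFullProfile(nat, nat, comp@nExchangeable)
  expect_identical(enrichment(full), 0)
  expect_false(full@atBoundary)
})

test_that("contamination on the monoisotope spares the A2/A1 estimate", {
  comp <- oracleFixtures()[[1]]
  nat <- isoValues(naturalIsotopeDistribution(comp))
  neh <- comp@nExchangeable
  px <- 0.03
  prof <- isoValues(oracleLabeledDistribution(comp, px))
  contaminated <- prof
  contaminated[1] <- contaminated[1] * 1.5
  est21 <- estimateEnrichmentFromPair(contaminated[3], contaminated[2],
                                      "A2/A1", nat, neh)
  expect_lt(abs(enrichment(est21) - px), 1e-5)
  est10 <- estimateEnrichmentFromPair(contaminated[2], contaminated[1],
                                      "A1/A0", nat, neh)
  expect_lt(enrichment(est10), px)  # inflated denominator biases low
  # pairs not involving the contaminated channel stay unbiased
  biases <- vapply(oracleFixtures()[1:3], function(cmp) {
    natc <- isoValues(naturalIsotopeDistribution(cmp))
    p <- isoValues(oracleLabeledDistribution(cmp, px))
    p[1] <- p[1] + 0.2 * max(p)
    e <- estimateEnrichmentFromPair(p[3], p[2], "A2/A1", natc,
                                    cmp@nExchangeable)
    enrichment(e) - px
  }, numeric(1))
  expect_lt(abs(mean(biases)), 1e-6)
})

test_that("bounded minimizer matches a dense grid search", {
  comp <- peptideComposition("AEFVEVTK")
  nat <- isoValues(naturalIsotopeDistribution(comp))
  neh <- nExchangeable(comp)
  grid <- seq(0, pW0, by = 1e-5)
  for (px in c(0.007, 0.0213, 0.0441)) {
    robs <- theoreticalRatio("A2/A1", px, nat, neh)
    gridVals <- abs(vapply(grid, function(p)
      theoreticalRatio("A2/A1", p, nat, neh), numeric(1)) - robs)
    gridBest <- grid[which.min(gridVals)]
    est <- estimateEnrichmentFromPair(robs, 1, "A2/A1", nat, neh)
    expect_lt(abs(enrichment(est) - gridBest), 1e-5 + 1e-9)
  }
})

test_that("reconstruction round-trips the forward monoisotope", {
  for (comp in oracleFixtures()[c(2, 4)]) {
    nat <- isoValues(naturalIsotopeDistribution(comp))
    neh <- comp@nExchangeable
    for (px in c(0.005, 0.02, 0.04)) {
      prof <- isoValues(labeledIsotopomerRias(nat, px, neh))
      est <- estimateEnrichmentFromPair(prof[2], prof[1], "A1/A0", nat, neh)
      rec <- reconstructMonoisotopicRia(enrichment(est), nat[1], neh)
      expect_lt(abs(rec - prof[1]), 1e-6)
    }
  }
})

test_that("reconstruction endpoints match the definition and the plateau", {
  expect_equal(reconstructMonoisotopicRia(0, 0.5, 20), 0.5)
  expect_equal(reconstructMonoisotopicRia(0.046, 0.5, 20),
               asymptoticRia(0.5, 20, 0.046))
  expect_equal(reconstructMonoisotopicRia(0.03, 0.5, 20, 0.000115),
               0.5 * (1 - 0.03 / (1 - 0.000115))^20)
})

test_that("unreachable ratios clip to the boundary and are flagged", {
  comp <- oracleFixtures()[[1]]
  nat <- isoValues(naturalIsotopeDistribution(comp))
  neh <- comp@nExchangeable
  rMax <- theoreticalRatio("A1/A0", pW0, nat, neh)
  est <- estimateEnrichmentFromPair(10 * rMax, 1, "A1/A0", nat, neh)
  expect_equal(enrichment(est), pW0, tolerance = 1e-6)
  expect_true(est@atBoundary)
  expect_gt(est@objectiveResidual, 0)
})

test_that("non-positive abundances invalidate the estimate", {
  comp <- oracleFixtures()[[1]]
  nat <- isoValues(naturalIsotopeDistribution(comp))
  est <- estimateEnrichmentFromPair(0, 1, "A1/A0", nat, 4)
  expect_false(est@valid)
  full <- estimateEnrichmentFullProfile(rep(0, 6), nat, 4)
  expect_false(full@valid)
})
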