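pH0 <- 0.000115

test_that("single atoms and empty compositions give the trivial patterns", {
  h <- makeComposition(c(H = 1), 0)
  expect_equal(isoValues(naturalIsotopeDistribution(h)),
               c(1 - pH0, pH0, 0, 0, 0, 0))
  empty <- makeComposition(stats::setNames(numeric(0), character(0)), 0)
  expect_equal(isoValues(naturalIsotopeDistribution(empty)),
               c(1, 0, 0, 0, 0, 0))
})

test_that("natural distribution matches the atom-wise enumeration oracle", {
  probs <- naturalElementProbs()
  for (comp in oracleFixtures()[1:3]) {
    ref <- pad6(atomwiseDistribution(
      comp@elementCounts[comp@elementCounts > 0], probs))
    got <- isoValues(naturalIsotopeDistribution(comp))
    expect_lt(max(abs(got - ref)), 1e-12)
  }
})

test_that("b coefficients match hand evaluation", {
  expect_equal(bCoefficient(1, 4, 0, 0), 0)
  p <- 0.03
  expect_equal(bCoefficient(1, 1, p, 0), p / (1 - p))
  expect_equal(bCoefficient(2, 10, 0.02, 0.000115),
               45 * (0.020115 / 0.979885)^2)
  expect_error(bCoefficient(1, 4, 0.6, 0.5), "pH \\+ pX")
})

test_that("c coefficients match hand evaluation", {
  expect_equal(cCoefficient(1, 7, 0), 0)
  ph <- 0.000115
  expect_equal(cCoefficient(1, 1, ph), ph / (1 - ph))
  expect_equal(cCoefficient(3, 5, ph), choose(7, 3) * (ph / (1 - ph))^3)
})

test_that("labeled RIAs reduce to the natural profile at zero enrichment", {
  for (comp in oracleFixtures()) {
    nat <- isoValues(naturalIsotopeDistribution(comp))
    out <- isoValues(labeledIsotopomerRias(nat, 0, comp@nExchangeable))
    expect_equal(out, nat, tolerance = 1e-14)
    # continuity: tiny enrichment stays near natural
    near <- isoValues(labeledIsotopomerRias(nat, 1e-10, comp@nExchangeable))
    expect_lt(max(abs(near - nat)), 1e-8)
  }
})

test_that("monoisotope follows the closed-form depletion for N_EH = 1", {
  comp <- makeComposition(c(C = 3, H = 6, N = 1, O = 2, S = 0), 1)
  nat <- isoValues(naturalIsotopeDistribution(comp))
  px <- 0.03
  out <- isoValues(labeledIsotopomerRias(nat, px, 1))
  expect_equal(out[1], nat[1] * (1 - px / (1 - pH0)), tolerance = 1e-14)
})

test_that("analytic dynamics agree with the convolution oracle", {
  for (comp in oracleFixtures()) {
    nat <- isoValues(naturalIsotopeDistribution(comp))
    for (px in c(0.01, 0.02, 0.046)) {
      analytic <- isoValues(labeledIsotopomerRias(nat, px,
                                                  comp@nExchangeable))
      oracle <- isoValues(oracleLabeledDistribution(comp, px))
      expect_lt(max(abs(analytic - oracle)), 1e-9)
    }
  }
})

test_that("package oracle agrees with the independent atom-wise oracle", {
  comp <- oracleFixtures()[[1]]
  for (px in c(0, 0.03)) {
    ref <- pad6(atomwiseLabeled(comp@elementCounts[comp@elementCounts > 0],
                                comp@nExchangeable, px))
    got <- isoValues(oracleLabeledDistribution(comp, px))
    expect_lt(max(abs(got - ref)), 1e-12)
  }
})

test_that("oracle reproduces the two-hydrogen binomial closed form", {
  comp <- makeComposition(c(H = 2), 2)
  px <- 0.3
  got <- isoValues(oracleLabeledDistribution(comp, px, pH = 1e-12))
  expect_equal(got[1:3],
               c((1 - px)^2, 2 * px * (1 - px), px^2), tolerance = 1e-9)
  expect_error(
    oracleLabeledDistribution(makeComposition(c(H = 4), 2.5), 0.02),
    "integer")
})

test_that("six-isotopomer truncation retains >= 99% of mass below 1800 Da", {
  panel <- c("LVNELTEFAK", "YLYEIAR", "AEFVEVTK", "TVMENFVAFVDK",
             "HLVDEPQNLIK", "GITWGEETLMEYLENPK")
  for (s in panel) {
    comp <- peptideComposition(s)
    if (monoisotopicMass(comp) >= 1800) next
    nat <- isoValues(naturalIsotopeDistribution(comp))
    expect_gte(sum(nat), 0.99)
    atPlateau <- isoValues(labeledIsotopomerRias(nat, 0.046,
                                                 comp@nExchangeable))
    expect_gte(sum(atPlateau), 0.99)
    beyond <- isoValues(labeledIsotopomerRias(nat, 0.05,
                                              comp@nExchangeable))
    expect_gte(sum(beyond), 0.985)
  }
})

test_that("I0 decreases and I1/I0, I2/I0 increase with enrichment", {
  grid <- seq(0, 0.046, length.out = 24)
  for (comp in oracleFixtures()[c(1, 3, 5)]) {
    nat <- isoValues(naturalIsotopeDistribution(comp))
    mats <- vapply(grid, function(p)
      isoValues(labeledIsotopomerRias(nat, p, comp@nExchangeable)),
      numeric(6))
    expect_true(all(diff(mats[1, ]) < 0))
    expect_true(all(diff(mats[2, ] / mats[1, ]) > 0))
    expect_true(all(diff(mats[3, ] / mats[1, ]) > 0))
  }
})
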