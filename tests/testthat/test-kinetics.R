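pH0 <- 0.000115
pW0 <- 0.046

test_that("asymptotic RIA endpoints and consistency with reconstruction", {
  expect_equal(asymptoticRia(0.6, 25, 0), 0.6)
  expect_equal(asymptoticRia(0.6, 0, pW0), 0.6)
  direct <- 0.6 * (1 - pW0 / (1 - pH0))^25
  expect_equal(asymptoticRia(0.6, 25, pW0, pH0), direct)
  expect_equal(asymptoticRia(0.6, 25, pW0, pH0),
               reconstructMonoisotopicRia(pW0, 0.6, 25, pH0))
})

test_that("noiseless exponential decay is recovered to machine precision", {
  k <- 0.135
  times <- c(0, 1, 3, 7, 14, 21)
  i0z <- 0.55; i0a <- 0.21
  ria <- i0a + (i0z - i0a) * exp(-k * times)
  fit <- fitExponentialDecay(times, ria, i0z, i0a)
  expect_lt(abs(rateConstant(fit) - k), 1e-9)
  expect_equal(unname(goodnessOfFit(fit)["r_squared"]), 1, tolerance = 1e-12)
  ci <- confint(fit)
  expect_lte(ci[["low"]], rateConstant(fit))
  expect_gte(ci[["high"]], rateConstant(fit))
})

test_that("a constant series yields k = 0 and is flagged", {
  times <- c(0, 1, 3, 7)
  fit <- fitExponentialDecay(times, rep(0.5, 4), 0.5, 0.2)
  expect_identical(rateConstant(fit), 0)
  expect_true(fit@flagged)
})

test_that("degenerate series are rejected", {
  fit <- fitExponentialDecay(c(3, 3, 3), c(0.5, 0.4, 0.45), 0.5, 0.2)
  expect_true(fit@flagged)
  expect_identical(fit@nPoints, 0L)
  bad <- fitExponentialDecay(c(0, 1, 3), c(0.5, 0.4, 0.3), 0.2, 0.5)
  expect_true(bad@flagged)  # anchors inverted
})

test_that("all methods agree on clean data and full profile wins ties", {
  cfg <- simulationConfig(noiseCv = 0, seed = 7)
  sim <- simulateTimeCourse(cfg)
  pep <- cfg$peptides[4, ]  # k = 0.135
  tc <- sim$quant[sim$quant$peptide == pep$sequence, ]
  comp <- peptideComposition(pep$sequence, pep$charge)
  res <- fitAllMethods(tc, comp)
  ks <- vapply(res$fits, rateConstant, numeric(1))
  expect_lt(max(ks) - min(ks), 1e-4)
  expect_lt(abs(rateConstant(res$best) - pep$k), 1e-5)
  expect_identical(fitMethod(res$best), "full_profile")
})

test_that("monoisotope contamination drives selection to A2/A1", {
  cont <- data.frame(channel = 0L, amplitude = 0.2)
  cfg <- simulationConfig(noiseCv = 0, contamination = cont, seed = 11)
  sim <- simulateTimeCourse(cfg)
  pep <- cfg$peptides[1, ]  # k = 0.30
  tc <- sim$quant[sim$quant$peptide == pep$sequence, ]
  comp <- peptideComposition(pep$sequence, pep$charge)
  res <- fitAllMethods(tc, comp)
  expect_identical(fitMethod(res$best), "A2/A1")
  expect_lt(abs(rateConstant(res$best) - pep$k) / pep$k, 0.02)
  fullR2 <- res$fits[["full_profile"]]@rSquared
  expect_lt(fullR2, res$best@rSquared)
})

test_that("selected method has the highest R-squared of all candidates", {
  cfg <- simulationConfig(noiseCv = 0.05, seed = 3)
  sim <- simulateTimeCourse(cfg)
  for (s in unique(sim$quant$peptide)[1:4]) {
    tc <- sim$quant[sim$quant$peptide == s, ]
    comp <- peptideComposition(s)
    res <- fitAllMethods(tc, comp)
    r2s <- vapply(res$fits, function(f) f@rSquared, numeric(1))
    expect_gte(res$best@rSquared + 1e-9, max(r2s, na.rm = TRUE))
  }
})

test_that("increasing contamination never improves the full-profile fit", {
  # amplitudes below the point where boundary clipping of the enrichment
  # estimate saturates the profile at its natural value
  amps <- c(0, 0.02, 0.05, 0.1, 0.2)
  r2 <- vapply(amps, function(a) {
    cont <- if (a > 0) data.frame(channel = 0L, amplitude = a) else NULL
    cfg <- simulationConfig(noiseCv = 0, contamination = cont, seed = 5)
    sim <- simulateTimeCourse(cfg)
    pep <- cfg$peptides[1, ]
    tc <- sim$quant[sim$quant$peptide == pep$sequence, ]
    comp <- peptideComposition(pep$sequence)
    fitAllMethods(tc, comp)$fits[["full_profile"]]@rSquared
  }, numeric(1))
  expect_true(all(diff(r2) <= 1e-9))
})

test_that("filters apply banding, time-point, and slow-turnover rules", {
  fits <- data.frame(
    protein = "P", peptide = letters[1:6], charge = 2L,
    method = "full_profile",
    k = c(0.2, 0.2, 0.2, 0.005, 0.005, 0.91),
    r_squared = c(0.95, 0.85, 0.79, 0.10, 0.10, 0.92),
    rse = c(0.01, 0.01, 0.01, 0.02, 0.08, 0.01),
    n_points = c(6L, 3L, 6L, 6L, 6L, 6L))
  out <- applyFilters(fits)
  expect_equal(as.character(out$r2_band[1:3]),
               c(">=0.95", "[0.8,0.9)", "<0.8"))
  expect_false(out$passed[2])  # only 3 time points
  expect_false(out$passed[3])  # R^2 below threshold, not slow
  expect_true(out$passed[4])   # slow turnover via RSE
  expect_false(out$passed[5])  # slow turnover but RSE too large
  banded <- applyFilters(fits, r2Threshold = 0.9)
  expect_false(banded$passed[2])
  expect_true(banded$passed[1])
  ranged <- applyFilters(fits, kRange = c(0.05, 0.6))
  expect_false(ranged$passed[6])
})

test_that("negative R-squared lands in the lowest band", {
  fits <- data.frame(k = 0.2, r_squared = -0.4, rse = 0.1, n_points = 6L)
  out <- applyFilters(fits)
  expect_equal(as.character(out$r2_band), "<0.8")
  expect_false(out$passed)
})

test_that("noisy replicates recover the rate with calibrated intervals", {
  set.seed(202)
  comp <- peptideComposition("LVNELTEFAK")
  nat <- isoValues(naturalIsotopeDistribution(comp))
  neh <- nExchangeable(comp)
  params <- labelingParameters()
  times <- params@timePoints
  i0z <- nat[1]
  i0a <- asymptoticRia(i0z, neh, params@pW, params@pH)
  k <- 0.135
  sdlog <- sqrt(log(1 + 0.03^2))
  nRep <- 120
  relErr <- numeric(nRep); covered <- logical(nRep)
  for (r in seq_len(nRep)) {
    i0 <- vapply(times, function(t) {
      i0t <- i0a + (i0z - i0a) * exp(-k * t)
      px <- (1 - params@pH) * (1 - (i0t / i0z)^(1 / neh))
      prof <- isoValues(labeledIsotopomerRias(nat, px, neh)) *
        exp(rnorm(6, -sdlog^2 / 2, sdlog))
      est <- estimateEnrichmentFullProfile(prof, nat, neh,
                                           params@pH, params@pW)
      reconstructMonoisotopicRia(enrichment(est), i0z, neh)
    }, numeric(1))
    fit <- fitExponentialDecay(times, i0, i0z, i0a)
    relErr[r] <- abs(rateConstant(fit) - k) / k
    ci <- confint(fit)
    covered[r] <- ci[["low"]] <= k && k <= ci[["high"]]
  }
  expect_lt(median(relErr), 0.05)
  expect_gte(mean(covered), 0.85)
  expect_lte(mean(covered), 1.0)
})
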