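test_that("angle distribution of a homogeneous ensemble is a point mass", {
  d <- buildDimer(omega = -30)
  ad <- angleDistribution(ensembleOf(rep(list(d), 6)), tmSelectors())
  expect_equal(ad@fractionRH, 1)
  expect_equal(ad@fractionLH, 0)
  expect_equal(unname(ad@modeMeans["RH"]), -30, tolerance = 0.5)
  expect_equal(sum(ad@histogram), 6)
})

test_that("sign-classified fractions recover the generator mixture weights", {
  for (sd in 1:10) {
    e <- generateModeEnsemble(nMembers = 300, seed = sd)
    ad <- angleDistribution(e)
    # binomial 3-sigma band around the 70/30 construction weights
    expect_lt(abs(ad@fractionRH - 0.70), 3 * sqrt(0.7 * 0.3 / 300))
  }
})

test_that("density maps integrate to one and recover construction clusters", {
  modes <- data.frame(label = c("P1", "P2"), weight = c(0.7, 0.3),
                      omegaMean = c(-30, 30), omegaSd = c(3, 3),
                      azimuth = c(20, 200), positionalSd = c(0.4, 0.4),
                      azimuthMobile = c(260, 80))
  e <- generateModeEnsemble(nMembers = 250, modes = modes, seed = 13)
  dm <- spatialDensityMap(e, tmSelectors())
  expect_equal(sum(densityValues(dm)), 1, tolerance = 1e-9)
  mx <- densityMaxima(dm)
  expect_equal(nrow(mx), 2L)
  # basin masses recover the realised construction fractions (and the
  # nominal 70/30 weights within the binomial sampling band)
  lab <- vapply(provenance(e), function(p) parseProvenance(p)["mode"],
                character(1))
  expect_equal(mx$mass[1], mean(lab == "P1"), tolerance = 0.01)
  expect_equal(mx$mass[2], mean(lab == "P2"), tolerance = 0.01)
  expect_lt(abs(mx$mass[1] - 0.70), 3 * sqrt(0.7 * 0.3 / 250) + 0.01)
  # maxima sit within one cell of the construction cluster centres
  # (reference interface azimuth az at separation 10: 10 * (cos az, sin az))
  c1 <- 10 * c(cos(20 * pi / 180), sin(20 * pi / 180))
  c2 <- 10 * c(cos(200 * pi / 180), sin(200 * pi / 180))
  expect_lt(sqrt(sum((c(mx$x[1], mx$y[1]) - c1)^2)), dm@cellSize)
  expect_lt(sqrt(sum((c(mx$x[2], mx$y[2]) - c2)^2)), dm@cellSize)
})

test_that("three construction clusters yield three ranked maxima", {
  modes <- data.frame(label = c("RH1", "RH2", "LH"),
                      weight = c(0.6, 0.1, 0.3),
                      omegaMean = c(-30, -20, 30), omegaSd = c(3, 3, 3),
                      azimuth = c(0, 120, 230), positionalSd = c(0.4, 0.4, 0.4),
                      azimuthMobile = c(260, 260, 80))
  e <- generateModeEnsemble(nMembers = 300, modes = modes, seed = 17)
  mx <- densityMaxima(spatialDensityMap(e, tmSelectors()))
  expect_equal(nrow(mx), 3L)
  expect_identical(mx$label, c("M1", "M2", "M3"))
  expect_true(all(diff(mx$mass) <= 0))
  lab <- vapply(provenance(e), function(p) parseProvenance(p)["mode"],
                character(1))
  realised <- sort(as.numeric(table(lab)) / 300, decreasing = TRUE)
  expect_equal(mx$mass, realised, tolerance = 0.01)
  expect_equal(mx$mass, c(0.6, 0.3, 0.1), tolerance = 0.1)
})

test_that("identical members give a single unit-mass maximum", {
  d <- buildDimer(omega = -30)
  dm <- spatialDensityMap(ensembleOf(rep(list(d), 4)), tmSelectors())
  mx <- densityMaxima(dm)
  expect_equal(nrow(mx), 1L)
  expect_equal(mx$mass, 1)
})

test_that("density maps are invariant under a global rigid transform", {
  e <- generateModeEnsemble(nMembers = 40, seed = 23)
  dm <- spatialDensityMap(e, tmSelectors())
  set.seed(31)
  R <- rotMat(rnorm(3), runif(1, 0, 360))
  tr <- rnorm(3, 0, 30)
  moved <- ensembleOf(lapply(members(e), rigidTransform, R = R, t = tr))
  dm2 <- spatialDensityMap(moved, tmSelectors())
  expect_equal(dm2@origin, dm@origin)
  expect_equal(densityValues(dm2), densityValues(dm), tolerance = 1e-6)
  expect_equal(densityMaxima(dm2)$mass, densityMaxima(dm)$mass,
               tolerance = 1e-6)
})

test_that("representative structures are the members nearest a mode", {
  d <- buildDimer(omega = -30)
  one <- ensembleOf(list(d))
  dm1 <- spatialDensityMap(one, tmSelectors())
  rep1 <- representativeStructure(one, dm1, "M1", tmSelectors())
  expect_identical(rep1$index, 1L)

  e <- generateModeEnsemble(nMembers = 120, seed = 19)
  dm <- spatialDensityMap(e, tmSelectors())
  repM1 <- representativeStructure(e, dm, "M1", tmSelectors())
  expect_identical(handedness(structureCrossing(repM1$structure,
                                                tmSelectors())), "RH")
  expect_match(provenance(e)[repM1$index], "mode=RH1")
  expect_error(representativeStructure(e, dm, "M9", tmSelectors()),
               "not present")
})

test_that("convergence divergence vanishes at full sampling and detects heterogeneity", {
  homog <- data.frame(label = "RH1", weight = 1, omegaMean = -30,
                      omegaSd = 8, azimuth = 0, positionalSd = 0.5,
                      azimuthMobile = 260)
  e <- generateModeEnsemble(nMembers = 200, modes = homog, seed = 29)

  cvFull <- convergenceCheck(e, tmSelectors(), fraction = 1, seed = 1)
  expect_equal(cvFull$divergence, 0, tolerance = 1e-12)

  cvHalf <- convergenceCheck(e, tmSelectors(), fraction = 0.5, seed = 1)
  expect_true(cvHalf$converged)
  expect_lt(cvHalf$divergence, 0.05)

  # divergence decays (in expectation) as the subsample grows
  divs <- vapply(c(0.25, 0.5, 0.75, 1), function(f)
    convergenceCheck(e, tmSelectors(), fraction = f, seed = 1)$divergence,
    numeric(1))
  expect_true(all(diff(divs) <= 0.005))
  expect_lt(divs[4], divs[1])

  # a tiny ensemble whose halves occupy disjoint modes cannot converge
  dA <- buildDimer(omega = -30); dB <- buildDimer(omega = 30)
  adv <- ensembleOf(list(dA, dA, dB, dB))
  cvAdv <- convergenceCheck(adv, tmSelectors(), fraction = 0.5, seed = 1)
  expect_false(cvAdv$converged)

  expect_error(convergenceCheck(adv, tmSelectors(), fraction = 0.2),
               "at least 2")
})
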