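test_that("ideal helix geometry matches closed-form expectations", {
  h <- buildIdealHelix(helixSpec())
  ca <- caOf(h, "A")
  expect_lt(dirAngle(axisDirection(fitHelixAxis(ca)), c(0, 0, 1)), 0.5)
  expect_equal(colMeans(ca), c(0, 0, 0), tolerance = 1e-9)

  # consecutive C-alpha chord: sqrt((2 r sin(twist/2))^2 + rise^2)
  chords <- sqrt(rowSums(diff(ca)^2))
  chordExpected <- sqrt((2 * 2.3 * sin(50 * pi / 180))^2 + 1.5^2)
  expect_equal(max(abs(chords - 3.8)), 0, tolerance = 0.05)
  expect_equal(chords[1], chordExpected, tolerance = 1e-9)

  # axial extent: (n - 1) * rise
  expect_equal(diff(range(ca[, 3])), 43.5, tolerance = 1e-9)

  # glycines carry no pseudo-C-beta, all other residues do
  a <- atoms(buildIdealHelix(defaultAlphaSpec()))
  expect_false(any(a$elety[a$resid == "GLY"] == "CB"))
  expect_equal(sum(a$elety == "CB"), 28L)

  expect_error(helixSpec(nResidues = 4), ">= 8")
  expect_error(helixSpec(sequence = "LLL"), "length")
})

test_that("dimer construction hits the target geometry and rejects clashes", {
  d <- buildDimer(omega = -30, separation = 10)
  cg <- structureCrossing(d)
  expect_equal(omega(cg), -30, tolerance = 0.5)
  expect_identical(handedness(cg), "RH")
  expect_equal(closestDistance(cg), 10, tolerance = 0.3)

  expect_identical(handedness(structureCrossing(buildDimer(omega = 30))), "LH")

  # construction truth is recorded in the label
  expect_equal(as.numeric(parseProvenance(structureLabel(d))["omega"]), -30)

  # steric infeasibility is an error, not a silent structure
  expect_error(buildDimer(omega = 0, separation = 6), "clash")
  expect_error(buildDimer(separation = 4), "diameter")
  expect_error(buildDimer(specB = helixSpec(chain = "A")), "distinct chains")
})

test_that("interface azimuths aim the requested residues at the partner", {
  gFace <- residueAzimuth(defaultAlphaSpec(), c(972, 976))
  d <- buildDimer(omega = -30, interfaceAzimuthA = gFace)
  axB <- axisOf(d, "B")
  for (r in c(972, 976))
    expect_identical(residueOrientation(d, "A", r, axB)$facing, "toward")
  # spinning the mobile helix by 180 degrees turns the face away
  dAway <- buildDimer(omega = -30, interfaceAzimuthA = (gFace + 180) %% 360)
  axB2 <- axisOf(dAway, "B")
  for (r in c(972, 976))
    expect_identical(residueOrientation(dAway, "A", r, axB2)$facing, "away")
})

test_that("mode ensembles are seeded, labelled and sign-consistent", {
  # zero-sd single mode: every drawn omega equals the mode mean exactly
  one <- data.frame(label = "RH1", weight = 1, omegaMean = -30, omegaSd = 0,
                    azimuth = 0, positionalSd = 0,
                    azimuthMobile = residueAzimuth(defaultAlphaSpec(),
                                                   c(972, 976)))
  e0 <- generateModeEnsemble(nMembers = 5, modes = one, seed = 3)
  oms <- vapply(provenance(e0), function(p)
    as.numeric(parseProvenance(p)["omega"]), numeric(1))
  expect_true(all(oms == -30))
  for (m in members(e0))
    expect_equal(omega(structureCrossing(m)), -30, tolerance = 0.5)

  # bit-identical reruns under a fixed seed
  eA <- generateModeEnsemble(nMembers = 20, seed = 9)
  eB <- generateModeEnsemble(nMembers = 20, seed = 9)
  expect_identical(provenance(eA), provenance(eB))
  expect_identical(lapply(members(eA), coords), lapply(members(eB), coords))

  # provenance mode labels agree with sign classification for >= 99%
  e <- generateModeEnsemble(nMembers = 400, seed = 5)
  lab <- vapply(provenance(e), function(p) parseProvenance(p)["mode"],
                character(1))
  om <- vapply(members(e), function(m) omega(structureCrossing(m)),
               numeric(1))
  agree <- (lab == "RH1" & om < 0) | (lab == "LH" & om > 0)
  expect_gte(mean(agree), 0.99)

  expect_error(generateModeEnsemble(10, modes = transform(one, weight = 2)),
               "sum to 1")
})

test_that("assembly trajectories start at exactly the prescribed separation", {
  tr <- generateAssemblyTrajectory(nFrames = 60, seed = 2)
  s1 <- frameStructure(tr, 1)
  dxy <- axisAnchor(axisOf(s1, "A"))[1:2] - axisAnchor(axisOf(s1, "B"))[1:2]
  expect_equal(sqrt(sum(dxy^2)), 60, tolerance = 1e-6)

  # frozen walk: constant separation, no dimerization event
  frz <- generateAssemblyTrajectory(nFrames = 30, stepSd = 0, tiltSd = 0,
                                    seed = 2)
  ev <- detectDimerization(frz, tmSelectors())
  expect_true(is.na(ev$stableFromFrame))
  expect_true(is.na(ev$eventTime))
  expect_equal(diff(range(ev$distances)), 0, tolerance = 1e-6)

  # forced encounter lands on the requested frame and persists
  bnd <- generateAssemblyTrajectory(nFrames = 200, bindFrame = 120, seed = 8)
  evb <- detectDimerization(bnd, tmSelectors())
  expect_identical(evb$stableFromFrame, 120L)
  expect_identical(evb$firstContactFrame, 120L)
  expect_equal(evb$eventTime, frameTimes(bnd)[120])
})

test_that("drift trajectories realise the requested RMSD archetypes", {
  d <- buildDimer(omega = -30)
  still <- generateDriftTrajectory(d, terminalRmsd = 0, nFrames = 20,
                                   noiseSd = 0, seed = 1)
  rs <- rmsdSeries(still, frameStructure(still, 1))
  expect_equal(max(rs$rmsd), 0, tolerance = 1e-9)

  pl <- generateDriftTrajectory(d, terminalRmsd = 2.5, nFrames = 80, seed = 3)
  rsP <- rmsdSeries(pl, frameStructure(pl, 1))
  lastHalf <- rsP$rmsd[seq(41, 80)]
  expect_equal(mean(lastHalf), 2.5, tolerance = 0.3)

  rp <- generateDriftTrajectory(d, terminalRmsd = 6, nFrames = 80,
                                mode = "ramp", seed = 3)
  rsR <- rmsdSeries(rp, frameStructure(rp, 1))
  expect_equal(rsR$rmsd[80], 6, tolerance = 0.4)
  expect_gt(stats::cor(rsR$time, rsR$rmsd), 0.99)
})

test_that("rotation scans step the designated helix azimuth exactly", {
  base <- buildDimer(omega = -30)
  sc <- generateRotationScan(base, chain = "B", increment = 15, n = 24)
  expect_equal(nMembers(sc), 24L)

  # marker azimuth about the fitted axis steps by 15 degrees
  ax <- axisOf(base, "B")
  e3 <- axisDirection(ax)
  e1 <- c(1, 0, 0) - e3[1] * e3; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2], e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  markerAz <- function(s) {   # azimuth measured in the axis-normal plane
    v <- caOf(s, "B")[1, ] - axisAnchor(ax)
    atan2(sum(v * e2), sum(v * e1)) * 180 / pi
  }
  az <- vapply(members(sc), markerAz, numeric(1))
  steps <- (diff(az) + 360) %% 360
  expect_equal(max(abs(steps - 15)), 0, tolerance = 1e-6)

  # a full turn reproduces the base structure
  expect_lt(max(abs(coords(members(sc)[[24]]) - coords(base))), 1e-6)

  # the non-designated helix is bit-identical across members
  aCoords <- lapply(members(sc), function(m) coords(selectAtoms(m, "A")))
  for (k in 2:24) expect_identical(aCoords[[k]], aCoords[[1]])
})
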