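test_that("helix axis fitting recovers the construction axis", {
  h <- buildIdealHelix(helixSpec())
  ca <- caOf(h, "A")
  ax <- fitHelixAxis(ca)
  expect_lt(dirAngle(axisDirection(ax), c(0, 0, 1)), 0.5)
  expect_equal(axisAnchor(ax), colMeans(ca), tolerance = 1e-9)

  # equivariance under a known rotation
  R <- rotMat(c(1, 2, 0.5), 37)
  ax2 <- fitHelixAxis(ca %*% t(R))
  expect_lt(dirAngle(axisDirection(ax2), R %*% c(0, 0, 1)), 0.5)

  # N-to-C orientation: reversing the residue order flips the direction
  ax3 <- fitHelixAxis(ca[nrow(ca):1, ])
  expect_lt(sum(axisDirection(ax3) * axisDirection(ax)), 0)

  # robust to isotropic noise
  set.seed(101)
  worst <- max(replicate(25, {
    noisy <- ca + matrix(rnorm(length(ca), 0, 0.3), ncol = 3)
    dirAngle(axisDirection(fitHelixAxis(noisy)), c(0, 0, 1))
  }))
  expect_lt(worst, 2)

  # stable under terminal-residue truncation
  axTrunc <- fitHelixAxis(ca[-1, ])
  expect_lt(dirAngle(axisDirection(axTrunc), axisDirection(ax)), 0.5)

  expect_error(fitHelixAxis(ca[1:4, ]), "at least 5")
  expect_error(fitHelixAxis(matrix(1, 6, 3)), "degenerate")
})

test_that("crossing geometry encodes the handedness sign convention", {
  # parallel, offset: zero angle, indeterminate handedness
  pg <- crossingGeometry(makeAxis(c(0, 0, 0), c(0, 0, 1)),
                         makeAxis(c(10, 0, 0), c(0, 0, 1)))
  expect_equal(omega(pg), 0)
  expect_identical(handedness(pg), "indeterminate")
  expect_equal(closestDistance(pg), 10)

  # rotating axis b by -30 degrees about the interhelix connector (+x)
  a <- makeAxis(c(0, 0, 0), c(0, 0, 1))
  b <- makeAxis(c(10, 0, 0), rotMat(c(1, 0, 0), -30) %*% c(0, 0, 1))
  cg <- crossingGeometry(a, b)
  expect_equal(omega(cg), -30, tolerance = 1e-6)
  expect_identical(handedness(cg), "RH")

  # mirror image through z: chirality inverts
  bM <- makeAxis(c(10, 0, 0), c(1, 1, -1) * axisDirection(b))
  cgM <- crossingGeometry(a, bM)
  expect_equal(omega(cgM), +30, tolerance = 1e-6)
  expect_identical(handedness(cgM), "LH")

  # pair property: symmetric under argument swap
  expect_equal(omega(crossingGeometry(b, a)), omega(cg), tolerance = 1e-9)

  # antiparallel N-to-C orientations describe the same line pair
  bFlip <- makeAxis(c(10, 0, 0), -axisDirection(b))
  expect_equal(omega(crossingGeometry(a, bFlip)), omega(cg),
               tolerance = 1e-6)
})

test_that("crossing angle magnitude is rigid-transform invariant and the sign flips under reflection", {
  d <- buildDimer(omega = -30)
  om0 <- omega(structureCrossing(d))
  expect_equal(om0, -30, tolerance = 0.5)

  set.seed(7)
  for (k in 1:8) {
    R <- rotMat(rnorm(3), runif(1, 0, 360))
    tr <- rnorm(3, 0, 20)
    omT <- omega(structureCrossing(rigidTransform(d, R, tr)))
    expect_equal(omT, om0, tolerance = 1e-6)
  }
  expect_equal(omega(structureCrossing(mirrorZ(d))), -om0, tolerance = 1e-6)
})

test_that("constructed dimers round-trip their target crossing angle", {
  for (om in c(-60, -45, -30, -10, 10, 30, 45, 60)) {
    cg <- structureCrossing(buildDimer(omega = om))
    expect_equal(omega(cg), om, tolerance = 0.5)
    expect_identical(handedness(cg), if (om < 0) "RH" else "LH")
  }
})

test_that("Kabsch superposition is optimal, proper and matches independent oracles", {
  set.seed(21)
  P <- matrix(rnorm(12, 0, 3), 4, 3)

  idem <- kabschSuperpose(P, P)
  expect_equal(idem$rmsd, 0, tolerance = 1e-9)
  expect_equal(idem$rotation, diag(3), tolerance = 1e-9)

  R <- rotMat(c(1, -1, 2), 72)
  moved <- sweep(P %*% t(R), 2, c(4, -2, 9), `+`)
  expect_lt(kabschSuperpose(moved, P)$rmsd, 1e-6)

  # perturbed copy: compare against brute-force rotational minimisation
  Q <- P + matrix(rnorm(12, 0, 0.4), 4, 3)
  got <- kabschSuperpose(Q, P)
  expect_equal(got$rmsd, bruteForceRmsd(Q, P), tolerance = 1e-4)
  expect_equal(det(got$rotation), 1, tolerance = 1e-9)

  # independent library route agrees
  fit <- suppressWarnings(bio3d::fit.xyz(as.vector(t(P)), as.vector(t(Q))))
  rmsdBio3d <- sqrt(mean(rowSums((matrix(fit, ncol = 3, byrow = TRUE) - P)^2)))
  expect_equal(got$rmsd, rmsdBio3d, tolerance = 1e-6)

  # a mirrored target must not be matched by a reflection
  mir <- P %*% diag(c(1, 1, -1))
  sup <- kabschSuperpose(mir, P)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  expect_gt(sup$rmsd, 0.1)

  # superposed RMSD never exceeds the unsuperposed RMSD
  raw <- sqrt(mean(rowSums((Q - P)^2)))
  expect_lte(got$rmsd, raw + 1e-12)

  expect_error(kabschSuperpose(P[1:2, ], P[1:2, ]), "at least 3")
  expect_error(kabschSuperpose(P, P[1:3, ]), "matching dimensions")
})

test_that("RMSD series are per-frame optimal superpositions against the reference", {
  d <- buildDimer(omega = -30)
  n <- nAtoms(d)
  xyz0 <- as.vector(t(coords(d)))
  tr <- new("HelixTrajectory", topology = d,
            xyz = rbind(xyz0, xyz0, xyz0), times = c(0, 1, 2))
  rs <- rmsdSeries(tr, d)
  expect_equal(rs$rmsd, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(rs$time, c(0, 1, 2))

  # one frame with a known perturbation matches the direct Kabsch value
  ca <- atoms(d)$elety == "CA"
  set.seed(4)
  pert <- coords(d) + matrix(rnorm(3 * n, 0, 0.5), ncol = 3)
  tr2 <- new("HelixTrajectory", topology = d,
             xyz = rbind(xyz0, as.vector(t(pert))))
  rs2 <- rmsdSeries(tr2, d)
  expect_equal(rs2$rmsd[1], 0, tolerance = 1e-9)
  direct <- kabschSuperpose(pert[ca, ], coords(d)[ca, ])$rmsd
  expect_equal(rs2$rmsd[2], direct, tolerance = 1e-9)

  other <- buildDimer(specB = helixSpec(30, chain = "C", firstResidue = 686))
  expect_error(rmsdSeries(tr, other), "chain|mismatch")
})
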