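test_that("contact maps are empty for separated helices and monotone in cutoff", {
  apart <- frameStructure(generateAssemblyTrajectory(nFrames = 2, stepSd = 0,
                                                     tiltSd = 0, seed = 1), 1)
  expect_equal(nrow(contacts(suppressMessages(contactMap(apart, "A", "B")))),
               0L)

  d <- buildDimer(omega = -30, separation = 9)
  expect_equal(nrow(contacts(suppressMessages(
    contactMap(d, "A", "B", cutoff = 0)))), 0L)

  c5 <- suppressMessages(contactMap(d, "A", "B", cutoff = 5))
  c7 <- suppressMessages(contactMap(d, "A", "B", cutoff = 7))
  key <- function(cs) paste(contacts(cs)$resnoA, contacts(cs)$resnoB)
  expect_true(all(key(c5) %in% key(c7)))
  expect_true(all(contacts(c7)$distance <= 7))

  # rigid-transform invariance of the contact list
  set.seed(41)
  moved <- rigidTransform(d, rotMat(rnorm(3), runif(1, 0, 360)),
                          rnorm(3, 0, 15))
  c7m <- suppressMessages(contactMap(moved, "A", "B", cutoff = 7))
  expect_identical(key(c7m), key(c7))
  expect_equal(contacts(c7m)$distance, contacts(c7)$distance,
               tolerance = 1e-9)

  # backbone-only input auto-selects the residue-center metric
  expect_message(contactMap(d, "A", "B"), "residue-center")
})

test_that("an RH GxxxG-face dimer packs the published interface residues", {
  d <- buildDimer(omega = -30, separation = 9)
  ir <- interfaceResidues(suppressMessages(contactMap(d, "A", "B")))
  expect_true(all(c(972, 976, 980) %in% ir$chainA))
  expect_true(all(c(701, 704, 708) %in% ir$chainB))

  # with the glycine face turned away the motif leaves the interface
  gFace <- residueAzimuth(defaultAlphaSpec(), c(972, 976))
  dAway <- buildDimer(omega = -30, separation = 9,
                      interfaceAzimuthA = (gFace + 180) %% 360)
  irAway <- interfaceResidues(suppressMessages(contactMap(dAway, "A", "B")))
  expect_false(any(c(972, 976) %in% irAway$chainA))
})

test_that("interface projection and overlap arithmetic", {
  cs <- new("ContactSet",
            contacts = data.frame(resnoA = c(972, 972, 976),
                                  residA = "GLY",
                                  resnoB = c(701, 704, 708),
                                  residB = c("MET", "ILE", "GLY"),
                                  distance = c(4, 4.2, 3.9)),
            chainA = "A", chainB = "B", cutoff = 4.5, metric = "heavy-atom")
  ir <- interfaceResidues(cs)
  expect_identical(ir$chainA, c(972, 976))
  expect_identical(ir$chainB, c(701, 704, 708))

  empty <- new("ContactSet",
               contacts = data.frame(resnoA = numeric(0), residA = character(0),
                                     resnoB = numeric(0), residB = character(0),
                                     distance = numeric(0)),
               chainA = "A", chainB = "B", cutoff = 4.5, metric = "heavy-atom")
  ie <- interfaceResidues(empty)
  expect_length(ie$chainA, 0)
  expect_length(ie$chainB, 0)

  expect_equal(interfaceOverlap(c(972, 976, 980), c(972, 976, 980)), 1)
  expect_equal(interfaceOverlap(c(1, 2), c(3, 4)), 0)
  expect_equal(interfaceOverlap(c(972, 976, 980), c(972, 976)), 2 / 3)
  expect_equal(interfaceOverlap(numeric(0), numeric(0)), 1)
})

test_that("residue orientation classifies toward, away and lateral", {
  # hand-built residue: CA at origin ring of own helix (axis +z through
  # (-3,0)), partner axis vertical through (10, 0)
  at <- data.frame(chain = "A", resno = c(1, 1), resid = "LEU",
                   elety = c("CA", "CB"),
                   x = c(0, 1.5), y = 0, z = 0)
  own <- makeAxis(c(-3, 0, 0), c(0, 0, 1))
  partner <- makeAxis(c(10, 0, 0), c(0, 0, 1))
  s <- new("HelixStructure", atoms = at, label = "")
  o <- residueOrientation(s, "A", 1, partner, ownAxis = own)
  expect_equal(o$azimuthToPartner, 0, tolerance = 1e-9)
  expect_identical(o$facing, "toward")

  at$x[2] <- -1.5   # CB anti-aligned
  s2 <- new("HelixStructure", atoms = at, label = "")
  o2 <- residueOrientation(s2, "A", 1, partner, ownAxis = own)
  expect_equal(o2$azimuthToPartner, 180, tolerance = 1e-9)
  expect_identical(o2$facing, "away")

  at$y[2] <- 1.5; at$x[2] <- 0  # CB perpendicular
  s3 <- new("HelixStructure", atoms = at, label = "")
  o3 <- residueOrientation(s3, "A", 1, partner, ownAxis = own)
  expect_equal(o3$azimuthToPartner, 90, tolerance = 1e-9)
  expect_identical(o3$facing, "lateral")

  # glycine: radial own-axis vector stands in for the missing CB
  d <- buildDimer(omega = -30)
  axB <- axisOf(d, "B")
  g <- residueOrientation(d, "A", 972, axB)
  expect_identical(g$facing, "toward")
  expect_error(residueOrientation(d, "A", 5000, axB), "not found")
})
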