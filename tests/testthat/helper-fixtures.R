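# Shared fixtures and small utilities.  All fixtures are built in code;
# nothing is read from disk except files the tests themselves write.

caOf <- function(s, chain) coords(selectAtoms(s, chain, atomNames = "CA"))

axisOf <- function(s, chain) fitHelixAxis(caOf(s, chain))

makeAxis <- function(anchor, direction, halfLength = 20) {
  new("HelixAxis", anchor = as.numeric(anchor),
      direction = as.numeric(direction / sqrt(sum(direction^2))),
      halfLength = halfLength)
}

# rotation matrix about `axis` by `deg` degrees
rotMat <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * cos(th) + sin(th) * K + (1 - cos(th)) * (u %o% u)
}

# apply a rigid transform (rotation R then translation t) to a structure
rigidTransform <- function(s, R, t = c(0, 0, 0)) {
  at <- atoms(s)
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at[, c("x", "y", "z")] <- sweep(xyz, 2, t, `+`)
  new("HelixStructure", atoms = at, label = structureLabel(s))
}

# mirror a structure through the xy plane (chirality inversion)
mirrorZ <- function(s) {
  at <- atoms(s)
  at$z <- -at$z
  new("HelixStructure", atoms = at, label = structureLabel(s))
}

ensembleOf <- function(structures) {
  new("StructureEnsemble", members = structures,
      provenance = paste0("member=", seq_along(structures)))
}

# angle in degrees between two directions (sign-insensitive)
dirAngle <- function(a, b) {
  acos(min(abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)), 1)) * 180 / pi
}

# Brute-force RMSD minimisation over rotations (translation handled by
# centroid alignment): coarse Euler-angle grid followed by Nelder-Mead
# refinement from the best grid points.  Independent of kabschSuperpose.
bruteForceRmsd <- function(mobile, reference) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  X <- sweep(mobile, 2, cm); Y <- sweep(reference, 2, cr)
  eulerR <- function(p)
    rotMat(c(0, 0, 1), p[1]) %*% rotMat(c(0, 1, 0), p[2]) %*%
      rotMat(c(1, 0, 0), p[3])
  f <- function(p) sqrt(mean(rowSums((X %*% t(eulerR(p)) - Y)^2)))
  grid <- expand.grid(a = seq(0, 300, 60), b = seq(-90, 90, 45),
                      c = seq(0, 300, 60))
  vals <- apply(grid, 1, f)
  best <- Inf
  for (k in order(vals)[1:8]) {
    op <- stats::optim(as.numeric(grid[k, ]), f, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, op$value)
  }
  best
}

tmSelectors <- function()
  helixSelectors(mobileChain = "A", referenceChain = "B",
                 mobileRange = c(966, 995), referenceRange = c(686, 715))
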