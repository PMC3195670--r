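# Core geometric observables: helix-axis fitting, the signed crossing
# angle with its handedness convention, Kabsch superposition and RMSD
# series.

#' Fit the axis of a single straight transmembrane helix
#'
#' The axis direction is the dominant principal direction of the centred
#' C-alpha coordinates, sign-fixed so that it points from the N- to the
#' C-terminus (\code{direction . (last - first) > 0}); the anchor is the
#' coordinate centroid.  Adequate for single-span TM helices; kinked-helix
#' models are out of scope.
#'
#' @param calpha numeric \code{n x 3} matrix of C-alpha positions in
#'   N-to-C order, Angstrom (n >= 5, about 1.4 helical turns).
#' @return a [HelixAxis-class].
#' @examples
#' ax <- fitHelixAxis(coords(buildIdealHelix(helixSpec())))
#' axisDirection(ax)   # ~ (0, 0, 1)
#' @export
fitHelixAxis <- function(calpha) {
  calpha <- as.matrix(calpha)
  n <- nrow(calpha)
  if (n < 5L)
    stop("need at least 5 C-alpha positions to fit a helix axis")
  ctr <- colMeans(calpha)
  X <- sweep(calpha, 2, ctr)
  sv <- svd(X, nu = 0, nv = 3)
  if (sv$d[1] < 1e-9)
    stop("degenerate (coincident) points: no axis defined")
  dir <- sv$v[, 1]
  # Refinement: on a helix the second differences p[i-1]+p[i+1]-2p[i] are
  # purely radial, so the axis is the null direction of their covariance.
  # Unlike the raw principal direction this is unbiased for partial turns;
  # it is used when the curve is genuinely helical (clear smallest
  # eigenvalue, direction consistent with the principal one).
  D <- calpha[1:(n - 2), , drop = FALSE] + calpha[3:n, , drop = FALSE] -
    2 * calpha[2:(n - 1), , drop = FALSE]
  if (mean(sqrt(rowSums(D^2))) > 1e-6) {
    B <- crossprod(D)
    eb <- eigen(B, symmetric = TRUE)
    cand <- eb$vectors[, 3]
    # accept only when nearly coincident with the principal direction:
    # on clean helical geometry this removes the partial-turn bias, while
    # noisy/irregular traces keep the robust principal direction.
    wellSep <- eb$values[2] > 4 * eb$values[3] + 1e-12
    if (wellSep && abs(sum(cand * dir)) > cos(.rad(1)))
      dir <- cand * sign(sum(cand * dir))
  }
  span <- calpha[n, ] - calpha[1, ]
  if (sum(dir * span) < 0) dir <- -dir
  proj <- X %*% dir
  new("HelixAxis", anchor = as.numeric(ctr), direction = as.numeric(dir),
      halfLength = max(max(abs(proj)), 1e-6))
}

#' Signed crossing angle and packing handedness of two helix axes
#'
#' The magnitude of omega is the acute angle between the axis directions.
#' The sign is the sign of the chirality triple product
#' \code{(d_a x d_b) . u}, where \code{u} is the unit vector between the
#' closest-approach points (a to b) of the finite axis segments, and
#' \code{d_b} is flipped first if the axes are antiparallel so the result
#' is a property of the line pair.  With this convention a right-handed
#' GxxxG-packed dimer has negative omega and a left-handed dimer positive
#' omega.  Frames within \code{signTolerance} of zero are classified
#' indeterminate (and excluded from RH/LH fraction denominators
#' downstream).
#'
#' @param axisA,axisB [HelixAxis-class] objects.
#' @param signTolerance degrees; |omega| at or below this gives
#'   handedness \code{"indeterminate"}.
#' @return a [CrossingGeometry-class].
#' @export
crossingGeometry <- function(axisA, axisB, signTolerance = 2) {
  segA <- axisSegment(axisA)
  segB <- axisSegment(axisB)
  cp <- .segmentClosestPoints(segA[1, ], segA[2, ], segB[1, ], segB[2, ])
  d1 <- axisA@direction
  d2 <- axisB@direction
  if (sum(d1 * d2) < 0) d2 <- -d2
  cosang <- min(max(sum(d1 * d2), -1), 1)
  ang <- .deg(acos(cosang))
  if (ang > 90) ang <- 180 - ang
  u <- cp$pb - cp$pa
  un <- .norm3(u)
  if (un < 1e-9 || ang < 1e-9) {
    om <- 0
    hand <- "indeterminate"
  } else {
    s <- sum(.cross3(d1, d2) * (u / un))
    om <- if (s < 0) -ang else ang
    if (om <= -90) om <- 90
    hand <- if (abs(om) <= signTolerance) "indeterminate"
            else if (om < 0) "RH" else "LH"
  }
  new("CrossingGeometry", omega = om, handedness = hand,
      closestDistance = cp$distance,
      closestPoints = rbind(cp$pa, cp$pb))
}

#' Crossing geometry of a two-helix structure
#'
#' Convenience wrapper: fits both helix axes from the C-alpha traces named
#' by \code{selectors} and returns their [crossingGeometry()].
#'
#' @param structure a [HelixStructure-class] containing both helices.
#' @param selectors a [helixSelectors()] configuration.
#' @param signTolerance degrees, see [crossingGeometry()].
#' @return a [CrossingGeometry-class].
#' @export
structureCrossing <- function(structure, selectors = helixSelectors(),
                              signTolerance = 2) {
  axA <- fitHelixAxis(.helixCalpha(structure, selectors$mobileChain,
                                   selectors$mobileRange))
  axB <- fitHelixAxis(.helixCalpha(structure, selectors$referenceChain,
                                   selectors$referenceRange))
  crossingGeometry(axA, axB, signTolerance)
}

#' Optimal least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (det = +1, never a reflection) and translation
#' minimising the RMSD of \code{mobile} onto \code{reference}.
#'
#' @param mobile,reference numeric \code{n x 3} matrices with matched rows
#'   (n >= 3).
#' @return list with \code{rotation} (3 x 3), \code{translation} (numeric
#'   3), \code{rmsd} (Angstrom) and \code{transformed} (the superposed
#'   mobile coordinates).  A point \code{x} maps to
#'   \code{rotation \%*\% x + translation}.
#' @export
kabschSuperpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("mobile and reference must have matching dimensions")
  if (nrow(mobile) < 3L) stop("need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  X <- sweep(mobile, 2, cm); Y <- sweep(reference, 2, cr)
  H <- t(X) %*% Y
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cr - R %*% cm)
  fitted <- sweep(mobile %*% t(R), 2, tr, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd, transformed = fitted)
}

#' RMSD time series of a trajectory against a reference structure
#'
#' One value per frame, each after optimal (Kabsch) superposition of the
#' selected atoms; equals 0 at frame 1 when the reference is the first
#' frame.
#'
#' @param trajectory a [HelixTrajectory-class].
#' @param reference a [HelixStructure-class]; the selection must resolve to
#'   the same atoms (chain, resno, elety) in both.
#' @param chain,residueRange,atomNames selection filters (default: all
#'   C-alpha atoms of every chain when \code{chain} is NULL).
#' @return data.frame with columns \code{time} (ns, frame index when the
#'   trajectory is untimed) and \code{rmsd} (Angstrom).
#' @export
rmsdSeries <- function(trajectory, reference, chain = NULL,
                       residueRange = NULL, atomNames = "CA") {
  topo <- trajectory@topology
  if (is.null(chain)) {
    idx <- which(topo@atoms$elety %in% atomNames)
    if (!length(idx)) stop("no atoms matching selection in topology")
    refSel <- reference@atoms[reference@atoms$elety %in% atomNames, , drop = FALSE]
  } else {
    idx <- .selectionIndices(topo, chain, residueRange, atomNames)
    refSel <- selectAtoms(reference, chain, residueRange, atomNames)@atoms
  }
  topoSel <- topo@atoms[idx, , drop = FALSE]
  if (!identical(paste(topoSel$chain, topoSel$resno, topoSel$elety),
                 paste(refSel$chain, refSel$resno, refSel$elety)))
    stop("selection mismatch between reference and trajectory topology")
  refXyz <- as.matrix(refSel[, c("x", "y", "z")])
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  rmsd <- vapply(seq_len(nrow(trajectory@xyz)), function(i) {
    fr <- matrix(trajectory@xyz[i, cols], ncol = 3L, byrow = TRUE)
    kabschSuperpose(fr, refXyz)$rmsd
  }, numeric(1))
  data.frame(time = frameTimes(trajectory), rmsd = rmsd)
}
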