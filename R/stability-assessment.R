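# Per-simulation conformational stability: RMSD plateau vs steady rise,
# crossing-angle spread, dimerization-event detection and cross-trajectory
# pairwise RMSD convergence.

# Theil-Sen estimator: median of all pairwise slopes (outlier-robust).
.theilSen <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  ij <- utils::combn(n, 2L)
  dt <- t[ij[2, ]] - t[ij[1, ]]
  ok <- dt != 0
  stats::median((y[ij[2, ]] - y[ij[1, ]])[ok] / dt[ok])
}

#' Classify the conformational stability of one simulation
#'
#' Formalises the usual empirical markers for membrane-protein model
#' assessment: a stable model reaches an RMSD plateau below about 3 A,
#' while an unstable one rises steadily over the run (reaching ~5-7 A by
#' 30 ns).  The plateau value is the mean RMSD over the final window and
#' the drift rate a Theil-Sen slope over the final half of the series.
#' Classification: stable iff plateau < \code{stableThreshold} and
#' |drift| < \code{driftThreshold}; unstable iff plateau >
#' \code{stableThreshold} and drift > \code{driftThreshold}; otherwise
#' indeterminate.
#'
#' @param rmsdSeries data.frame with columns \code{time} (ns) and
#'   \code{rmsd} (A), as returned by [rmsdSeries()]; needs >= 10 samples
#'   spanning >= 2 ns.
#' @param angleSeries optional numeric vector of signed crossing angles
#'   (degrees) for the same simulation; its determinate spread is reported.
#' @param stableThreshold plateau threshold, Angstrom.
#' @param driftThreshold drift threshold, Angstrom/ns.
#' @param finalWindowFraction fraction of the run defining the plateau
#'   window.
#' @param signTolerance degrees; angles within this of zero are excluded
#'   from the spread.
#' @return a [StabilityReport-class].
#' @export
assessStability <- function(rmsdSeries, angleSeries = NULL,
                            stableThreshold = 3.0, driftThreshold = 0.05,
                            finalWindowFraction = 0.25, signTolerance = 2) {
  stopifnot(is.data.frame(rmsdSeries),
            all(c("time", "rmsd") %in% names(rmsdSeries)))
  t <- rmsdSeries$time; y <- rmsdSeries$rmsd
  if (length(t) < 10L) stop("need at least 10 RMSD samples")
  if (diff(range(t)) < 2) stop("series must span at least 2 ns")
  nW <- max(2L, ceiling(finalWindowFraction * length(t)))
  plateau <- mean(utils::tail(y, nW))
  half <- seq.int(ceiling(length(t) / 2), length(t))
  drift <- .theilSen(t[half], y[half])
  cls <- if (plateau < stableThreshold && abs(drift) < driftThreshold) "stable"
         else if (plateau > stableThreshold && drift > driftThreshold) "unstable"
         else "indeterminate"
  spread <- if (is.null(angleSeries)) c(min = NA_real_, max = NA_real_,
                                        sd = NA_real_)
            else angleSpread(angleSeries, signTolerance)
  new("StabilityReport", series = rmsdSeries, plateauValue = plateau,
      driftRate = drift, classification = cls, angleSpread = spread)
}

#' Spread of a crossing-angle series
#'
#' Minimum, maximum and population standard deviation of the determinate
#' angles (those with |omega| above \code{signTolerance}).
#'
#' @param angleSeries numeric vector of signed crossing angles, degrees.
#' @param signTolerance degrees.
#' @return named numeric: \code{min}, \code{max}, \code{sd} (degrees).
#' @export
angleSpread <- function(angleSeries, signTolerance = 2) {
  a <- angleSeries[abs(angleSeries) > signTolerance]
  if (length(a) < 2L) {
    if (length(angleSeries[!is.na(angleSeries)]) >= 2L &&
        stats::sd(angleSeries) == 0)
      return(c(min = angleSeries[1], max = angleSeries[1], sd = 0))
    stop("need at least 2 determinate angle samples")
  }
  c(min = min(a), max = max(a),
    sd = sqrt(mean((a - mean(a))^2)))
}

#' Detect a dimerization event in an assembly trajectory
#'
#' Follows the closest approach between the two fitted helix-axis segments
#' through the trajectory (an encounter notion at helix scale, rather than
#' an atom-atom minimum distance).  The first contact is the first frame
#' with distance below \code{contactDistance}; the event is the first
#' frame from which the distance stays below the cutoff for at least
#' \code{persistence} consecutive frames.
#'
#' @param trajectory a [HelixTrajectory-class].
#' @param selectors a [helixSelectors()].
#' @param contactDistance contact cutoff between axis segments, Angstrom.
#' @param persistence minimum run of consecutive bound frames.
#' @return list with \code{eventTime} (ns; NA when no event),
#'   \code{firstContactFrame}, \code{stableFromFrame} (1-based; NA when
#'   never satisfied) and \code{distances} (per-frame axis distance).
#' @export
detectDimerization <- function(trajectory, selectors = helixSelectors(),
                               contactDistance = 8.0, persistence = 10L) {
  nf <- nFrames(trajectory)
  dist <- vapply(seq_len(nf), function(i) {
    s <- frameStructure(trajectory, i)
    axA <- fitHelixAxis(.helixCalpha(s, selectors$mobileChain,
                                     selectors$mobileRange))
    axB <- fitHelixAxis(.helixCalpha(s, selectors$referenceChain,
                                     selectors$referenceRange))
    sa <- axisSegment(axA); sb <- axisSegment(axB)
    .segmentClosestPoints(sa[1, ], sa[2, ], sb[1, ], sb[2, ])$distance
  }, numeric(1))
  below <- dist < contactDistance
  firstContact <- if (any(below)) which(below)[1] else NA_integer_
  stableFrom <- NA_integer_
  run <- rle(below)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  ok <- run$values & run$lengths >= persistence
  if (any(ok)) stableFrom <- starts[which(ok)[1]]
  times <- frameTimes(trajectory)
  list(eventTime = if (is.na(stableFrom)) NA_real_ else times[stableFrom],
       firstContactFrame = firstContact, stableFromFrame = stableFrom,
       distances = dist)
}

#' Pairwise RMSD between the final windows of two trajectories
#'
#' Superposes and scores every cross pair of frames drawn from the final
#' window of each trajectory (used to test whether two simulations have
#' converged to the same structure within their dynamic fluctuations).
#'
#' @param trajA,trajB [HelixTrajectory-class] objects with a shared
#'   selection.
#' @param chain,residueRange,atomNames selection (see [rmsdSeries()]).
#' @param window final fraction of each trajectory compared.
#' @param maxFrames per-trajectory cap on compared frames (evenly strided)
#'   to bound the quadratic cost.
#' @return list with \code{min}, \code{max}, \code{mean} (Angstrom) and
#'   \code{n} (number of pairs).
#' @export
pairwiseEnsembleRmsd <- function(trajA, trajB, chain = NULL,
                                 residueRange = NULL, atomNames = "CA",
                                 window = 0.5, maxFrames = 50L) {
  pick <- function(tr) {
    nf <- nFrames(tr)
    idx <- seq.int(max(1L, floor((1 - window) * nf) + 1L), nf)
    if (length(idx) > maxFrames)
      idx <- idx[unique(round(seq(1, length(idx), length.out = maxFrames)))]
    idx
  }
  sel <- function(tr, i) {
    s <- frameStructure(tr, i)
    if (is.null(chain)) {
      out <- s@atoms[s@atoms$elety %in% atomNames, , drop = FALSE]
      as.matrix(out[, c("x", "y", "z")])
    } else coords(selectAtoms(s, chain, residueRange, atomNames))
  }
  ia <- pick(trajA); ib <- pick(trajB)
  xa <- lapply(ia, function(i) sel(trajA, i))
  xb <- lapply(ib, function(i) sel(trajB, i))
  if (nrow(xa[[1]]) != nrow(xb[[1]]))
    stop("selection mismatch between the two trajectories")
  vals <- as.vector(vapply(xa, function(A)
    vapply(xb, function(B) kabschSuperpose(A, B)$rmsd, numeric(1)),
    numeric(length(xb))))
  list(min = min(vals), max = max(vals), mean = mean(vals),
       n = length(vals))
}
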