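# Ensemble-level characterisation: crossing-angle distributions and RH/LH
# fractions, the 2D spatial probability-density map of the mobile helix
# around the reference helix, packing-mode detection, representative
# selection, and the half-ensemble convergence check.

# One signed crossing angle per conformation of a member.  Trajectories
# contribute one angle per frame; weights are scaled so every ensemble
# member carries equal total weight.
.memberOmegas <- function(member, selectors, signTolerance) {
  if (is(member, "HelixStructure")) {
    cg <- structureCrossing(member, selectors, signTolerance)
    data.frame(frame = 1L, omega = omega(cg), handedness = handedness(cg))
  } else {
    nf <- nFrames(member)
    res <- lapply(seq_len(nf), function(i)
      .memberOmegas(frameStructure(member, i), selectors, signTolerance))
    out <- do.call(rbind, res)
    out$frame <- seq_len(nf)
    out
  }
}

#' Crossing-angle distribution of an ensemble
#'
#' Computes one signed crossing angle per member conformation (per frame
#' for trajectory members, weighted so each member contributes equally),
#' classifies handedness by sign, and summarises the distribution.
#' RH/LH fractions are computed over determinate conformations only;
#' mode means are the weighted means of each sign class.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param selectors a [helixSelectors()].
#' @param binWidth histogram bin width, degrees.
#' @param signTolerance degrees, see [crossingGeometry()].
#' @return an [AngleDistribution-class].
#' @export
angleDistribution <- function(ensemble, selectors = helixSelectors(),
                              binWidth = 5, signTolerance = 2) {
  if (nMembers(ensemble) < 1L) stop("empty ensemble")
  rows <- lapply(seq_len(nMembers(ensemble)), function(i) {
    out <- .memberOmegas(ensemble@members[[i]], selectors, signTolerance)
    out$member <- i
    out$weight <- 1 / nrow(out)
    out
  })
  samples <- do.call(rbind, rows)[, c("member", "frame", "omega",
                                      "handedness", "weight")]
  det <- samples$handedness != "indeterminate"
  if (!any(det)) stop("all conformations have indeterminate handedness")
  wDet <- sum(samples$weight[det])
  fracRH <- sum(samples$weight[det & samples$handedness == "RH"]) / wDet
  fracLH <- sum(samples$weight[det & samples$handedness == "LH"]) / wDet
  wmean <- function(keep)
    if (any(keep)) sum(samples$omega[keep] * samples$weight[keep]) /
      sum(samples$weight[keep]) else NA_real_
  lim <- max(90, ceiling(max(abs(samples$omega)) / binWidth) * binWidth)
  breaks <- seq(-lim, lim, by = binWidth)
  bin <- findInterval(samples$omega, breaks, rightmost.closed = TRUE)
  hist <- vapply(seq_len(length(breaks) - 1L),
                 function(b) sum(samples$weight[bin == b]), numeric(1))
  new("AngleDistribution", samples = samples, binWidth = binWidth,
      breaks = breaks, histogram = hist,
      fractionRH = fracRH, fractionLH = fracLH,
      modeMeans = c(RH = wmean(det & samples$handedness == "RH"),
                    LH = wmean(det & samples$handedness == "LH")))
}

# Canonical bilayer frame of one conformation: reference-helix axis on +z
# through the origin, azimuth pinned by the first C-alpha of the reference
# TM range lying in the +x half-plane.  Returns a function mapping lab
# coordinates (n x 3) into the canonical frame.
.canonicalFrame <- function(structure, selectors) {
  ca <- .helixCalpha(structure, selectors$referenceChain,
                     selectors$referenceRange)
  ax <- fitHelixAxis(ca)
  e3 <- axisDirection(ax)
  marker <- ca[1, ] - axisAnchor(ax)
  mPerp <- marker - sum(marker * e3) * e3
  if (.norm3(mPerp) < 1e-9) {   # marker on the axis: fall back to any normal
    mPerp <- .cross3(e3, c(1, 0, 0))
    if (.norm3(mPerp) < 1e-9) mPerp <- .cross3(e3, c(0, 1, 0))
  }
  e1 <- .unit(mPerp)
  e2 <- .cross3(e3, e1)
  R <- cbind(e1, e2, e3)
  anchor <- axisAnchor(ax)
  function(xyz) sweep(xyz, 2, anchor) %*% R
}

# Mobile-helix backbone positions of every conformation of a member,
# mapped to the canonical frame and projected on the bilayer (xy) plane.
.memberProjectedPoints <- function(member, selectors) {
  oneFrame <- function(s) {
    toCanon <- .canonicalFrame(s, selectors)
    mob <- selectAtoms(s, selectors$mobileChain, selectors$mobileRange,
                       selectors$backboneAtoms)
    toCanon(coords(mob))[, 1:2, drop = FALSE]
  }
  if (is(member, "HelixStructure")) oneFrame(member)
  else do.call(rbind, lapply(seq_len(nFrames(member)), function(i)
    oneFrame(frameStructure(member, i))))
}

.smooth3x3 <- function(v) {
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    ri <- max(1, 1 + di):min(nr, nr + di)
    rj <- max(1, 1 + dj):min(nc, nc + dj)
    out[ri - di, rj - dj] <- out[ri - di, rj - dj] + v[ri, rj]
    cnt[ri - di, rj - dj] <- cnt[ri - di, rj - dj] + 1
  }
  out / cnt
}

# Steepest-ascent watershed on a smoothed grid.  Every positive cell is
# assigned to the local maximum reached by repeatedly stepping to the
# highest 8-neighbour; returns an integer matrix of peak ids (0 = empty).
.watershed <- function(sm, raw) {
  nr <- nrow(sm); nc <- ncol(sm)
  assign <- matrix(0L, nr, nc)
  target <- matrix(0L, nr, nc)  # linear index of uphill step (0 = self)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (raw[i, j] <= 0 && sm[i, j] <= 0) next
    best <- sm[i, j]; bi <- 0L
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      if (sm[ii, jj] > best) { best <- sm[ii, jj]; bi <- ii + (jj - 1L) * nr }
    }
    target[i, j] <- bi
  }
  resolve <- function(lin) {
    path <- integer(0)
    while (target[lin] != 0L && assign[lin] == 0L) {
      path <- c(path, lin)
      lin <- target[lin]
    }
    root <- if (assign[lin] != 0L) assign[lin] else lin
    assign[path] <<- root
    if (assign[lin] == 0L) assign[lin] <<- root
    root
  }
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (raw[i, j] <= 0 && sm[i, j] <= 0) next
    lin <- i + (j - 1L) * nr
    if (assign[lin] == 0L) resolve(lin)
  }
  assign
}


# Merge watershed basins into packing modes.  A basin is absorbed into its
# highest-saddle taller neighbour when its relative prominence
# (peak - saddle)/peak falls below `prominence` -- suppressing ridge lumps
# along the elongated footprint of a tilted helix -- or when the two peak
# cells lie within `mergeDistance`.  Saddles are computed once and re-keyed
# incrementally as basins merge (the saddle between a merged basin and a
# third one is the higher of the two constituent saddles).
.mergedMaxima <- function(sm, values, basin, origin, cellSize,
                          mergeDistance, prominence, minorMass) {
  nr <- nrow(sm); nc <- ncol(sm)
  roots <- setdiff(unique(as.vector(basin)), 0L)
  empty <- data.frame(label = character(0), x = numeric(0), y = numeric(0),
                      peak = numeric(0), mass = numeric(0),
                      minor = logical(0))
  if (!length(roots)) return(empty)
  peak <- stats::setNames(sm[roots], as.character(roots))
  sad <- new.env(parent = emptyenv())
  skey <- function(a, b) paste(min(a, b), max(a, b))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    b1 <- basin[i, j]
    if (b1 == 0L) next
    for (dd in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
      ii <- i + dd[1]; jj <- j + dd[2]
      if (ii < 1L || ii > nr || jj < 1L || jj > nc) next
      b2 <- basin[ii, jj]
      if (b2 == 0L || b2 == b1) next
      k <- skey(b1, b2)
      h <- min(sm[i, j], sm[ii, jj])
      if (is.null(sad[[k]]) || h > sad[[k]]) sad[[k]] <- h
    }
  }
  alias <- stats::setNames(roots, as.character(roots))
  resolve <- function(r) {
    while (alias[[as.character(r)]] != r) r <- alias[[as.character(r)]]
    r
  }
  pos <- function(r) {
    i <- ((r - 1L) %% nr) + 1L
    j <- ((r - 1L) %/% nr) + 1L
    c(origin[1] + (i - 0.5) * cellSize, origin[2] + (j - 0.5) * cellSize)
  }
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    live <- unique(vapply(roots, resolve, numeric(1)))
    for (r in live[order(peak[as.character(live)])]) {
      nb <- numeric(0); nbSad <- numeric(0)
      for (k in ls(sad)) {
        ab <- vapply(unique(vapply(as.numeric(strsplit(k, " ")[[1]]),
                                   resolve, numeric(1))), identity, numeric(1))
        if (length(ab) != 2L || !(r %in% ab)) next
        o <- setdiff(ab, r)
        if (peak[as.character(o)] < peak[as.character(r)]) next
        nb <- c(nb, o); nbSad <- c(nbSad, sad[[k]])
      }
      if (!length(nb)) next
      best <- which.max(nbSad)
      pk <- peak[as.character(r)]
      if ((pk - nbSad[best]) < prominence * pk ||
          sqrt(sum((pos(r) - pos(nb[best]))^2)) < mergeDistance) {
        alias[[as.character(r)]] <- nb[best]
        changed <- TRUE
      }
    }
  }
  final <- vapply(roots, resolve, numeric(1))
  live <- unique(final)
  lookup <- stats::setNames(final, as.character(roots))
  flat <- basin
  nz <- flat != 0L
  flat[nz] <- lookup[as.character(flat[nz])]
  out <- do.call(rbind, lapply(live, function(r) {
    # position: smoothed-density-weighted centroid of the near-peak region
    # of the basin (robust on ridge-like footprints, unlike the raw
    # arg-max cell)
    cells <- which(flat == r & sm >= 0.5 * sm[r])
    ci <- ((cells - 1L) %% nr) + 1L
    cj <- ((cells - 1L) %/% nr) + 1L
    w <- sm[cells]
    data.frame(x = origin[1] + (sum(w * (ci - 0.5)) / sum(w)) * cellSize,
               y = origin[2] + (sum(w * (cj - 0.5)) / sum(w)) * cellSize,
               peak = sm[r], mass = sum(values[flat == r]))
  }))
  out <- out[out$mass > 0, , drop = FALSE]
  if (!nrow(out)) return(empty)
  out <- out[order(-out$mass), , drop = FALSE]
  out$label <- paste0("M", seq_len(nrow(out)))
  out$minor <- out$mass < minorMass
  rownames(out) <- NULL
  out[, c("label", "x", "y", "peak", "mass", "minor")]
}

#' 2D spatial probability-density map of helix packing
#'
#' For every conformation, the reference-helix backbone defines a canonical
#' frame (axis on +z through the origin, azimuth pinned by the first
#' C-alpha of its TM range); the mobile-helix backbone positions are
#' projected onto the bilayer (xy) plane of that frame and accumulated into
#' a regular grid, each ensemble member contributing equal total mass.  The
#' grid is sized to contain all projected points and normalised to total
#' probability 1.  Density maxima (packing modes) are detected on a
#' 3x3-smoothed copy, merged when closer than \code{mergeDistance}, and
#' ranked by the mass of their steepest-ascent watershed basin; modes below
#' \code{minorMass} are flagged minor.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param selectors a [helixSelectors()].
#' @param cellSize grid cell edge, Angstrom.
#' @param mergeDistance maxima closer than this merge into one mode,
#'   Angstrom.
#' @param prominence relative prominence threshold: a maximum whose peak
#'   rises above its highest saddle by less than this fraction of the peak
#'   is merged into the neighbouring basin (suppresses ridge lumps along
#'   the elongated footprint of a tilted helix).
#' @param smoothPasses number of 3x3 smoothing passes applied before
#'   maxima detection (the stored density is unsmoothed).
#' @param minorMass basin-mass threshold below which a mode is flagged
#'   minor.
#' @return a [DensityMap-class].
#' @export
spatialDensityMap <- function(ensemble, selectors = helixSelectors(),
                              cellSize = 1.0, mergeDistance = 3,
                              prominence = 0.4, smoothPasses = 3L,
                              minorMass = 0.05) {
  n <- nMembers(ensemble)
  pts <- vector("list", n)
  wts <- vector("list", n)
  for (i in seq_len(n)) {
    p <- .memberProjectedPoints(ensemble@members[[i]], selectors)
    pts[[i]] <- p
    wts[[i]] <- rep(1 / (n * nrow(p)), nrow(p))
  }
  P <- do.call(rbind, pts)
  w <- unlist(wts)
  pad <- 2 * cellSize
  origin <- c(floor((min(P[, 1]) - pad) / cellSize) * cellSize,
              floor((min(P[, 2]) - pad) / cellSize) * cellSize)
  nx <- ceiling((max(P[, 1]) + pad - origin[1]) / cellSize)
  ny <- ceiling((max(P[, 2]) + pad - origin[2]) / cellSize)
  ix <- pmin(pmax(floor((P[, 1] - origin[1]) / cellSize) + 1L, 1L), nx)
  iy <- pmin(pmax(floor((P[, 2] - origin[2]) / cellSize) + 1L, 1L), ny)
  values <- matrix(0, nx, ny)
  for (k in seq_along(w))
    values[ix[k], iy[k]] <- values[ix[k], iy[k]] + w[k]
  values <- values / sum(values)

  sm <- values
  for (p in seq_len(smoothPasses)) sm <- .smooth3x3(sm)
  basin <- .watershed(sm, values)
  maxima <- .mergedMaxima(sm, values, basin, origin, cellSize,
                          mergeDistance, prominence, minorMass)
  new("DensityMap", origin = origin, cellSize = cellSize, values = values,
      maxima = maxima)
}

#' Representative member of a packing mode
#'
#' Returns the ensemble member whose mobile-helix projected centroid (in
#' the canonical frame, averaged over frames for trajectory members) is
#' nearest the selected density maximum; ties break deterministically to
#' the lowest member index.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param map a [DensityMap-class] computed from it.
#' @param modeLabel a label present in \code{densityMaxima(map)$label}.
#' @param selectors a [helixSelectors()].
#' @return list with \code{index} (member index) and \code{structure} (the
#'   member; for trajectory members, the frame nearest the mode).
#' @export
representativeStructure <- function(ensemble, map, modeLabel = "M1",
                                    selectors = helixSelectors()) {
  mx <- densityMaxima(map)
  row <- mx[mx$label == modeLabel, ]
  if (nrow(row) != 1L) stop("mode not present in map: ", modeLabel)
  pos <- c(row$x, row$y)
  cent <- t(vapply(members(ensemble), function(m) {
    p <- .memberProjectedPoints(m, selectors)
    colMeans(p)
  }, numeric(2)))
  d <- sqrt((cent[, 1] - pos[1])^2 + (cent[, 2] - pos[2])^2)
  idx <- unname(which.min(d))  # which.min takes the first (lowest) index on ties
  m <- ensemble@members[[idx]]
  if (is(m, "HelixTrajectory")) {
    df <- vapply(seq_len(nFrames(m)), function(i) {
      p <- .memberProjectedPoints(frameStructure(m, i), selectors)
      sum((colMeans(p) - pos)^2)
    }, numeric(1))
    m <- frameStructure(m, which.min(df))
  }
  list(index = idx, structure = m)
}

# Jensen-Shannon divergence (bits) between two weight vectors on a shared
# binning; zero cells contribute zero.
.jsd <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Half-ensemble convergence check
#'
#' Measures whether the ensemble's crossing-angle distribution is converged
#' with respect to sample size: the mean Jensen-Shannon divergence (bits)
#' between the full-ensemble angle histogram and the histogram of random
#' member subsamples of the given fraction (drawn without replacement).
#' Divergence 0 at fraction 1; converged when the mean divergence falls
#' below \code{threshold}.
#'
#' @param ensemble a [StructureEnsemble-class] (>= 4 members).
#' @param selectors a [helixSelectors()].
#' @param fraction subsample fraction in (0, 1].
#' @param nDraws number of random subsamples averaged.
#' @param seed integer seed for the subsampling.
#' @param binWidth histogram bin width, degrees.
#' @param threshold convergence threshold, bits.
#' @return list with \code{divergence} (mean JSD, bits), \code{perDraw},
#'   \code{fractionUsed}, \code{threshold} and \code{converged}.
#' @export
convergenceCheck <- function(ensemble, selectors = helixSelectors(),
                             fraction = 0.5, nDraws = 20L, seed = 1L,
                             binWidth = 5, threshold = 0.05) {
  n <- nMembers(ensemble)
  if (n < 4L) stop("need at least 4 members for a convergence check")
  k <- floor(fraction * n)
  if (k < 2L) stop("fraction * ensemble size must be at least 2 members")
  ad <- angleDistribution(ensemble, selectors, binWidth = binWidth)
  s <- ad@samples
  breaks <- ad@breaks
  binOf <- findInterval(s$omega, breaks, rightmost.closed = TRUE)
  histOf <- function(memberIdx) {
    keep <- s$member %in% memberIdx
    vapply(seq_len(length(breaks) - 1L), function(b)
      sum(s$weight[keep & binOf == b]), numeric(1))
  }
  full <- histOf(seq_len(n))
  per <- .withSeed(seed, vapply(seq_len(nDraws), function(d) {
    sub <- sample.int(n, k)
    .jsd(histOf(sub), full)
  }, numeric(1)))
  div <- mean(per)
  list(divergence = div, perDraw = per, fractionUsed = k / n,
       threshold = threshold, converged = div < threshold)
}
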