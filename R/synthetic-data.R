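# Synthetic helix-dimer generators.  These emulate the study conditions of
# a coarse-grained self-assembly campaign -- bimodal RH/LH packing
# ensembles, diffusion--association trajectories started at 60 A
# separation, plateau vs drifting RMSD series, 15-degree rotation scans,
# and dimers with a prescribed interface azimuth -- with full construction
# bookkeeping recorded in labels/provenance so every analysis is testable
# as parameter recovery.

.AA31 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")

#' Specification of an ideal alpha-helix
#'
#' Textbook ideal-helix parameters: 1.5 A rise per residue, 100 degree
#' twist per residue (3.6 residues/turn), 2.3 A C-alpha radius.  The
#' sequence string places residue identities (e.g. glycines at the
#' 972/976-equivalent positions) and non-glycine residues optionally get a
#' pseudo-C-beta placed radially outward, giving them a side-chain
#' direction without full side-chain building.
#'
#' @param nResidues number of residues (>= 8).
#' @param sequence optional 1-letter sequence of length \code{nResidues}
#'   (default poly-leucine).
#' @param rise,twist,radius helix geometry (A, degrees, A).
#' @param cbeta place pseudo-C-beta atoms 1.5 A radially outward on
#'   non-glycine residues?
#' @param chain chain identifier.
#' @param firstResidue author number of the first residue.
#' @return list of class \code{helixSpec}.
#' @export
helixSpec <- function(nResidues = 30L, sequence = NULL, rise = 1.5,
                      twist = 100, radius = 2.3, cbeta = TRUE,
                      chain = "A", firstResidue = 1L) {
  if (nResidues < 8L) stop("nResidues must be >= 8")
  if (rise <= 0 || radius <= 0) stop("rise and radius must be positive")
  if (is.null(sequence)) sequence <- strrep("L", nResidues)
  if (nchar(sequence) != nResidues)
    stop("sequence length must equal nResidues")
  structure(list(nResidues = as.integer(nResidues), sequence = sequence,
                 rise = rise, twist = twist, radius = radius, cbeta = cbeta,
                 chain = chain, firstResidue = as.integer(firstResidue)),
            class = "helixSpec")
}

#' Default helix specs for an integrin-like alphaIIb/beta3 dimer
#'
#' \code{defaultAlphaSpec()}: 30 residues numbered 966-995, poly-leucine
#' with the GxxxG glycines at 972 and 976 (chain A, the mobile helix).
#' \code{defaultBetaSpec()}: 30 residues numbered 686-715 with M701, I704
#' and G708 (chain B, the reference helix).
#'
#' @return a \code{helixSpec}.
#' @export
defaultAlphaSpec <- function() {
  seq <- rep("L", 30)
  seq[972 - 966 + 1] <- "G"
  seq[976 - 966 + 1] <- "G"
  helixSpec(30L, paste(seq, collapse = ""), chain = "A", firstResidue = 966L)
}

#' @rdname defaultAlphaSpec
#' @export
defaultBetaSpec <- function() {
  seq <- rep("L", 30)
  seq[701 - 686 + 1] <- "M"
  seq[704 - 686 + 1] <- "I"
  seq[708 - 686 + 1] <- "G"
  helixSpec(30L, paste(seq, collapse = ""), chain = "B", firstResidue = 686L)
}

#' Body-frame azimuth of a residue on an ideal helix
#'
#' The azimuth (degrees, mod 360) at which residue \code{resno}'s C-alpha
#' sits around the helix axis in the helix's own body frame (residue 1 at
#' 0).  Used to aim a given face at the partner helix via the
#' \code{interfaceAzimuth*} arguments of [buildDimer()]: setting
#' \code{interfaceAzimuth = residueAzimuth(spec, r)} makes residue \code{r}
#' face the partner.  For several residues the circular mean is returned.
#'
#' @param spec a [helixSpec()].
#' @param resno author residue number(s).
#' @return azimuth in degrees, in [0, 360).
#' @export
residueAzimuth <- function(spec, resno) {
  a <- (resno - spec$firstResidue) * spec$twist
  ang <- atan2(mean(sin(.rad(a))), mean(cos(.rad(a))))
  (.deg(ang) + 360) %% 360
}

#' Build an ideal alpha-helix structure along +z
#'
#' C-alpha atoms lie on an ideal helical curve along +z, N-to-C with
#' increasing z; the C-alpha centroid sits exactly at the origin (so a
#' fitted axis anchor coincides with the placement position when the helix
#' is translated).  Pseudo-C-beta atoms, when requested, are 1.5 A
#' radially outward of non-glycine C-alphas.
#'
#' @param spec a [helixSpec()].
#' @return a [HelixStructure-class].
#' @export
buildIdealHelix <- function(spec) {
  stopifnot(inherits(spec, "helixSpec"))
  n <- spec$nResidues
  i <- seq_len(n)
  az <- .rad((i - 1) * spec$twist)
  ca <- cbind(spec$radius * cos(az), spec$radius * sin(az),
              (i - (n + 1) / 2) * spec$rise)
  ca <- sweep(ca, 2, colMeans(ca))   # CA centroid exactly at origin
  aa <- strsplit(spec$sequence, "")[[1]]
  resid3 <- unname(.AA31[aa])
  if (anyNA(resid3)) stop("unknown 1-letter code in sequence")
  caDf <- data.frame(chain = spec$chain, resno = spec$firstResidue + i - 1L,
                     resid = resid3, elety = "CA",
                     x = ca[, 1], y = ca[, 2], z = ca[, 3],
                     stringsAsFactors = FALSE)
  at <- caDf
  if (spec$cbeta && any(aa != "G")) {
    k <- which(aa != "G")
    cbDf <- data.frame(chain = spec$chain, resno = spec$firstResidue + k - 1L,
                       resid = resid3[k], elety = "CB",
                       x = ca[k, 1] + 1.5 * cos(az[k]),
                       y = ca[k, 2] + 1.5 * sin(az[k]),
                       z = ca[k, 3], stringsAsFactors = FALSE)
    at <- rbind(caDf, cbDf)
    at <- at[order(at$resno, at$elety), , drop = FALSE]
    rownames(at) <- NULL
  }
  new("HelixStructure", atoms = at,
      label = sprintf("ideal_helix;chain=%s;n=%d", spec$chain, n))
}

.applyToChain <- function(atoms, chain, f) {
  idx <- atoms$chain == chain
  xyz <- as.matrix(atoms[idx, c("x", "y", "z")])
  atoms[idx, c("x", "y", "z")] <- f(xyz)
  atoms
}

#' Build a two-helix dimer at prescribed crossing geometry
#'
#' Helix A is placed vertically at the origin, spun about its own axis so
#' that body azimuth \code{interfaceAzimuthA} faces the partner (+x).
#' Helix B is spun so \code{interfaceAzimuthB} faces A (-x), translated to
#' \code{(separation, 0, zOffset)} and then rotated by \code{omega} about
#' the interhelix connector axis, which sets the measured signed crossing
#' angle to \code{omega} (negative = right-handed).  Construction
#' parameters are recorded in the structure label.
#'
#' @param specA,specB [helixSpec()]s for the two helices (chains must
#'   differ).
#' @param omega target signed crossing angle, degrees.
#' @param separation axis separation, Angstrom (> 2 radius).
#' @param interfaceAzimuthA,interfaceAzimuthB body-frame azimuth of each
#'   helix aimed at the partner, degrees (see [residueAzimuth()]).
#' @param zOffset relative insertion depth of helix B, Angstrom.
#' @return a [HelixStructure-class] containing both chains.
#' @examples
#' d <- buildDimer(defaultAlphaSpec(), defaultBetaSpec(), omega = -30)
#' structureCrossing(d)   # ~ -30 deg, RH
#' @export
buildDimer <- function(specA = defaultAlphaSpec(), specB = defaultBetaSpec(),
                       omega = -30, separation = 10,
                       interfaceAzimuthA = residueAzimuth(specA, c(972, 976)),
                       interfaceAzimuthB = 0, zOffset = 0) {
  if (specA$chain == specB$chain) stop("the two helices must use distinct chains")
  if (separation <= 2 * max(specA$radius, specB$radius))
    stop("separation must exceed the helix diameter")
  hA <- buildIdealHelix(specA)
  hB <- buildIdealHelix(specB)
  atA <- .applyToChain(hA@atoms, specA$chain, function(xyz)
    .rotateAbout(xyz, c(0, 0, 1), -interfaceAzimuthA))
  atB <- .applyToChain(hB@atoms, specB$chain, function(xyz)
    .rotateAbout(xyz, c(0, 0, 1), 180 - interfaceAzimuthB))
  atB <- .applyToChain(atB, specB$chain, function(xyz)
    sweep(xyz, 2, c(separation, 0, zOffset), `+`))
  # crossing rotation about the interhelix connector (x axis through B's centre)
  atB <- .applyToChain(atB, specB$chain, function(xyz)
    .rotateAbout(xyz, c(1, 0, 0), omega, point = c(separation, 0, zOffset)))
  at <- rbind(atA, atB)
  xa <- as.matrix(atA[, c("x", "y", "z")])
  xb <- as.matrix(atB[, c("x", "y", "z")])
  dmin <- sqrt(max(min(outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)), 0))
  if (is.finite(dmin) && dmin < 2)
    stop(sprintf("infeasible geometry: interhelix clash (min distance %.2f A)", dmin))
  new("HelixStructure", atoms = at,
      label = sprintf("dimer;omega=%.4f;separation=%.4f;azimuthA=%.4f;azimuthB=%.4f;zOffset=%.4f",
                      omega, separation, interfaceAzimuthA, interfaceAzimuthB,
                      zOffset))
}

#' Default packing modes of the synthetic bimodal ensemble
#'
#' The major right-handed mode holds 70% of the weight with mean crossing
#' angle -30 degrees (sd 8); the minor left-handed mode holds 30% at +30
#' degrees (sd 10) on the opposite interface azimuth of the reference
#' helix.  The mobile helix presents its GxxxG face to the partner in the
#' RH mode and turns it away in the LH mode.
#'
#' @return data.frame with columns \code{label}, \code{weight},
#'   \code{omegaMean}, \code{omegaSd}, \code{azimuth} (reference-helix
#'   interface azimuth, which is where the mobile helix appears in the
#'   density map), \code{positionalSd} (A), \code{azimuthMobile}.
#' @export
defaultPackingModes <- function() {
  gFace <- residueAzimuth(defaultAlphaSpec(), c(972, 976))
  data.frame(label = c("RH1", "LH"), weight = c(0.70, 0.30),
             omegaMean = c(-30, 30), omegaSd = c(8, 10),
             azimuth = c(0, 180), positionalSd = c(0.5, 0.5),
             azimuthMobile = c(gFace, (gFace + 180) %% 360),
             stringsAsFactors = FALSE)
}

#' Generate a mode-mixture ensemble of dimers
#'
#' Each member samples a packing mode by weight, a crossing angle from that
#' mode's normal distribution, and jittered interface azimuths/separation,
#' then builds the dimer.  The true mode label and drawn parameters are
#' stored in the member provenance, so sign-classification and density
#' analyses can be scored as parameter recovery.  Deterministic under a
#' fixed seed.
#'
#' @param nMembers number of members.
#' @param modes mode table as in [defaultPackingModes()].
#' @param separation mean axis separation, Angstrom.
#' @param seed integer seed.
#' @param specA,specB helix specs.
#' @return a [StructureEnsemble-class].
#' @export
generateModeEnsemble <- function(nMembers = 1000L, modes = defaultPackingModes(),
                                 separation = 10, seed = 1L,
                                 specA = defaultAlphaSpec(),
                                 specB = defaultBetaSpec()) {
  if (any(modes$weight < 0) || abs(sum(modes$weight) - 1) > 1e-9)
    stop("mode weights must be non-negative and sum to 1")
  if (nMembers < 1L) stop("nMembers must be >= 1")
  .withSeed(seed, {
    members <- vector("list", nMembers)
    prov <- character(nMembers)
    modeIdx <- sample.int(nrow(modes), nMembers, replace = TRUE,
                          prob = modes$weight)
    for (i in seq_len(nMembers)) {
      m <- modes[modeIdx[i], ]
      # redraw the member's jitters on the (rare) sterically infeasible draw
      for (try in 1:25) {
        om <- stats::rnorm(1, m$omegaMean, m$omegaSd)
        sdDeg <- .deg(m$positionalSd / separation)
        azB <- m$azimuth + stats::rnorm(1, 0, sdDeg)
        azA <- m$azimuthMobile + stats::rnorm(1, 0, sdDeg)
        sep <- max(separation + stats::rnorm(1, 0, m$positionalSd),
                   2 * max(specA$radius, specB$radius) + 0.6)
        zo <- stats::rnorm(1, 0, m$positionalSd)
        d <- tryCatch(buildDimer(specA, specB, omega = om, separation = sep,
                                 interfaceAzimuthA = azA,
                                 interfaceAzimuthB = azB, zOffset = zo),
                      error = function(e) NULL)
        if (!is.null(d)) break
      }
      if (is.null(d)) stop("could not draw a clash-free member for mode ", m$label)
      members[[i]] <- d
      prov[i] <- sprintf("member=%d;mode=%s;omega=%.4f;azimuthB=%.4f;separation=%.4f",
                         i, m$label, om, azB, sep)
    }
    new("StructureEnsemble", members = members, provenance = prov)
  })
}

#' Generate a diffusion--association trajectory
#'
#' Two vertical helices in the bilayer plane; the helix centres perform a
#' seeded 2D random walk, with frame-1 axis separation exactly
#' \code{initialSeparation} (60 A by default, large enough that no
#' interhelix interaction is implied at the start).  If \code{bindFrame} is
#' set, the approach is steered so that a persistent encounter (separation
#' below \code{boundSeparation}) starts exactly at that frame and the dimer
#' stays bound afterwards.  Axes carry a small angular jitter.
#'
#' @param nFrames number of frames.
#' @param initialSeparation frame-1 centre separation, Angstrom.
#' @param stepSd per-frame random-walk step standard deviation, Angstrom.
#' @param bindFrame frame (1-based) of the forced encounter, or NULL for
#'   free diffusion.
#' @param boundSeparation bound-state separation, Angstrom.
#' @param tiltSd axis angular jitter, degrees.
#' @param dt frame spacing, ns.
#' @param seed integer seed.
#' @param specA,specB helix specs.
#' @return a [HelixTrajectory-class]; the label records
#'   \code{initialSeparation} and \code{bindFrame}.
#' @export
generateAssemblyTrajectory <- function(nFrames = 300L, initialSeparation = 60,
                                       stepSd = 1, bindFrame = NULL,
                                       boundSeparation = 7, tiltSd = 1.5,
                                       dt = 1, seed = 1L,
                                       specA = defaultAlphaSpec(),
                                       specB = defaultBetaSpec()) {
  if (initialSeparation <= 8)
    stop("initialSeparation must exceed the contact distance")
  hA <- buildIdealHelix(specA)
  hB <- buildIdealHelix(specB)
  xb0 <- coords(hB)
  atB <- hB@atoms
  atB[, c("x", "y", "z")] <- sweep(xb0, 2, c(initialSeparation, 0, 0), `+`)
  topo <- new("HelixStructure", atoms = rbind(hA@atoms, atB),
              label = "assembly_topology")
  nA <- nAtoms(hA)
  .withSeed(seed, {
    sep <- numeric(nFrames)
    sep[1] <- initialSeparation
    if (is.null(bindFrame)) {
      for (t in seq_len(nFrames)[-1])
        sep[t] <- abs(sep[t - 1] + stats::rnorm(1, 0, stepSd))
    } else {
      stopifnot(bindFrame >= 2L, bindFrame <= nFrames)
      approach <- seq(initialSeparation, boundSeparation + 4,
                      length.out = bindFrame)[-bindFrame]
      pre <- pmax(approach + stats::rnorm(bindFrame - 1L, 0, min(stepSd, 0.3)),
                  boundSeparation + 3.2)
      pre[1] <- initialSeparation
      post <- pmin(pmax(boundSeparation + stats::rnorm(nFrames - bindFrame + 1L, 0, 0.25),
                        boundSeparation - 0.7), 7.7)
      sep <- c(pre, post)
    }
    theta <- cumsum(c(0, stats::rnorm(nFrames - 1L, 0, .rad(2))))
    xyz <- matrix(0, nFrames, 3L * nAtoms(topo))
    xa0 <- coords(hA)
    for (t in seq_len(nFrames)) {
      tiltAxis <- c(cos(stats::runif(1, 0, 2 * pi)),
                    sin(stats::runif(1, 0, 2 * pi)), 0)
      xa <- .rotateAbout(xa0, tiltAxis, stats::rnorm(1, 0, tiltSd))
      tiltAxis2 <- c(cos(stats::runif(1, 0, 2 * pi)),
                     sin(stats::runif(1, 0, 2 * pi)), 0)
      xb <- .rotateAbout(xb0, tiltAxis2, stats::rnorm(1, 0, tiltSd))
      ctr <- sep[t] * c(cos(theta[t]), sin(theta[t]), 0)
      xb <- sweep(xb, 2, ctr, `+`)
      if (t == 1L) { xa <- xa0; xb <- sweep(xb0, 2, c(initialSeparation, 0, 0), `+`) }
      xyz[t, ] <- as.vector(t(rbind(xa, xb)))
    }
    new("HelixTrajectory", topology = topo, xyz = xyz,
        times = (seq_len(nFrames) - 1) * dt,
        label = sprintf("assembly;initialSeparation=%.4f;bindFrame=%s;seed=%d",
                        initialSeparation,
                        if (is.null(bindFrame)) "none" else bindFrame,
                        as.integer(seed)))
  })
}

# Scale a zero-mean per-atom deformation so the Kabsch RMSD of
# (start + deformation) against start equals `target`.
.calibrateDeformation <- function(start, D, target) {
  if (target <= 0) return(D * 0)
  s <- 1
  for (k in 1:6) {
    cur <- kabschSuperpose(start + s * D, start)$rmsd
    if (cur < 1e-12) break
    s <- s * target / cur
  }
  s * D
}

#' Generate a plateauing or steadily drifting trajectory
#'
#' Emulates the two stability archetypes of membrane-protein model
#' assessment: a \code{"plateau"} trajectory whose C-alpha RMSD from the
#' start rises quickly and then fluctuates around \code{terminalRmsd}
#' (stable when below ~3 A), and a \code{"ramp"} trajectory whose RMSD
#' grows linearly to \code{terminalRmsd} at the final frame (the unstable
#' archetype).  The displacement is a fixed random per-atom deformation
#' calibrated so the superposed RMSD hits the target.
#'
#' @param start a [HelixStructure-class] (frame 1 and RMSD reference).
#' @param terminalRmsd target RMSD, Angstrom.
#' @param nFrames frames.
#' @param totalTime trajectory length, ns.
#' @param mode \code{"plateau"} or \code{"ramp"}.
#' @param noiseSd per-frame per-atom positional noise, Angstrom.
#' @param rampIn fraction of the run used to reach the plateau.
#' @param seed integer seed.
#' @return a [HelixTrajectory-class].
#' @export
generateDriftTrajectory <- function(start, terminalRmsd, nFrames = 120L,
                                    totalTime = 30, mode = c("plateau", "ramp"),
                                    noiseSd = 0.1, rampIn = 0.1, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(terminalRmsd >= 0)
  x0 <- coords(start)
  n <- nrow(x0)
  .withSeed(seed, {
    D <- matrix(stats::rnorm(3 * n), n, 3)
    D <- sweep(D, 2, colMeans(D))
    D <- .calibrateDeformation(x0, D, terminalRmsd)
    tfrac <- (seq_len(nFrames) - 1) / (nFrames - 1)
    g <- switch(mode,
                plateau = pmin(1, tfrac / max(rampIn, 1e-9)),
                ramp = tfrac)
    xyz <- matrix(0, nFrames, 3 * n)
    for (t in seq_len(nFrames)) {
      noise <- if (noiseSd > 0) {
        Nz <- matrix(stats::rnorm(3 * n, 0, noiseSd), n, 3)
        sweep(Nz, 2, colMeans(Nz))
      } else 0
      xyz[t, ] <- as.vector(t(x0 + g[t] * D + noise))
    }
    new("HelixTrajectory", topology = start, xyz = xyz,
        times = tfrac * totalTime,
        label = sprintf("drift;mode=%s;terminalRmsd=%.4f;seed=%d", mode,
                        terminalRmsd, as.integer(seed)))
  })
}

#' Generate a rotation-scan ensemble of initial configurations
#'
#' Member \code{i} is the base structure with the designated helix spun by
#' \code{i * increment} degrees about its own fitted axis (all other
#' coordinates identical), emulating an initial-configuration scan in
#' 15-degree increments.
#'
#' @param base a [HelixStructure-class].
#' @param chain chain to rotate (default the reference/beta3-like helix
#'   \code{"B"}).
#' @param increment rotation step, degrees (> 0).
#' @param n number of members.
#' @return a [StructureEnsemble-class]; provenance records each member's
#'   rotation.
#' @export
generateRotationScan <- function(base, chain = "B", increment = 15, n = 24L) {
  stopifnot(increment > 0, n >= 1L)
  ax <- fitHelixAxis(.helixCalpha(base, chain, NULL))
  members <- vector("list", n)
  prov <- character(n)
  for (i in seq_len(n)) {
    rot <- i * increment
    at <- .applyToChain(base@atoms, chain, function(xyz)
      .rotateAbout(xyz, axisDirection(ax), rot, point = axisAnchor(ax)))
    members[[i]] <- new("HelixStructure", atoms = at,
                        label = sprintf("%s;scanRotation=%.4f", base@label, rot))
    prov[i] <- sprintf("member=%d;scanRotation=%.4f;chain=%s", i, rot, chain)
  }
  new("StructureEnsemble", members = members, provenance = prov)
}

#' Parse a construction label/provenance string
#'
#' Generator bookkeeping is stored as \code{key=value;key=value} strings;
#' this returns them as a named character vector.
#'
#' @param x a label or provenance string.
#' @return named character vector.
#' @export
parseProvenance <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts[grepl("=", parts, fixed = TRUE)], "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, character(1), 2),
                  vapply(kv, `[`, character(1), 1))
}
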