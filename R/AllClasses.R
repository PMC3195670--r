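#' @import methods
NULL

.ATOM_COLS <- c("chain", "resno", "resid", "elety", "x", "y", "z")

.validAtoms <- function(atoms) {
  msg <- character(0)
  if (!is.data.frame(atoms) || !all(.ATOM_COLS %in% names(atoms)))
    return(paste("atoms must be a data.frame with columns",
                 paste(.ATOM_COLS, collapse = ", ")))
  if (nrow(atoms) == 0L)
    msg <- c(msg, "structure must contain at least one atom")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) > 0L && !all(is.finite(xyz)))
    msg <- c(msg, "atom coordinates must be finite")
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    msg <- c(msg, "(chain, resno, elety) must be unique within a structure")
  for (ch in unique(atoms$chain)) {
    rn <- atoms$resno[atoms$chain == ch]
    if (is.unsorted(rn))
      msg <- c(msg, sprintf("residue numbers in chain %s must be non-decreasing", ch))
  }
  if (length(msg)) msg else TRUE
}

#' One conformation of a (two-)helix system
#'
#' A labelled set of atoms with 3D coordinates in Angstrom.  Atom records
#' carry author residue numbering (no renumbering on read), so residues such
#' as the alphaIIb glycines G972/G976 are addressable exactly as published.
#'
#' @slot atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resid} (3-letter code), \code{elety} (atom name, e.g. \code{CA}),
#'   and coordinates \code{x}, \code{y}, \code{z} in Angstrom.
#' @slot label free-text label; synthetic generators record their
#'   construction parameters here as \code{key=value} pairs.
#'
#' @seealso [readStructure()], [selectAtoms()], [buildIdealHelix()]
#' @export
setClass("HelixStructure",
         representation(atoms = "data.frame", label = "character"),
         prototype(label = ""),
         validity = function(object) {
           ok <- .validAtoms(object@atoms)
           if (isTRUE(ok) && length(object@label) != 1L)
             return("label must be a single character string")
           ok
         })

#' Ordered frames sharing one topology
#'
#' A time series of coordinate snapshots over a fixed atom labelling.
#' Coordinates are stored bio3d-style as an \code{nFrames x (3 nAtoms)}
#' matrix.  Frame times, when present, are in nanoseconds and strictly
#' increasing.
#'
#' @slot topology a [HelixStructure-class] supplying atom labels (its own
#'   coordinates are frame 1 by convention of the constructors).
#' @slot xyz numeric matrix, one row per frame, columns x1,y1,z1,x2,...
#' @slot times numeric, length 0 (untimed) or \code{nFrames}, in ns.
#' @slot label free-text construction/provenance label.
#' @export
setClass("HelixTrajectory",
         representation(topology = "HelixStructure", xyz = "matrix",
                        times = "numeric", label = "character"),
         prototype(times = numeric(0), label = ""),
         validity = function(object) {
           na <- nrow(object@topology@atoms)
           if (ncol(object@xyz) != 3L * na)
             return("xyz must have 3 columns per topology atom")
           if (nrow(object@xyz) < 1L)
             return("trajectory must contain at least one frame")
           if (!all(is.finite(object@xyz)))
             return("frame coordinates must be finite")
           nt <- length(object@times)
           if (nt != 0L && nt != nrow(object@xyz))
             return("times must be empty or one per frame")
           if (nt > 1L && any(diff(object@times) <= 0))
             return("frame times must be strictly increasing")
           TRUE
         })

#' A bag of structures and/or trajectories
#'
#' Holds the members of a simulation ensemble (for example ~100 independent
#' self-assembly runs, or the models of a deposited NMR ensemble) together
#' with per-member provenance strings.
#'
#' @slot members list of [HelixStructure-class] and/or
#'   [HelixTrajectory-class] objects sharing chain/residue naming for the
#'   two helices.
#' @slot provenance character, one entry per member (source path + model
#'   index for files; construction truth for synthetic members).
#' @export
setClass("StructureEnsemble",
         representation(members = "list", provenance = "character"),
         validity = function(object) {
           if (length(object@members) < 1L)
             return("ensemble must have at least one member")
           ok <- vapply(object@members, function(m)
             is(m, "HelixStructure") || is(m, "HelixTrajectory"), logical(1))
           if (!all(ok))
             return("members must be HelixStructure or HelixTrajectory objects")
           if (length(object@provenance) != length(object@members))
             return("provenance must have one entry per member")
           TRUE
         })

#' Fitted axis of a single transmembrane helix
#'
#' @slot anchor numeric(3), axis anchor (C-alpha centroid), Angstrom.
#' @slot direction numeric(3), unit vector oriented N-terminus to
#'   C-terminus.
#' @slot halfLength numeric(1), half the axial extent of the fitted
#'   residues, Angstrom.  The finite axis segment is
#'   \code{anchor +/- halfLength * direction}.
#' @export
setClass("HelixAxis",
         representation(anchor = "numeric", direction = "numeric",
                        halfLength = "numeric"),
         validity = function(object) {
           if (length(object@anchor) != 3L || length(object@direction) != 3L)
             return("anchor and direction must be length-3 numeric")
           if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-9)
             return("direction must be a unit vector")
           if (length(object@halfLength) != 1L || object@halfLength <= 0)
             return("halfLength must be a positive scalar")
           TRUE
         })

#' Signed crossing geometry of a helix pair
#'
#' The crossing angle omega is the signed acute angle between the two helix
#' axes, in (-90, +90] degrees.  Following the usual membrane-protein
#' convention, a negative omega corresponds to right-handed (RH) helix
#' packing and a positive omega to left-handed (LH) packing.
#'
#' @slot omega signed crossing angle, degrees.
#' @slot handedness one of \code{"RH"}, \code{"LH"}, \code{"indeterminate"}.
#' @slot closestDistance closest-approach distance between the finite axis
#'   segments, Angstrom.
#' @slot closestPoints 2 x 3 matrix; row 1 on axis a, row 2 on axis b.
#' @export
setClass("CrossingGeometry",
         representation(omega = "numeric", handedness = "character",
                        closestDistance = "numeric", closestPoints = "matrix"),
         validity = function(object) {
           if (!object@handedness %in% c("RH", "LH", "indeterminate"))
             return("handedness must be RH, LH or indeterminate")
           if (object@closestDistance < 0)
             return("closestDistance must be >= 0")
           if (object@omega <= -90 || object@omega > 90)
             return("omega must lie in (-90, 90]")
           TRUE
         })

#' Crossing-angle distribution over an ensemble
#'
#' @slot samples data.frame with one row per analysed conformation:
#'   \code{member}, \code{frame}, \code{omega} (degrees), \code{handedness},
#'   \code{weight} (members contribute equal total weight).
#' @slot binWidth histogram bin width, degrees.
#' @slot breaks histogram bin edges, degrees.
#' @slot histogram weighted counts per bin (sums to number of members).
#' @slot fractionRH,fractionLH fractions of determinate weight classified
#'   right-/left-handed; the remainder is indeterminate.
#' @slot modeMeans named numeric: weighted mean omega of the RH and LH
#'   sign classes.
#' @export
setClass("AngleDistribution",
         representation(samples = "data.frame", binWidth = "numeric",
                        breaks = "numeric", histogram = "numeric",
                        fractionRH = "numeric", fractionLH = "numeric",
                        modeMeans = "numeric"),
         validity = function(object) {
           if (object@fractionRH + object@fractionLH > 1 + 1e-9)
             return("fractionRH + fractionLH must be <= 1")
           TRUE
         })

#' 2D spatial probability-density map in the bilayer plane
#'
#' Normalised occupancy probability of the mobile helix around the
#' reference-fitted helix, on a regular grid in the xy (bilayer) plane of
#' the canonical frame, plus the detected density maxima (packing modes).
#'
#' @slot origin numeric(2), lower-left corner of cell (1,1), Angstrom.
#' @slot cellSize numeric(1), grid cell edge, Angstrom.
#' @slot values matrix of cell probabilities (sum = 1); rows index x,
#'   columns index y.
#' @slot maxima data.frame ranked by basin mass: \code{label}, \code{x},
#'   \code{y} (cell-centre position), \code{peak} (smoothed peak density),
#'   \code{mass} (watershed basin mass in (0,1]), \code{minor} (below the
#'   minor-mode threshold).
#' @export
setClass("DensityMap",
         representation(origin = "numeric", cellSize = "numeric",
                        values = "matrix", maxima = "data.frame"),
         validity = function(object) {
           if (any(object@values < -1e-12))
             return("density values must be non-negative")
           if (abs(sum(object@values) - 1) > 1e-9)
             return("density values must sum to 1")
           if (nrow(object@maxima) && sum(object@maxima$mass) > 1 + 1e-9)
             return("basin masses must sum to <= 1")
           TRUE
         })

#' Per-simulation conformational stability report
#'
#' @slot series data.frame with columns \code{time} (ns) and \code{rmsd}
#'   (Angstrom).
#' @slot plateauValue mean RMSD over the final window, Angstrom.
#' @slot driftRate robust (Theil-Sen) slope over the final half, Angstrom/ns.
#' @slot classification \code{"stable"}, \code{"unstable"} or
#'   \code{"indeterminate"}.
#' @slot angleSpread named numeric (\code{min}, \code{max}, \code{sd}) of the
#'   determinate crossing angles, degrees; NA when no angle series given.
#' @export
setClass("StabilityReport",
         representation(series = "data.frame", plateauValue = "numeric",
                        driftRate = "numeric", classification = "character",
                        angleSpread = "numeric"),
         validity = function(object) {
           if (object@plateauValue < 0)
             return("plateauValue must be >= 0")
           if (!object@classification %in% c("stable", "unstable", "indeterminate"))
             return("classification must be stable, unstable or indeterminate")
           TRUE
         })

#' Inter-chain residue contact set
#'
#' @slot contacts data.frame with columns \code{resnoA}, \code{residA},
#'   \code{resnoB}, \code{residB}, \code{distance} (Angstrom); each
#'   inter-chain residue pair at most once, distance <= cutoff.
#' @slot chainA,chainB the two chain identifiers.
#' @slot cutoff distance cutoff, Angstrom.
#' @slot metric \code{"heavy-atom"} (minimum heavy-atom distance) or
#'   \code{"residue-center"} (distance between residue centroids, used for
#'   backbone-only / coarse-grained-like inputs).
#' @export
setClass("ContactSet",
         representation(contacts = "data.frame", chainA = "character",
                        chainB = "character", cutoff = "numeric",
                        metric = "character"),
         validity = function(object) {
           if (nrow(object@contacts) &&
               any(object@contacts$distance > object@cutoff + 1e-9))
             return("all contact distances must be <= cutoff")
           if (!object@metric %in% c("heavy-atom", "residue-center"))
             return("metric must be heavy-atom or residue-center")
           TRUE
         })
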