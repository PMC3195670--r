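#' Accessors for helixpack classes
#'
#' Small accessor generics: slot access from user code should go through
#' these rather than \code{@}.
#'
#' @param x a helixpack object.
#' @return \code{atoms()} the atom table; \code{coords()} an
#'   \code{nAtoms x 3} coordinate matrix; \code{nAtoms()}, \code{nFrames()},
#'   \code{nMembers()} integer counts; \code{frameCoords()} one frame as an
#'   \code{nAtoms x 3} matrix; \code{frameTimes()} times in ns;
#'   \code{members()} / \code{provenance()} ensemble content;
#'   \code{structureLabel()} the free-text label.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("structureLabel", function(x) standardGeneric("structureLabel"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @param i frame index (1-based).
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname accessors
#' @export
setGeneric("nMembers", function(x) standardGeneric("nMembers"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setMethod("atoms", "HelixStructure", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("coords", "HelixStructure", function(x)
  unname(as.matrix(x@atoms[, c("x", "y", "z")])))
#' @rdname accessors
#' @export
setMethod("nAtoms", "HelixStructure", function(x) nrow(x@atoms))
#' @rdname accessors
#' @export
setMethod("structureLabel", "HelixStructure", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("structureLabel", "HelixTrajectory", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("atoms", "HelixTrajectory", function(x) x@topology@atoms)
#' @rdname accessors
#' @export
setMethod("nAtoms", "HelixTrajectory", function(x) nrow(x@topology@atoms))
#' @rdname accessors
#' @export
setMethod("nFrames", "HelixTrajectory", function(x) nrow(x@xyz))
#' @rdname accessors
#' @export
setMethod("frameCoords", "HelixTrajectory", function(x, i) {
  stopifnot(i >= 1L, i <= nrow(x@xyz))
  matrix(x@xyz[i, ], ncol = 3L, byrow = TRUE)
})
#' @rdname accessors
#' @export
setMethod("frameTimes", "HelixTrajectory", function(x) {
  if (length(x@times)) x@times else seq_len(nrow(x@xyz)) - 1
})
#' @rdname accessors
#' @export
setMethod("members", "StructureEnsemble", function(x) x@members)
#' @rdname accessors
#' @export
setMethod("nMembers", "StructureEnsemble", function(x) length(x@members))
#' @rdname accessors
#' @export
setMethod("provenance", "StructureEnsemble", function(x) x@provenance)

#' Extract one frame of a trajectory as a structure
#'
#' @param x a [HelixTrajectory-class].
#' @param i frame index.
#' @return a [HelixStructure-class] with the topology's labels and frame
#'   \code{i}'s coordinates.
#' @export
setGeneric("frameStructure", function(x, i) standardGeneric("frameStructure"))

#' @rdname frameStructure
#' @export
setMethod("frameStructure", "HelixTrajectory", function(x, i) {
  at <- x@topology@atoms
  at[, c("x", "y", "z")] <- frameCoords(x, i)
  new("HelixStructure", atoms = at,
      label = sprintf("%s;frame=%d", x@label, i))
})

#' Crossing-geometry accessors
#'
#' @param x a [CrossingGeometry-class] object.
#' @return \code{omega()} the signed crossing angle in degrees;
#'   \code{handedness()} the packing-handedness class;
#'   \code{closestDistance()} the closest-approach distance in Angstrom.
#' @name crossing-accessors
NULL

#' @rdname crossing-accessors
#' @export
setGeneric("omega", function(x) standardGeneric("omega"))
#' @rdname crossing-accessors
#' @export
setGeneric("handedness", function(x) standardGeneric("handedness"))
#' @rdname crossing-accessors
#' @export
setGeneric("closestDistance", function(x) standardGeneric("closestDistance"))
#' @rdname crossing-accessors
#' @export
setMethod("omega", "CrossingGeometry", function(x) x@omega)
#' @rdname crossing-accessors
#' @export
setMethod("handedness", "CrossingGeometry", function(x) x@handedness)
#' @rdname crossing-accessors
#' @export
setMethod("closestDistance", "CrossingGeometry", function(x) x@closestDistance)

#' Axis accessors
#'
#' @param x a [HelixAxis-class].
#' @return \code{axisAnchor()} / \code{axisDirection()} numeric(3);
#'   \code{axisHalfLength()} scalar Angstrom; \code{axisSegment()} a 2 x 3
#'   matrix with the segment end points (N-side first).
#' @name axis-accessors
NULL

#' @rdname axis-accessors
#' @export
setGeneric("axisAnchor", function(x) standardGeneric("axisAnchor"))
#' @rdname axis-accessors
#' @export
setGeneric("axisDirection", function(x) standardGeneric("axisDirection"))
#' @rdname axis-accessors
#' @export
setGeneric("axisHalfLength", function(x) standardGeneric("axisHalfLength"))
#' @rdname axis-accessors
#' @export
setGeneric("axisSegment", function(x) standardGeneric("axisSegment"))
#' @rdname axis-accessors
#' @export
setMethod("axisAnchor", "HelixAxis", function(x) x@anchor)
#' @rdname axis-accessors
#' @export
setMethod("axisDirection", "HelixAxis", function(x) x@direction)
#' @rdname axis-accessors
#' @export
setMethod("axisHalfLength", "HelixAxis", function(x) x@halfLength)
#' @rdname axis-accessors
#' @export
setMethod("axisSegment", "HelixAxis", function(x)
  rbind(x@anchor - x@halfLength * x@direction,
        x@anchor + x@halfLength * x@direction))

#' Density-map accessors
#'
#' @param x a [DensityMap-class].
#' @return \code{densityValues()} the probability matrix;
#'   \code{densityMaxima()} the ranked maxima table; \code{cellCenters()} a
#'   list with vectors \code{x} and \code{y} of cell-centre coordinates.
#' @name density-accessors
NULL

#' @rdname density-accessors
#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))
#' @rdname density-accessors
#' @export
setGeneric("densityMaxima", function(x) standardGeneric("densityMaxima"))
#' @rdname density-accessors
#' @export
setGeneric("cellCenters", function(x) standardGeneric("cellCenters"))
#' @rdname density-accessors
#' @export
setMethod("densityValues", "DensityMap", function(x) x@values)
#' @rdname density-accessors
#' @export
setMethod("densityMaxima", "DensityMap", function(x) x@maxima)
#' @rdname density-accessors
#' @export
setMethod("cellCenters", "DensityMap", function(x)
  list(x = x@origin[1] + (seq_len(nrow(x@values)) - 0.5) * x@cellSize,
       y = x@origin[2] + (seq_len(ncol(x@values)) - 0.5) * x@cellSize))

#' Contact-set accessors
#'
#' @param x a [ContactSet-class].
#' @return \code{contacts()} the contact table; \code{contactCutoff()} the
#'   cutoff in Angstrom.
#' @name contact-accessors
NULL

#' @rdname contact-accessors
#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))
#' @rdname contact-accessors
#' @export
setGeneric("contactCutoff", function(x) standardGeneric("contactCutoff"))
#' @rdname contact-accessors
#' @export
setMethod("contacts", "ContactSet", function(x) x@contacts)
#' @rdname contact-accessors
#' @export
setMethod("contactCutoff", "ContactSet", function(x) x@cutoff)

setMethod("show", "HelixStructure", function(object) {
  at <- object@atoms
  cat(sprintf("HelixStructure: %d atoms, %d residues, chains %s\n",
              nrow(at), length(unique(paste(at$chain, at$resno))),
              paste(unique(at$chain), collapse = ",")))
  if (nzchar(object@label)) cat("  label:", object@label, "\n")
})

setMethod("show", "HelixTrajectory", function(object) {
  cat(sprintf("HelixTrajectory: %d frames x %d atoms", nrow(object@xyz),
              nrow(object@topology@atoms)))
  if (length(object@times))
    cat(sprintf(", t = %g..%g ns", object@times[1],
                object@times[length(object@times)]))
  cat("\n")
  if (nzchar(object@label)) cat("  label:", object@label, "\n")
})

setMethod("show", "StructureEnsemble", function(object) {
  kinds <- vapply(object@members, function(m) class(m)[1], character(1))
  cat(sprintf("StructureEnsemble: %d members (%s)\n", length(object@members),
              paste(sprintf("%d %s", table(kinds), names(table(kinds))),
                    collapse = ", ")))
})

setMethod("show", "HelixAxis", function(object) {
  cat(sprintf("HelixAxis: anchor (%.2f, %.2f, %.2f), direction (%.3f, %.3f, %.3f), half-length %.2f A\n",
              object@anchor[1], object@anchor[2], object@anchor[3],
              object@direction[1], object@direction[2], object@direction[3],
              object@halfLength))
})

setMethod("show", "CrossingGeometry", function(object) {
  cat(sprintf("CrossingGeometry: omega = %+.2f deg (%s), closest approach %.2f A\n",
              object@omega, object@handedness, object@closestDistance))
})

setMethod("show", "AngleDistribution", function(object) {
  cat(sprintf("AngleDistribution: %d samples, RH %.1f%% (mean %+.1f deg), LH %.1f%% (mean %+.1f deg)\n",
              nrow(object@samples), 100 * object@fractionRH,
              object@modeMeans["RH"], 100 * object@fractionLH,
              object@modeMeans["LH"]))
})

setMethod("show", "DensityMap", function(object) {
  cat(sprintf("DensityMap: %d x %d grid, cell %.2f A, %d maxima\n",
              nrow(object@values), ncol(object@values), object@cellSize,
              nrow(object@maxima)))
  if (nrow(object@maxima)) {
    m <- object@maxima
    for (i in seq_len(nrow(m)))
      cat(sprintf("  %s: (%.1f, %.1f) A, basin mass %.2f%s\n", m$label[i],
                  m$x[i], m$y[i], m$mass[i],
                  if (m$minor[i]) " [minor]" else ""))
  }
})

setMethod("show", "StabilityReport", function(object) {
  cat(sprintf("StabilityReport: %s (plateau %.2f A, drift %+.3f A/ns)\n",
              object@classification, object@plateauValue, object@driftRate))
  if (all(is.finite(object@angleSpread)))
    cat(sprintf("  crossing-angle spread: %.1f..%.1f deg (sd %.1f)\n",
                object@angleSpread["min"], object@angleSpread["max"],
                object@angleSpread["sd"]))
})

setMethod("show", "ContactSet", function(object) {
  cat(sprintf("ContactSet: %d inter-chain residue contacts (%s, cutoff %.1f A) between chains %s and %s\n",
              nrow(object@contacts), object@metric, object@cutoff,
              object@chainA, object@chainB))
})
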