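# Helix/helix interface characterisation: inter-chain residue contacts,
# interface residue sets, residue orientation toward/away from the
# partner helix, and interface overlap between two structures.

.BACKBONE <- c("N", "CA", "C", "O", "CB")

#' Inter-chain residue contact map
#'
#' Lists every inter-chain residue pair in contact.  For atomistic
#' structures (side-chain atoms present in both chains) the metric is the
#' minimum heavy-atom distance with a 4.5 A default cutoff; for
#' backbone-only / coarse-grained-like inputs it falls back to the distance
#' between residue centroids with a 7 A default cutoff.  The chosen metric
#' is reported in the returned object and via \code{message()}.
#'
#' @param structure a [HelixStructure-class] containing both chains.
#' @param chainA,chainB chain identifiers.
#' @param cutoff distance cutoff, Angstrom; default depends on the
#'   auto-selected metric.
#' @param metric force \code{"heavy-atom"} or \code{"residue-center"}
#'   instead of auto-selection.
#' @return a [ContactSet-class].
#' @export
contactMap <- function(structure, chainA = "A", chainB = "B", cutoff = NULL,
                       metric = NULL) {
  a <- selectAtoms(structure, chainA)@atoms
  b <- selectAtoms(structure, chainB)@atoms
  a <- a[!grepl("^[0-9]*H", a$elety), , drop = FALSE]
  b <- b[!grepl("^[0-9]*H", b$elety), , drop = FALSE]
  if (is.null(metric)) {
    hasSide <- function(at) any(!at$elety %in% .BACKBONE)
    metric <- if (hasSide(a) && hasSide(b)) "heavy-atom" else "residue-center"
    message("contactMap: using ", metric, " distances")
  }
  if (is.null(cutoff)) cutoff <- if (metric == "heavy-atom") 4.5 else 7.0
  if (metric == "residue-center") {
    center <- function(at) {
      sp <- split(at, at$resno)
      do.call(rbind, lapply(sp, function(d)
        data.frame(resno = d$resno[1], resid = d$resid[1],
                   x = mean(d$x), y = mean(d$y), z = mean(d$z))))
    }
    a <- center(a); b <- center(b)
  }
  xa <- as.matrix(a[, c("x", "y", "z")])
  xb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  pairKey <- expand.grid(ia = seq_len(nrow(a)), ib = seq_len(nrow(b)))
  df <- data.frame(resnoA = a$resno[pairKey$ia], residA = a$resid[pairKey$ia],
                   resnoB = b$resno[pairKey$ib], residB = b$resid[pairKey$ib],
                   distance = sqrt(as.vector(d2)))
  agg <- stats::aggregate(distance ~ resnoA + residA + resnoB + residB,
                          data = df, FUN = min)
  agg <- agg[agg$distance <= cutoff, , drop = FALSE]
  agg <- agg[order(agg$resnoA, agg$resnoB), , drop = FALSE]
  rownames(agg) <- NULL
  new("ContactSet",
      contacts = agg[, c("resnoA", "residA", "resnoB", "residB", "distance")],
      chainA = chainA, chainB = chainB, cutoff = cutoff, metric = metric)
}

#' Interface residue sets of a contact map
#'
#' @param contactSet a [ContactSet-class].
#' @return list with sorted residue-number vectors \code{chainA} and
#'   \code{chainB}.
#' @export
interfaceResidues <- function(contactSet) {
  stopifnot(is(contactSet, "ContactSet"))
  list(chainA = sort(unique(contactSet@contacts$resnoA)),
       chainB = sort(unique(contactSet@contacts$resnoB)))
}

#' Orientation of a residue relative to the partner helix
#'
#' The side-chain direction is C-alpha to C-beta, or, for glycine (which
#' has no C-beta), the outward radial vector from the residue's own helix
#' axis through its C-alpha.  Both this direction and the vector from the
#' C-alpha to the partner axis are projected onto the plane normal to the
#' own-helix axis; the azimuth between the projections (0-180 degrees)
#' classifies the residue as facing \code{toward} the partner (< 60),
#' \code{away} (> 120) or \code{lateral}.
#'
#' @param structure a [HelixStructure-class].
#' @param chain,resno the residue.
#' @param partnerAxis [HelixAxis-class] of the partner helix.
#' @param ownAxis optional [HelixAxis-class] of the residue's own helix
#'   (fitted from the chain's C-alphas when NULL).
#' @param towardMax,awayMin classification thresholds, degrees.
#' @return list with \code{residue}, \code{azimuthToPartner} (degrees) and
#'   \code{facing}.
#' @export
residueOrientation <- function(structure, chain, resno, partnerAxis,
                               ownAxis = NULL, towardMax = 60, awayMin = 120) {
  at <- structure@atoms
  res <- at[at$chain == chain & at$resno == resno, , drop = FALSE]
  if (!nrow(res)) stop(sprintf("residue %s:%d not found", chain, resno))
  ca <- res[res$elety == "CA", c("x", "y", "z")]
  if (!nrow(ca)) stop(sprintf("residue %s:%d has no CA atom", chain, resno))
  ca <- as.numeric(ca[1, ])
  if (is.null(ownAxis))
    ownAxis <- fitHelixAxis(.helixCalpha(structure, chain, NULL))
  e3 <- axisDirection(ownAxis)
  cb <- res[res$elety == "CB", c("x", "y", "z")]
  dir <- if (nrow(cb)) as.numeric(cb[1, ]) - ca
         else {
           onAxis <- axisAnchor(ownAxis) +
             sum((ca - axisAnchor(ownAxis)) * e3) * e3
           ca - onAxis
         }
  # foot of the perpendicular from CA to the partner axis (infinite line)
  pa <- axisAnchor(partnerAxis); pd <- axisDirection(partnerAxis)
  foot <- pa + sum((ca - pa) * pd) * pd
  toPartner <- foot - ca
  proj <- function(v) v - sum(v * e3) * e3
  d1 <- proj(dir); d2 <- proj(toPartner)
  if (.norm3(d1) < 1e-9 || .norm3(d2) < 1e-9)
    stop("degenerate orientation geometry for residue ", resno)
  az <- .deg(acos(min(max(sum(.unit(d1) * .unit(d2)), -1), 1)))
  facing <- if (az < towardMax) "toward" else if (az > awayMin) "away"
            else "lateral"
  list(residue = list(chain = chain, resno = resno),
       azimuthToPartner = az, facing = facing)
}

#' Jaccard overlap of two interface residue sets
#'
#' @param setA,setB vectors of residue numbers.
#' @return |intersection| / |union| in [0, 1]; 1 when both sets are empty.
#' @export
interfaceOverlap <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  if (!length(setA) && !length(setB)) return(1)
  length(intersect(setA, setB)) / length(union(setA, setB))
}
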