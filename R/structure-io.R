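# Structure / ensemble I/O.  PDB parsing and writing are delegated to
# bio3d; this layer adds the package's containers, author-numbering
# guarantees, altloc/hydrogen policy and multi-model expansion.

.pdbToAtoms <- function(pdb, xyzRow, keepHydrogens = FALSE) {
  at <- pdb$atom
  keep <- rep(TRUE, nrow(at))
  # first altloc only
  if (!is.null(at$alt)) {
    alt <- at$alt
    alt[is.na(alt)] <- ""
    firstAlt <- tapply(alt[alt != ""], paste(at$chain, at$resno, at$elety)[alt != ""],
                       function(v) v[1])
    keep <- alt == "" | alt == firstAlt[paste(at$chain, at$resno, at$elety)]
  }
  if (!keepHydrogens)
    keep <- keep & !grepl("^[0-9]*H", trimws(at$elety))
  idx <- which(keep)
  xyz <- matrix(xyzRow, ncol = 3L, byrow = TRUE)[idx, , drop = FALSE]
  ch <- at$chain[idx]
  ch[is.na(ch) | ch == ""] <- "A"
  data.frame(chain = as.character(ch),
             resno = as.integer(at$resno[idx]),
             resid = as.character(at$resid[idx]),
             elety = trimws(as.character(at$elety[idx])),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Read one model of a (multi-model) PDB file
#'
#' Atom records preserve author residue numbering.  By default the first
#' alternate location of each atom is kept and hydrogens are dropped
#' (analyses here are heavy-atom only).
#'
#' @param path path to a PDB file (MODEL/ENDMDL-delimited multi-model
#'   allowed).
#' @param modelIndex which model to return (1-based; default the first).
#' @param keepHydrogens keep hydrogen atoms?
#' @return a [HelixStructure-class].
#' @examples
#' h <- buildIdealHelix(helixSpec(chain = "A"))
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(h, f)
#' readStructure(f)
#' @export
readStructure <- function(path, modelIndex = 1L, keepHydrogens = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nModels <- nrow(pdb$xyz)
  if (modelIndex < 1L || modelIndex > nModels)
    stop(sprintf("modelIndex %d out of range: %s has %d model(s)",
                 modelIndex, path, nModels))
  new("HelixStructure",
      atoms = .pdbToAtoms(pdb, pdb$xyz[modelIndex, ], keepHydrogens),
      label = sprintf("%s;model=%d", basename(path), modelIndex))
}

#' Read an ensemble from one or more PDB files
#'
#' Multi-model files expand to one ensemble member per model; member count
#' is additive over files.  Provenance records source path and model index.
#'
#' @param paths character vector of PDB paths.
#' @param requireChains optional chain identifiers that every member must
#'   contain; a missing chain is an error naming the chain (no silent
#'   reindexing).
#' @param keepHydrogens keep hydrogen atoms?
#' @return a [StructureEnsemble-class].
#' @export
readEnsemble <- function(paths, requireChains = NULL, keepHydrogens = FALSE) {
  members <- list()
  prov <- character(0)
  for (p in paths) {
    if (!file.exists(p)) stop("file not found: ", p)
    pdb <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
    for (m in seq_len(nrow(pdb$xyz))) {
      s <- new("HelixStructure", atoms = .pdbToAtoms(pdb, pdb$xyz[m, ], keepHydrogens),
               label = sprintf("%s;model=%d", basename(p), m))
      if (!is.null(requireChains)) {
        missing <- setdiff(requireChains, unique(s@atoms$chain))
        if (length(missing))
          stop(sprintf("chain %s absent in %s model %d",
                       paste(missing, collapse = ","), p, m))
      }
      members[[length(members) + 1L]] <- s
      prov <- c(prov, sprintf("source=%s;model=%d", p, m))
    }
  }
  chainSets <- lapply(members, function(s) sort(unique(s@atoms$chain)))
  if (length(unique(vapply(chainSets, paste, character(1), collapse = ","))) > 1L)
    stop("inconsistent chain naming across ensemble members")
  new("StructureEnsemble", members = members, provenance = prov)
}

#' Write structures to a (multi-model) PDB file
#'
#' @param x a [HelixStructure-class], [HelixTrajectory-class] (one MODEL per
#'   frame) or [StructureEnsemble-class] of structures sharing one topology.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(x, path) {
  if (is(x, "HelixStructure")) {
    at <- x@atoms
    xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  } else if (is(x, "HelixTrajectory")) {
    at <- x@topology@atoms
    xyz <- x@xyz
  } else if (is(x, "StructureEnsemble")) {
    at <- x@members[[1]]@atoms
    key0 <- paste(at$chain, at$resno, at$elety)
    xyz <- t(vapply(x@members, function(m) {
      if (!identical(paste(m@atoms$chain, m@atoms$resno, m@atoms$elety), key0))
        stop("ensemble members do not share one topology; write individually")
      as.vector(t(as.matrix(m@atoms[, c("x", "y", "z")])))
    }, numeric(3L * nrow(at))))
  } else stop("unsupported object for writeStructure")
  pdb <- .atomsToPdb(at)
  bio3d::write.pdb(pdb, xyz = xyz, file = path)
  invisible(path)
}

.atomsToPdb <- function(at) {
  n <- nrow(at)
  atom <- data.frame(type = rep("ATOM", n), eleno = seq_len(n),
                     elety = at$elety, alt = NA, resid = at$resid,
                     chain = at$chain, resno = at$resno, insert = NA,
                     x = at$x, y = at$y, z = at$z, o = 1, b = 0,
                     segid = NA, elesy = substr(at$elety, 1, 1), charge = NA,
                     stringsAsFactors = FALSE)
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  pdb <- list(atom = atom, xyz = bio3d::as.xyz(matrix(xyz, nrow = 1)),
              calpha = at$elety == "CA")
  class(pdb) <- c("pdb")
  pdb
}

#' Select a helix sub-system
#'
#' Returns exactly the atoms matching all filters, original order
#' preserved.  An empty selection is an error (an empty helix would break
#' axis fitting downstream).
#'
#' @param structure a [HelixStructure-class].
#' @param chain chain identifier (required).
#' @param residueRange inclusive \code{c(first, last)} pair of author
#'   residue numbers, or NULL for the whole chain.
#' @param atomNames optional atom-name subset (e.g. \code{"CA"}).
#' @return a [HelixStructure-class] with the selected atoms.
#' @export
selectAtoms <- function(structure, chain, residueRange = NULL, atomNames = NULL) {
  stopifnot(is(structure, "HelixStructure"))
  at <- structure@atoms
  if (!chain %in% at$chain)
    stop("chain not present in structure: ", chain)
  keep <- at$chain == chain
  if (!is.null(residueRange)) {
    stopifnot(length(residueRange) == 2L)
    keep <- keep & at$resno >= residueRange[1] & at$resno <= residueRange[2]
  }
  if (!is.null(atomNames)) keep <- keep & at$elety %in% atomNames
  if (!any(keep)) stop("empty selection for chain ", chain)
  new("HelixStructure", atoms = at[keep, , drop = FALSE], label = structure@label)
}

# Indices of the selected atoms in the topology's atom order (shared by
# trajectory operations, which index columns of the xyz matrix).
.selectionIndices <- function(structure, chain, residueRange = NULL,
                              atomNames = NULL) {
  at <- structure@atoms
  if (!chain %in% at$chain) stop("chain not present: ", chain)
  keep <- at$chain == chain
  if (!is.null(residueRange))
    keep <- keep & at$resno >= residueRange[1] & at$resno <= residueRange[2]
  if (!is.null(atomNames)) keep <- keep & at$elety %in% atomNames
  if (!any(keep)) stop("empty selection for chain ", chain)
  which(keep)
}

#' Describe the two helices of a dimer system
#'
#' A small configuration object naming which chain (and author-numbering
#' residue range) is the mobile helix (alphaIIb-like) and which the
#' reference helix (beta3-like), and which atom names count as "backbone"
#' for fitting and density accumulation.  TM residue ranges are user input:
#' they are never hard-coded by analyses.
#'
#' @param mobileChain,referenceChain chain identifiers.
#' @param mobileRange,referenceRange inclusive residue-number pairs or NULL
#'   (whole chain).
#' @param backboneAtoms atom names treated as backbone (default
#'   \code{"CA"}, matching a one-particle-per-residue backbone trace).
#' @return a list of class \code{helixSelectors}.
#' @export
helixSelectors <- function(mobileChain = "A", referenceChain = "B",
                           mobileRange = NULL, referenceRange = NULL,
                           backboneAtoms = "CA") {
  structure(list(mobileChain = mobileChain, referenceChain = referenceChain,
                 mobileRange = mobileRange, referenceRange = referenceRange,
                 backboneAtoms = backboneAtoms),
            class = "helixSelectors")
}

.helixCalpha <- function(structure, chain, range) {
  sel <- selectAtoms(structure, chain, range, "CA")
  coords(sel)
}
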