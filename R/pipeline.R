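# End-to-end orchestration: validated configuration, full ensemble
# analysis, structure comparison, and report/artefact writing.

#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent nested list) naming
#' the inputs (PDB paths, or a synthetic-generator block), the chain ids
#' and TM residue ranges of the mobile (alphaIIb-like) and reference
#' (beta3-like) helices, the backbone atom subset, and analysis
#' parameters.  Validation happens before any I/O or computation.
#'
#' @param config path to a YAML file, or a list.
#' @return the validated configuration list (with defaults filled in), of
#'   class \code{pipelineConfig}.
#' @export
readPipelineConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  need <- function(x, what) if (is.null(x)) stop("config missing: ", what) else x
  hel <- need(config$helices, "helices")
  for (role in c("mobile", "reference")) {
    h <- need(hel[[role]], paste0("helices$", role))
    need(h$chain, paste0("helices$", role, "$chain"))
  }
  if (is.null(config$input) ||
      (is.null(config$input$paths) && is.null(config$input$simulate)))
    stop("config missing: input$paths or input$simulate")
  defaults <- list(binWidth = 5, cellSize = 1.0, signTolerance = 2,
                   contactCutoff = NULL, stableThreshold = 3.0,
                   driftThreshold = 0.05, convergenceFraction = 0.5,
                   convergenceDraws = 20, mergeDistance = 3, minorMass = 0.05)
  ana <- utils::modifyList(defaults, if (is.null(config$analysis)) list()
                           else config$analysis)
  config$analysis <- ana
  if (is.null(config$seed)) config$seed <- 1L
  class(config) <- c("pipelineConfig", "list")
  config
}

.configSelectors <- function(config) {
  h <- config$helices
  rng <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))
  helixSelectors(mobileChain = h$mobile$chain,
                 referenceChain = h$reference$chain,
                 mobileRange = rng(h$mobile$range),
                 referenceRange = rng(h$reference$range),
                 backboneAtoms = if (is.null(h$backbone)) "CA"
                                 else unlist(h$backbone))
}

.configEnsemble <- function(config) {
  if (!is.null(config$input$paths))
    return(readEnsemble(unlist(config$input$paths),
                        requireChains = c(config$helices$mobile$chain,
                                          config$helices$reference$chain)))
  sim <- config$input$simulate
  n <- if (is.null(sim$nMembers)) 200L else as.integer(sim$nMembers)
  generateModeEnsemble(nMembers = n, seed = .subSeed(config$seed, 1L))
}

#' Run the full dimer-ensemble analysis pipeline
#'
#' Ingests (or simulates) the ensemble, computes the crossing-angle
#' distribution, the spatial density map with packing modes, a
#' representative structure and interface analysis for each mode, the
#' half-ensemble convergence check, and stability reports for trajectory
#' members.  Deterministic given the configuration and its seed.  When
#' \code{outputDir} is given, all artefacts (resolved config, angle table,
#' density grid, report) are written there.
#'
#' @param config a configuration accepted by [readPipelineConfig()].
#' @param outputDir optional run directory.
#' @return list of class \code{runReport}: \code{angles}
#'   ([AngleDistribution-class]), \code{density} ([DensityMap-class]),
#'   \code{modes} (per-mode representative index, crossing angle and
#'   interface sets), \code{convergence}, \code{stability} (per trajectory
#'   member), \code{config}.
#' @export
runPipeline <- function(config, outputDir = NULL) {
  config <- readPipelineConfig(config)
  sel <- .configSelectors(config)
  ana <- config$analysis
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  ens <- stage("ingest", .configEnsemble(config))
  ad <- stage("angles", angleDistribution(ens, sel, binWidth = ana$binWidth,
                                          signTolerance = ana$signTolerance))
  dm <- stage("density", spatialDensityMap(ens, sel, cellSize = ana$cellSize,
                                           mergeDistance = ana$mergeDistance,
                                           minorMass = ana$minorMass))
  modes <- stage("modes", lapply(seq_len(nrow(densityMaxima(dm))), function(i) {
    lab <- densityMaxima(dm)$label[i]
    rep <- representativeStructure(ens, dm, lab, sel)
    cg <- structureCrossing(rep$structure, sel, ana$signTolerance)
    cm <- suppressMessages(contactMap(rep$structure, sel$mobileChain,
                                      sel$referenceChain,
                                      cutoff = ana$contactCutoff))
    list(label = lab, representativeIndex = rep$index,
         omega = omega(cg), handedness = handedness(cg),
         basinMass = densityMaxima(dm)$mass[i],
         interface = interfaceResidues(cm))
  }))
  conv <- stage("convergence",
                if (nMembers(ens) >= 4L)
                  convergenceCheck(ens, sel, fraction = ana$convergenceFraction,
                                   nDraws = ana$convergenceDraws,
                                   seed = .subSeed(config$seed, 2L),
                                   binWidth = ana$binWidth)
                else NULL)
  isTraj <- vapply(members(ens), is, logical(1), "HelixTrajectory")
  stab <- stage("stability", lapply(which(isTraj), function(i) {
    tr <- members(ens)[[i]]
    rs <- rmsdSeries(tr, frameStructure(tr, 1L), atomNames = sel$backboneAtoms)
    angs <- .memberOmegas(tr, sel, ana$signTolerance)$omega
    assessStability(rs, angs, stableThreshold = ana$stableThreshold,
                    driftThreshold = ana$driftThreshold,
                    signTolerance = ana$signTolerance)
  }))
  report <- structure(list(angles = ad, density = dm, modes = modes,
                           convergence = conv, stability = stab,
                           config = config),
                      class = "runReport")
  if (!is.null(outputDir)) .writeRunReport(report, outputDir)
  report
}

#' @export
print.runReport <- function(x, ...) {
  cat("Helix-dimer ensemble run report\n")
  show(x$angles)
  show(x$density)
  for (m in x$modes)
    cat(sprintf("  mode %s: representative member %d, omega %+.1f deg (%s)\n",
                m$label, m$representativeIndex, m$omega, m$handedness))
  if (!is.null(x$convergence))
    cat(sprintf("  convergence: JSD %.4f bits at fraction %.2f (%s)\n",
                x$convergence$divergence, x$convergence$fractionUsed,
                if (x$convergence$converged) "converged" else "not converged"))
  invisible(x)
}

.writeRunReport <- function(report, outputDir) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  class(cfg) <- "list"
  yaml::write_yaml(cfg, file.path(outputDir, "config_resolved.yaml"))
  utils::write.table(report$angles@samples,
                     file.path(outputDir, "angles.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeDensityMap(report$density, file.path(outputDir, "density.txt"))
  summ <- list(
    fractionRH = report$angles@fractionRH,
    fractionLH = report$angles@fractionLH,
    modeMeans = as.list(report$angles@modeMeans),
    maxima = lapply(seq_len(nrow(densityMaxima(report$density))), function(i)
      as.list(densityMaxima(report$density)[i, ])),
    modes = lapply(report$modes, function(m)
      list(label = m$label, representativeIndex = m$representativeIndex,
           omega = m$omega, handedness = m$handedness,
           basinMass = m$basinMass,
           interfaceMobile = m$interface$chainA,
           interfaceReference = m$interface$chainB)),
    convergence = if (is.null(report$convergence)) NULL else
      report$convergence[c("divergence", "fractionUsed", "converged")],
    stability = lapply(report$stability, function(s)
      list(plateau = s@plateauValue, drift = s@driftRate,
           classification = s@classification)))
  yaml::write_yaml(summ, file.path(outputDir, "report.yaml"))
  invisible(outputDir)
}

#' Write a density map as a plain-text grid
#'
#' A commented header records the grid origin and cell size and the
#' detected maxima; the body is the probability matrix (rows = x cells).
#'
#' @param map a [DensityMap-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDensityMap <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# origin %.4f %.4f", map@origin[1], map@origin[2]), con)
  writeLines(sprintf("# cell_size %.4f", map@cellSize), con)
  mx <- densityMaxima(map)
  for (i in seq_len(nrow(mx)))
    writeLines(sprintf("# maximum %s x=%.3f y=%.3f mass=%.4f", mx$label[i],
                       mx$x[i], mx$y[i], mx$mass[i]), con)
  utils::write.table(map@values, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Compare two dimer structures
#'
#' Mirrors a simulation-vs-NMR comparison: C-alpha RMSD after optimal
#' superposition of the TM selections (both chains), both signed crossing
#' angles, and the Jaccard overlap of the two helix/helix interfaces.
#'
#' @param a,b [HelixStructure-class] objects with resolvable TM selections.
#' @param selectors a [helixSelectors()].
#' @param signTolerance degrees.
#' @param contactCutoff optional cutoff for [contactMap()].
#' @return list with \code{rmsd} (A), \code{omegaA}, \code{omegaB}
#'   (degrees), \code{interfaceJaccard} (combined over both chains) and
#'   the per-chain overlaps.
#' @export
compareStructures <- function(a, b, selectors = helixSelectors(),
                              signTolerance = 2, contactCutoff = NULL) {
  selCa <- function(s) {
    rbind(.helixCalpha(s, selectors$mobileChain, selectors$mobileRange),
          .helixCalpha(s, selectors$referenceChain, selectors$referenceRange))
  }
  xa <- selCa(a); xb <- selCa(b)
  if (nrow(xa) != nrow(xb))
    stop("TM selections of the two structures have different sizes")
  sup <- kabschSuperpose(xb, xa)
  cgA <- structureCrossing(a, selectors, signTolerance)
  cgB <- structureCrossing(b, selectors, signTolerance)
  iface <- function(s) interfaceResidues(
    suppressMessages(contactMap(s, selectors$mobileChain,
                                selectors$referenceChain,
                                cutoff = contactCutoff)))
  ia <- iface(a); ib <- iface(b)
  tag <- function(f) c(paste0("A", f$chainA), paste0("B", f$chainB))
  list(rmsd = sup$rmsd, omegaA = omega(cgA), omegaB = omega(cgB),
       interfaceJaccard = interfaceOverlap(tag(ia), tag(ib)),
       jaccardMobile = interfaceOverlap(ia$chainA, ib$chainA),
       jaccardReference = interfaceOverlap(ia$chainB, ib$chainB))
}

#' Plot a crossing-angle distribution
#'
#' @param x an [AngleDistribution-class].
#' @param y ignored.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot.AngleDistribution <- function(x, y, ...) {
  mids <- (utils::head(x@breaks, -1) + utils::tail(x@breaks, -1)) / 2
  graphics::barplot(x@histogram, names.arg = mids, space = 0,
                    xlab = "crossing angle (deg)", ylab = "weight", ...)
}

#' Plot a spatial density map
#'
#' @param x a [DensityMap-class].
#' @param y ignored.
#' @param ... passed to [graphics::image()].
#' @return invisibly NULL.
#' @export
plot.DensityMap <- function(x, y, ...) {
  cc <- cellCenters(x)
  graphics::image(cc$x, cc$y, x@values, xlab = "x (A)", ylab = "y (A)",
                  asp = 1, col = grDevices::hcl.colors(64, "viridis"), ...)
  mx <- densityMaxima(x)
  if (nrow(mx)) {
    graphics::points(mx$x, mx$y, pch = 3, col = "red")
    graphics::text(mx$x, mx$y, mx$label, pos = 3, col = "red")
  }
  invisible(NULL)
}
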