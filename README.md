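# helixpack

Crossing-angle and packing-mode analysis of transmembrane (TM) helix dimer
ensembles, in R.

## What it is for

Single-span TM helices dimerise with a characteristic geometry.  For the
integrin alphaIIb/beta3 pair — the motivating system — the inactive state is
held by right-handed packing in which the GxxxG glycines of alphaIIb (G972,
G976) press against M701 and I704 of beta3, with beta3 G708 meeting alphaIIb
L980.  Whether a simulation campaign or an NMR ensemble supports that
arrangement is judged from a handful of ensemble observables, and this
package is that observable layer for structural bioinformaticians working
on helix-helix packing:

* **Signed crossing angle** Omega of the two fitted helix axes, in
  (-90, +90] degrees.  Negative Omega = right-handed (RH) packing,
  positive = left-handed (LH); the sign is the chirality triple product
  `(d_a x d_b) . u` with `u` the unit vector between the closest-approach
  points of the finite axis segments.
* **Spatial density maps**: the probability density of the mobile helix
  around the reference helix in the bilayer plane, after every
  conformation is superposed into a canonical frame (reference axis on
  +z, azimuth pinned).  Watershed maxima are the packing modes; their
  basin masses are the mode weights.
* **Stability classification** from C-alpha RMSD time series: plateau
  below ~3 Angstrom = stable model, steady rise to 5-7 Angstrom =
  unstable, with a Theil-Sen drift slope and crossing-angle spread.
* **Interface characterisation**: inter-chain residue contacts, residue
  orientation toward/away from the partner helix (glycines handled via
  the radial C-alpha vector), and Jaccard overlap of two interfaces.
* **Synthetic generators** for every input class — ideal helices, dimers
  at prescribed crossing angle and interface azimuth, 70/30 RH/LH
  mode-mixture ensembles, 60-Angstrom diffusion-association trajectories,
  plateau/ramp RMSD archetypes, and 15-degree rotation scans — with the
  construction truth recorded in provenance strings, so every analysis is
  testable as parameter recovery.

Structures round-trip through multi-model PDB (via bio3d) with author
residue numbering preserved.  The central containers are S4 classes
(`HelixStructure`, `HelixTrajectory`, `StructureEnsemble`, `DensityMap`,
`StabilityReport`, ...) with accessors and validity checks.

## Worked example

```r
library(helixpack)

e  <- generateModeEnsemble(nMembers = 300, seed = 42)  # synthetic CG-like ensemble
ad <- angleDistribution(e)
ad
#> AngleDistribution: 300 samples, RH 68.7% (mean -30.1 deg), LH 31.3% (mean +31.2 deg)

dm <- spatialDensityMap(e)
dm
#> DensityMap: 34 x 43 grid, cell 1.00 A, 2 maxima
#>   M1: (10.0, 0.3) A, basin mass 0.69
#>   M2: (-9.9, 0.1) A, basin mass 0.31

rep1 <- representativeStructure(e, dm, "M1")
ir <- interfaceResidues(contactMap(rep1$structure, "A", "B"))
#> contactMap: using residue-center distances
ir$chainA
#> [1] 972 975 976 979 980 983 987 990 994

cv <- convergenceCheck(e, seed = 1)
sprintf("half-ensemble JSD: %.4f bits (converged: %s)", cv$divergence, cv$converged)
#> [1] "half-ensemble JSD: 0.0178 bits (converged: TRUE)"
```

Reading it: 68.7% of members classify right-handed with an RH mode mean of
-30.1 degrees (the generator's construction is a 70% RH mode centred at
-30); the density map resolves the two packing modes at opposite interface
azimuths with basin masses matching the realised mode fractions; the M1
representative presents the 972/976 glycine face at the interface; and a
random half of the ensemble already reproduces the full angle histogram to
0.018 bits, i.e. the ensemble is converged by the 0.05-bit criterion.

The full pipeline (`runPipeline()`) chains ingest, angles, density map,
per-mode representatives and interfaces, convergence and stability, and
writes a run directory with the resolved configuration, angle table,
density grid and summary report.  A thin subcommand CLI over the same
functions ships at `inst/cli/helixpack`
(`helixpack run|angles|density|stability|interface|compare|simulate`).

## Scope notes

Helix axes are single straight segments (no kink models); density maps are
2D occupancy, not free-energy surfaces; stability is a classifier over
RMSD series, not a kinetic model.  TM residue ranges are user input — the
package never hard-codes them.
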