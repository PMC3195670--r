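---
title: "Analysing transmembrane helix-dimer ensembles with helixpack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing transmembrane helix-dimer ensembles with helixpack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(helixpack)
```

## The problem

Single-span transmembrane (TM) helices such as those of the integrin
alphaIIb and beta3 subunits associate into dimers whose packing geometry
carries the biological signal: the inactive integrin is held together by an
outer-membrane-clasp interaction in which the GxxxG glycines of the alphaIIb
helix (G972, G976) pack against bulky beta3 side chains (M701, I704), with
beta3 G708 against alphaIIb L980.  Ensembles of candidate dimers — from
coarse-grained self-assembly simulations, atomistic refinement runs, or
deposited NMR models — are characterised by a small set of observables, and
helixpack implements that observable layer:

* the **signed crossing angle** Omega between the two helix axes, with the
  convention that negative Omega is right-handed (RH) packing and positive
  Omega left-handed (LH);
* the **2D spatial probability density** of one helix around the other in
  the bilayer plane, whose maxima are the packing modes and whose watershed
  basin masses are the mode weights;
* **C-alpha RMSD stability** of individual simulations (plateau vs steady
  drift);
* the **helix/helix interface**: inter-chain residue contacts, whether
  labelled residues face toward or away from the partner, and the overlap
  of two structures' interfaces.

Because real trajectory archives are bulky and rarely deposited, the package
also ships a fully parameterised synthetic generator that reproduces the
*statistical shape* of such data with complete construction bookkeeping, so
every analysis can be tested as parameter recovery.

## Geometry

**Helix axis.**  The axis direction is, primarily, the dominant principal
direction of the centred C-alpha coordinates (deterministic and robust).
Principal directions of helical arcs with a non-integer number of turns are
biased by a few tenths of a degree, so the fit is refined with an estimator
that is exact on helices: for points on any helix the second differences
`p[i-1] + p[i+1] - 2 p[i]` are purely radial, hence the axis is the null
eigenvector of their covariance.  The refinement is accepted only when it
agrees with the principal direction to within 1 degree and the smallest
eigenvalue is well separated, so irregular or very noisy traces fall back to
the principal direction.  On ideal helices the axis is exact; with 0.3 A
isotropic coordinate noise the direction error stays below 2 degrees.  The
direction is sign-fixed N-terminus to C-terminus; the anchor is the C-alpha
centroid; the finite segment spans the projected extent.

**Signed crossing angle.**  |Omega| is the acute angle between the two axis
directions (one direction is flipped first if the pair is antiparallel, so
the result is a property of the line pair).  The sign is the sign of the
chirality triple product `(d_a x d_b) . u`, with `u` the unit vector
between the closest-approach points of the *finite* axis segments (TM
helices are short; infinite-line closest points can fall outside the
membrane span).  The convention is calibrated so a constructed right-handed
GxxxG dimer measures negative and is locked by regression tests; a mirror
image flips the sign exactly.  Angles within a `signTolerance` (default 2
degrees) of zero are classified indeterminate and excluded from RH/LH
fraction denominators.  Omega is reported in (-90, +90].

**Superposition.**  Kabsch superposition is implemented in closed form via
SVD with the determinant correction, so the rotation is always proper; the
test suite cross-checks it against a brute-force rotational minimisation and
against an independent library implementation.

```{r}
d <- buildDimer(omega = -30)
structureCrossing(d)
```

## Spatial density maps and packing modes

Each conformation is mapped into a canonical frame: the reference
(beta3-like) helix axis goes to +z through the origin, and the azimuth is
pinned by requiring the first C-alpha of its TM range to lie in the +x
half-plane — without pinning the azimuth the map would smear.  Mobile-helix
backbone positions are projected onto the bilayer (xy) plane and
accumulated on a grid (1 A cells by default), each ensemble member
contributing equal total mass so long trajectories cannot dominate.  The
grid is sized to enclose every projected point, and the stored density sums
to 1 exactly.

Maxima detection works on a smoothed copy (three 3x3-average passes by
default): steepest-ascent watershed assigns every cell to a local maximum,
then basins are merged by two rules — peak cells closer than 3 A, and
*relative prominence* below 0.4 (a basin whose peak rises above its highest
saddle by less than 40% of the peak is a ridge lump, not a mode).  The
prominence rule matters because a tilted helix projects to an elongated
(~20 A) streak whose discretised ridge would otherwise fragment into
several shallow maxima; genuine packing modes are separated by deep density
gaps and survive merging.  A mode's position is the density-weighted
centroid of the near-peak (>= 50% of peak) region of its basin, which is
stable on ridge-like footprints where the literal arg-max cell wanders;
modes holding less than 5% of the mass are flagged minor.  All four
thresholds are exposed as arguments.

```{r}
e <- generateModeEnsemble(nMembers = 300, seed = 3)
dm <- spatialDensityMap(e)
dm
```

On synthetic ensembles the basin masses reproduce the realised mode
fractions to about 0.01 and the maxima land within one grid cell of the
construction cluster centres.

## Stability classification

The field's empirical markers are formalised rather than invented: a
"stable" membrane-protein model shows a C-alpha RMSD plateau below about
3 A, an "unstable" one rises steadily to 5-7 A over tens of nanoseconds.
`assessStability()` reports the mean RMSD over the final quarter of the
run (the plateau value), a Theil-Sen slope over the final half (robust to
single excursions), and classifies: stable iff plateau < 3 A *and*
|slope| < 0.05 A/ns; unstable iff plateau > 3 A *and* slope > 0.05 A/ns;
anything else indeterminate.  The thresholds are parameters, since the
literature states observations, not a classifier.  Crossing-angle spread
(min, max, population SD of determinate angles) accompanies the
classification, since loosely packed dimers show ranges like -60..0
degrees while tight ones stay narrow.

Dimerization events in assembly trajectories are detected on the closest
approach between the two *fitted axis segments* (an encounter notion at
helix scale, deliberately not an atom-atom minimum distance): first
contact below 8 A, and the event frame is the start of the first run of at
least 10 consecutive bound frames.  Both the 8 A cutoff and the
persistence are documented choices.

## The synthetic generator as study-condition model

The generators encode the study conditions the analyses are meant to face:

* **Ideal helices** use textbook parameters (1.5 A rise, 100 degree twist,
  2.3 A C-alpha radius); non-glycine residues carry a pseudo-C-beta 1.5 A
  radially outward so that side-chain orientation is defined without
  side-chain building.  The default sequences place G972/G976 on the
  mobile (alphaIIb-like, residues 966-995) helix and M701/I704/G708 on the
  reference (beta3-like, residues 686-715) helix, all in author numbering.
* **Mode-mixture ensembles** default to a 70% right-handed mode with mean
  crossing angle -30 degrees (SD 8) and a 30% left-handed mode at +30
  degrees (SD 10) on the opposite interface azimuth — the 70/30 split and
  the -30 degree centre are the published ensemble statistics this
  emulates; the LH centre and both SDs are documented assumptions chosen
  to give a clearly bimodal distribution.  The mean axis separation is
  10 A: with radially protruding pseudo-C-betas on every non-glycine
  residue, 10 A is the smallest separation that is sterically feasible
  over the whole sampled crossing-angle range.  (Real GxxxG dimers pack
  closer; the cartoon trades packing realism for clash-free geometry.)
  Draws that would still clash — possible in the extreme tails of the
  jitters — are redrawn within their mode, which truncates far below 0.1%
  of the distribution.  Every member records its mode label and drawn
  parameters in the ensemble provenance.
* **Assembly trajectories** start with both helices vertical at exactly
  60 A centre separation (the C-alpha centroid of a built helix sits
  exactly on its placement point, so fitted-axis anchors reproduce the
  60 A by construction) and diffuse by a seeded 2D random walk with small
  axis-tilt jitter; a forced encounter can be steered to a prescribed
  frame, with the approach floor kept above the contact cutoff so the
  event frame is exact.
* **Drift trajectories** displace a structure along a fixed random
  per-atom deformation whose Kabsch RMSD is calibrated to the requested
  terminal value — a plateau mode that saturates quickly and a ramp mode
  that grows linearly — with optional per-frame noise.
* **Rotation scans** spin one helix about its own fitted axis in fixed
  increments (15 degrees by default), leaving every other coordinate
  bit-identical.

What the generator does *not* emulate: real sequence-dependent packing
energetics, helix kinks or unwinding, lipid interactions, or correlated
frame-to-frame dynamics.  Passing the recovery tests therefore shows the
*analyses* are correct and well-calibrated, not that any particular
biological system behaves this way.

## Interfaces

Contacts default to minimum heavy-atom distance with a 4.5 A cutoff when
both chains carry side-chain atoms, and fall back to residue-centroid
distances with a 7 A cutoff for backbone-only / coarse-grained-like inputs
(the generator's CA/CB cartoons use the latter; the choice is logged).
Residue orientation projects the side-chain direction (C-alpha to C-beta,
or the outward radial vector for glycine, which has no C-beta) and the
direction to the partner axis onto the plane normal to the own-helix axis;
the angle between them classifies toward (< 60 degrees), away (> 120) or
lateral.  Interface overlap between two structures is the Jaccard index of
their interface residue sets (defined as 1 when both are empty).

## Convergence checking

Whether half the ensemble already tells the same story as the whole is
answered with the mean Jensen-Shannon divergence (in bits, on the 5-degree
angle histogram) between random half-subsamples and the full ensemble,
averaged over 20 seeded draws; below 0.05 bits counts as converged.  The
divergence is exactly zero at fraction 1 and decays as the subsample
fraction grows.

## Numerical and design notes

* All randomness flows through explicit integer seeds; generators restore
  the caller's RNG state.  Sub-seeds for pipeline stages are derived from
  the top-level seed with a fixed affine scheme, keeping every derived
  seed below 2^31.
* Multi-model PDB is the baseline ensemble format (readable and writable
  everywhere, adequate for the structure counts involved); author residue
  numbering is never rewritten, so published residue numbers remain
  addressable.  First altloc kept, hydrogens dropped by default.
* Exactly parallel axes have no defined chirality: Omega is reported as 0
  with indeterminate handedness rather than an arbitrary sign.
* Representative-structure selection breaks ties at the lowest member
  index, making pipeline output order-dependent only in that documented
  respect; everything else is invariant to member permutation.
* Test problem sizes (ensembles of 200-1000 members, trajectories of
  40-300 frames) were chosen as the smallest sizes at which the binomial
  and geometric tolerances asserted by the test suite are comfortably
  meaningful.

## Limitations

The axis model is a single straight segment per helix: kinked or partially
unwound helices are out of scope, as are per-residue helix parameters,
free-energy surfaces over the density maps, kinetic (on/off-rate) models,
and buried-surface-area style interface scores.  The crossing-angle
convention is validated against constructed chirality exemplars; when
applied to experimental structures, the TM residue ranges must be supplied
by the user (they are inputs, never hard-coded).
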