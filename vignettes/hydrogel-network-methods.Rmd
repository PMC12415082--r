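---
title: "Modelling and quantifying the nanoscale network of starPEG-heparin hydrogels"
author: "LatticeGel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and quantifying the nanoscale network of starPEG-heparin hydrogels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LatticeGel)
```

# The system and the model

starPEG-heparin biohybrid hydrogels are formed by a Michael-type addition
between thiol-terminated four-armed poly(ethylene glycol) stars (10 kg/mol)
and maleimide-functionalized heparin (14 kg/mol), a stiff, highly charged
glycosaminoglycan that acts as a multifunctional crosslinker. The
crosslinking degree is set by the molar ratio `gamma = nPEG/nHEP` of the
precursor mixture at a fixed heparin concentration of 1.5 mM. The network
that results is too fine for optical microscopy; its quantitative
characterization rests on coarse-grained simulation, electron-microscopy
image analysis, and scattering - the three pillars this package implements.

## Bond Fluctuation Model

The simulation engine is a Bond Fluctuation Model (BFM): every statistical
monomer occupies a 2x2x2 cube of sites on a periodic cubic lattice, and
bonds are restricted to the classic set of 108 vectors (signed permutations
of (2,0,0), (2,1,0), (2,1,1), (2,2,1), (3,0,0), (3,1,0)). Together with
excluded volume this guarantees chains can neither cross nor break during
single-monomer unit moves, so the topology of the network is exactly
preserved. One Monte Carlo step (MCS) is one attempted move per monomer on
average. One lattice unit maps to 0.3 nm via the PEG segment length
(0.71 nm).

starPEG is a tetra-functional star: a central monomer plus four arms of 29
monomers (117 total), the four termini carrying the reactive thiols. The
central monomer is counted in addition to the arms; the alternative reading
(the centre being one of the 29) changes the monomer count by one and none
of the reported observables measurably.

Heparin is built as a bulky, rod-like object of 90 cubes: 26 axial slices
at spacing 2 with a 2x2 (or 3-monomer) cross-section, fully bonded with
minimum-length vectors. Because every internal bond already sits at the
minimum allowed length and the cross-section blocks lateral moves by
excluded volume, the object is effectively rigid under plain BFM moves - no
angular potential or special rejection rule is needed, which keeps the move
kernel uniform and fast. Its long-axis extent is 52 sites = 15.6 nm,
matching the ~15.5 nm end-to-end distance reported for heparin of this
molar mass (about three Kuhn segments). 28 monomers per heparin are labelled
reactive, following the average number of carboxylic acid groups available
for functionalization; the experimental material carries on average only
six maleimides, and the site count is therefore exposed as a parameter
(`hepReactive`) for sensitivity studies.

The only interaction energy is a short-ranged PEG-PEG contact energy
(squared corner distance 4-6, the nearest non-overlap shells): zero in good
solvent (PBS), attractive -0.30 kT to model the deswelling and starPEG
aggregation seen in ethanol. Moves that raise the energy are accepted with
the Metropolis probability `exp(-dE/kT)`.

## Crosslinking and network analysis

Reactive sites of opposite species that arrive within one allowed bond
vector of each other after an accepted move form a permanent crosslink
("direct collision"); both sites are consumed, and ties between several
partners are broken uniformly at random. The simulation proceeds until the
extent of reaction `p` - crosslinks over all starPEG termini - reaches the
target 0.90.

The crosslinked system is summarized as a molecule-level bipartite
multigraph. Its largest connected component, the biggest molecule cluster
(BMC), is the gel-fraction proxy; everything outside it would be leached on
swelling. The quality metrics are the effective molar ratio `gamma_BMC`,
the heparin functionality `f_HEP,BMC` (crosslink bonds per heparin in the
BMC - "functionality" counts junction connections, so parallel bonds count;
the distinct-partner reading is reported alongside), per-species
incorporation efficiencies, the cycle rank `E - V + 1` of the connected
multigraph with its per-strand normalisation (strand = crosslink edge, each
anchoring one elastically active arm), and the census of primitive defects
(dangling arms, star-heparin multi-edges, unbound molecules). A minimum
functionality f > 2 is needed for percolation against a 4-arm partner,
which is why compositions near `gamma = 0.4` sit at the gelation threshold.

## Deswelling and the virtual TEM bridge

For imaging, the BMC is extracted and re-centred in a box twice its
original edge, then collapsed for a poor-solvent run at -0.30 kT. A gel
cluster formed at high conversion can wind around the periodic box; in that
case no consistent unwrap exists, the cluster is kept in its original box
(flagged `wrapped`), and cluster-level radii of gyration are reported as
NA. The final snapshot is projected into a virtual TEM image: heparin
monomers inside a 70 nm slab (the experimental section thickness) render
dark with occupancy-proportional darkening - mimicking uranyl-acetate
staining, which highlights heparin while PEG and resin stay bright -
followed by Gaussian blur and Poisson shot noise.

## Micrograph quantification

The image chain reimplements the ImageJ-macro analysis: percentile contrast
stretch (1-99 by default), Gaussian filter (sigma 1 px), Otsu threshold.
Heparin lengths come from Zhang-Suen skeletonization with the skeleton
decomposed into branches between endpoints and junctions (adjacent junction
pixels merged into one junction cluster, the ImageJ convention); branch
length is the along-path length with sqrt(2)-weighted diagonals, spurs
shorter than 3 px pruned. Void sizes come from the inverted mask: Euclidean
distance transform, local maxima with a minimum separation (10 px default)
seeding a marker-based segmentation, maximum caliper (Feret) diameter per
region measured on the convex hull of pixel corners, border-touching
regions excluded. Both distributions are summarized by least-squares
Gaussian fits to their histograms; the fit carries a reduced chi-square
diagnostic that flags clearly non-Gaussian samples (e.g. well-separated
mixtures). A between-class-variance diagnostic on the threshold flags
feature-free (pure noise) inputs, whose Otsu split would otherwise be
meaningless.

The exact macro parameters are not published; the defaults above are
recorded in every `QuantResult` and exposed in the configuration.

## Scattering

`intensityProfile` computes the orientation-averaged Debye sum over a
seeded subsample of coordinates (default cap 2000 points, the O(n^2) desk
budget). `rodFormFactor` is the analytic thin-rod form factor
`P(q) = (2/(qL)) Si(qL) - 4 sin^2(qL/2)/(qL)^2`, whose intermediate-q
log-log slope of -1 is the rod signature assigned to heparin scattering at
q > 1 1/nm. Peak positions are found on a 5-point moving average with
parabolic sub-grid refinement and reported with the d-spacing `2*pi/q`. The
thin-rod length estimate is provided as an explicit form-factor fit with
residual diagnostics, since the exact construction behind the published
"3-4 nm" estimate is not specified.

## Physical-characterization formulas

Closed forms with CODATA constants: volume swelling degree `(d/d0)^3`;
rubber-elasticity mesh size `xi = (R T / (N_A G'))^(1/3)` (storage modulus
in Pa, temperature default 298.15 K, result in nm; G' = 1 kPa gives
~16 nm); shear from Young's modulus `G = E/(2(1+nu))` with `nu = 0.5` for
incompressible gels. Both the modulus-to-mesh and mesh-to-modulus
directions are exported and round-trip to 1e-10 relative error.

# Synthetic data: what it emulates and what it does not

Every stage is testable without external data through seeded generators:

- `plantedRodImage` emulates UA-stained heparin rods: dark capsules of
  planted length (default 15.5 +/- 0.5 nm) on a bright background at
  0.5 nm/px, width 4 px, with blur and shot noise, plus a ground-truth
  table of every rod.
- `plantedVoidImage` plants bright elliptical voids in a dark textured
  matrix; the truth records each region's major axis (the max Feret).
- `syntheticScattering` produces analytic power-law, rod and
  peak-over-background curves with log-normal noise and echoes the
  generating parameters.
- `fixtureNetwork` builds miniature crosslinked systems with the real
  assembly and crosslinking machinery under deterministic seed scans, so
  graph metrics can be checked against hand counts (e.g. the `mini_gel`
  preset: 4 stars, 3 heparins, 12 bonds, cycle rank 6).

These generators share the pipeline's forward models, which is their
purpose: they validate the *measurement* chain against a known truth. They
do not emulate everything in real micrographs - curved or bundled heparin,
stain granularity, uneven illumination, focus gradients - so passing
recovery tests demonstrates correctness of the algorithms at the modelled
geometry and noise scale, not robustness to arbitrary experimental imaging
conditions.

# Study conditions and scaled defaults

The reference conditions are a 256^3 box (76.8 nm edge) at 1.5 mM heparin,
1e8 MCS equilibration, crosslinking to p = 0.90, BMC relocation into 512^3
and at least 6.5e7 MCS of deswelling, with >= 20 independent replicates.
Those remain available through the configuration, but the package's working
defaults are scaled so that full chains run on a desk machine: the
composition checks use a 128^3 box with 1e4 MCS equilibration and 5 seeds
(at 1.5 mM this box holds 51 heparins; with gamma = 0.4, 20 stars; reaching
p = 0.9 takes ~4e4 MCS), trend suites use 96^3 with 2e3 MCS equilibration
and 2e4 MCS deswelling, and the smoke pipeline uses 56^3 - the smallest box
that holds the 52-site heparin rod without periodic self-overlap.
Composition metrics at these scales reproduce the reference values well
within the seed-to-seed spread (`gamma_BMC` ~ 0.57 and `f_HEP,BMC` ~ 2.0 at
gamma = 0.4); absolute void sizes, by contrast, are box-limited and are
used only for rank comparisons across gamma.

# Numerical choices and edge cases

- Coordinates are 0-based integers; minimum-image arithmetic is used for
  all bond and contact geometry; boxes must be at least 56 lattice units
  when heparin is present.
- The RNG is xoshiro256++ (seeded via splitmix64) inside the kernel;
  every stochastic entry point takes an explicit integer seed, and R-side
  generators run in a private RNG stream that restores the caller's state.
- Zero-energy moves never consult the Metropolis draw, so athermal
  trajectories are independent of the acceptance RNG stream.
- `gaussianFit` requires >= 20 values, refuses zero-spread samples, and
  reports the sample mean in its error condition when the fit cannot
  proceed.
- Degenerate images: constant inputs are unthresholdable (error);
  fully-foreground masks yield an empty void list with a flag; empty masks
  yield empty branch lists.
- Void probing caps the reported radius at half the box edge and flags
  states (e.g. an empty box) that reach the cap.
- Tie-breaks are deterministic everywhere: BMC selection by size, then
  edges, then smallest molecule id; collision partners uniformly at random
  under the seeded kernel RNG.

# Known limitations

- Heparin rigidity is geometric (dense packing), not parameterized; the
  rod cannot bend, which slightly overstates stiffness relative to three
  Kuhn segments.
- The deswelling interaction applies to all PEG monomers of the collapsed
  system (the BMC is extracted first, so in the default pipeline this is
  indistinguishable from restricting it to BMC members).
- No electrostatics, explicit solvent, or hydrodynamics; the -0.30 kT
  attraction is an effective surrogate for ethanol-induced PEG
  aggregation.
- The virtual TEM is a projection model, not an electron-optics
  simulation: no defocus, contrast transfer function, or stain chemistry.
- Scattering profiles are unsmeared and on arbitrary intensity scale;
  instrument effects are out of scope.
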