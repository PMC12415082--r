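# LatticeGel

Coarse-grained simulation and nanostructure quantification of
starPEG–heparin biohybrid hydrogels.

These cell-instructive materials are formed by Michael-type addition
between four-armed, thiol-terminated poly(ethylene glycol) stars
(starPEG, 10 kg/mol) and maleimide-functionalized heparin (14 kg/mol), a
stiff rod-like glycosaminoglycan acting as a multifunctional crosslinker.
Their biomedical function depends on a nanoscale polymer network that
optical microscopy cannot resolve. LatticeGel implements, as a tested R
package, the computational side of characterizing that network:

- a **Bond Fluctuation Model (BFM)** lattice Monte Carlo engine
  (excluded-volume 2×2×2 monomer cubes, the classic 108-vector bond set,
  Metropolis acceptance for contact energies) with builders for starPEG
  stars (1 + 4×29 monomers) and rod-like heparin (90 cubes, 28 reactive
  sites, 15.6 nm extent at 0.3 nm per lattice unit);
- **collision crosslinking** to a target extent of reaction
  p = crosslinks / (4·nPEG), default 0.90;
- **network-quality metrics** of the biggest molecule cluster (BMC, the
  gel-fraction proxy): effective molar ratio γ_BMC = nPEG,BMC/nHEP,BMC,
  heparin functionality f_HEP,BMC, incorporation efficiencies, cycle rank
  ζ = E − V + 1 per strand, and the census of primitive defects (dangling
  arms, star–heparin multi-edges, unbound molecules);
- **poor-solvent deswelling** (attractive PEG–PEG contacts, −0.30 kT)
  mimicking the ethanol dehydration before electron microscopy, with
  aggregate and largest-empty-sphere void statistics;
- a **virtual TEM projector** (70 nm slabs, heparin rendered dark as under
  uranyl-acetate staining) and a reimplementation of the automated
  micrograph quantification: Otsu binarization, Zhang–Suen
  skeletonization with branch decomposition (heparin lengths), distance
  map + local maxima + maximum-caliper Feret diameters (void sizes), each
  summarized by Gaussian histogram fits;
- **scattering utilities**: orientation-averaged Debye profiles, the
  analytic thin-rod form factor P(q) = (2/(qL))·Si(qL) − 4 sin²(qL/2)/(qL)²
  with its I ∝ q⁻¹ signature, power-law slopes, and peak positions with
  d-spacings d = 2π/q;
- **closed-form physical characterization**: volume swelling degree
  (d/d₀)³, rubber-elasticity mesh size ξ = (R·T/(N_A·G′))^{1/3}, and the
  E ↔ G′ conversion through a Poisson ratio of 0.5;
- **seeded synthetic-data generators** (planted-rod and planted-void
  micrographs with ground truth, analytic scattering curves, miniature
  network fixtures) so the whole chain is testable without external data.

It is aimed at polymer-physics and biomaterials researchers who want to
relate hydrogel composition (the molar ratio γ = nPEG/nHEP at 1.5 mM
heparin) to network connectivity, defect load, and the void/branch
statistics seen in TEM.

## Worked example

Assemble a scaled solution at γ = 0.4 (the gelation-threshold
composition), crosslink to p = 0.9, and inspect the gel cluster:

```r
library(LatticeGel)

sol <- assembleSolution(gamma = 0.4, cHep = 1.5, boxEdge = 128,
                        equilibrationMCS = 1e4, seed = 3)
cl  <- crosslinkUntil(sol, pTarget = 0.9, maxMCS = 3e5, seed = 104)
g   <- moleculeGraph(cl$state)
bmcMetrics(g, initialCounts = list(nPEG = attr(sol, "nPEG"),
                                   nHEP = attr(sol, "nHEP")))
#> BMCMetrics:
#>   gammaBMC = 0.562, fHepBMC = 2.031 (distinct 1.656)
#>   incorporation: PEG 0.900, HEP 0.627
#>   cycle rank = 16 (zeta per strand = 0.246)
#>   defects: 7 dangling PEG arms, 14 multi-edges, 2/19 unbound PEG/HEP
```

At this composition the heparin functionality sits essentially at the
f = 2 percolation threshold for a 4-arm partner: the cluster holds
together, but barely — little more than half the heparin is incorporated,
and a large defect load (dangling arms, parallel star–heparin bonds,
unbound molecules) remains. Raising γ raises f_HEP,BMC and densifies the
network.

Quantify a synthetic stained micrograph with known ground truth:

```r
pr  <- plantedRodImage(nRods = 200, lengthMeanNm = 15.5, seed = 901)
mask <- binarizePreprocess(pr$image)
fit <- gaussianFit(branchLengthAnalysis(mask, pixelSize(pr$image)), bins = 40)
round(c(mean = fit$mean, sd = fit$sd), 2)
#>  mean    sd
#> 15.67  1.82
```

The skeleton pipeline recovers the 15.5 nm planted heparin backbone
length to within a fraction of the blur width. Closed-form physics:

```r
meshSizeFromModulus(1000)        # G' = 1 kPa -> 16.0 nm mesh
peakAndDspacing(syntheticScattering("peak_background",
    list(qPeak = 14.2), qGrid = seq(10, 18, 0.01))$profile,
    qWindow = c(12, 16))$dSpacing   # ~0.44 nm
```

A full chain (assemble → crosslink → BMC → deswell → virtual TEM →
quantification → scattering) over several seeds is one call:
`runPipeline(list(gamma = 1, boxEdge = 64, seeds = 1:5))`, which returns
per-seed results plus ensemble means and standard errors, and writes a
checksummed result bundle when given `outDir`.

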