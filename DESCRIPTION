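Package: LatticeGel
Title: Lattice Monte Carlo Modelling and Nanostructure Quantification of
    starPEG-Heparin Hydrogel Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained Bond Fluctuation Model (BFM) simulation of
    covalently crosslinked starPEG-heparin biohybrid hydrogels, together with
    the analysis chain used to characterize their nanoscale network structure:
    molecule-level network graphs with gel-cluster (biggest molecule cluster)
    quality metrics (effective molar ratio, heparin functionality, cycle rank,
    defect census), poor-solvent deswelling, virtual transmission electron
    microscopy projections, automated micrograph quantification
    (skeleton branch lengths and void Feret diameters with Gaussian-fit
    summaries), small-angle scattering observables (Debye profiles, thin-rod
    form factor, power-law slopes, peak d-spacings), and closed-form
    rubber-elasticity and swelling formulas. Includes seeded synthetic-data
    generators (planted-rod and planted-void micrographs, analytic scattering
    curves, miniature network fixtures) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    igraph,
    EBImage,
    pracma,
    minpack.lm,
    jsonlite,
    yaml,
    png,
    tiff
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
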