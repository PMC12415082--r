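#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib LatticeGel, .registration = TRUE
NULL

#' LatticeState: a full Bond Fluctuation Model microstate
#'
#' Holds one configuration of the coarse-grained lattice model: a periodic
#' cubic box of edge \code{boxEdge} lattice units, one 2x2x2 cube per
#' monomer anchored at integer corner coordinates, the molecular topology
#' (intramolecular bonds plus any crosslinks), and the bookkeeping for
#' reactive sites used by the crosslinking stage.
#'
#' Invariants (checked cheaply by \code{validObject}, exhaustively by
#' \code{\link{auditState}}): monomer cubes never overlap, every bond
#' displacement (minimum image) is one of the 108 allowed vectors, and
#' consumed sites are a subset of reactive sites.
#'
#' @slot boxEdge integer, box edge in lattice units.
#' @slot periodic logical(3), periodicity per axis (all TRUE supported).
#' @slot positions integer matrix n x 3, 0-based corner coordinates in
#'   \code{[0, boxEdge)}.
#' @slot species character vector, \code{"PEG"} or \code{"HEP"} per monomer.
#' @slot moleculeId integer vector, molecule membership per monomer.
#' @slot bonds data.frame with integer columns \code{i}, \code{j} (1-based
#'   monomer indices) and character column \code{kind}
#'   (\code{"intra"} or \code{"crosslink"}).
#' @slot reactive logical vector, reactive-site flag per monomer.
#' @slot consumed logical vector, TRUE once a reactive site has formed its
#'   crosslink.
#'
#' @seealso [assembleSolution()], [crosslinkUntil()], [auditState()]
#' @export
setClass("LatticeState",
  representation(
    boxEdge = "integer",
    periodic = "logical",
    positions = "matrix",
    species = "character",
    moleculeId = "integer",
    bonds = "data.frame",
    reactive = "logical",
    consumed = "logical"
  )
)

setValidity("LatticeState", function(object) {
  n <- nrow(object@positions)
  msg <- character()
  if (length(object@boxEdge) != 1L || object@boxEdge < 8L)
    msg <- c(msg, "boxEdge must be a single integer >= 8")
  if (length(object@periodic) != 3L || !all(object@periodic))
    msg <- c(msg, "only fully periodic boxes are supported")
  if (ncol(object@positions) != 3L || !is.numeric(object@positions))
    msg <- c(msg, "positions must be an n x 3 integer matrix")
  if (n > 0 && (min(object@positions) < 0 ||
                max(object@positions) >= object@boxEdge))
    msg <- c(msg, "positions must lie in [0, boxEdge)")
  if (length(object@species) != n || length(object@moleculeId) != n ||
      length(object@reactive) != n || length(object@consumed) != n)
    msg <- c(msg, "per-monomer slots must all have length n")
  if (n > 0 && !all(object@species %in% c("PEG", "HEP")))
    msg <- c(msg, "species must be 'PEG' or 'HEP'")
  if (!all(c("i", "j", "kind") %in% names(object@bonds)))
    msg <- c(msg, "bonds must have columns i, j, kind")
  if (nrow(object@bonds) > 0) {
    if (min(object@bonds$i, object@bonds$j) < 1 ||
        max(object@bonds$i, object@bonds$j) > n)
      msg <- c(msg, "bond indices out of range")
    if (!all(object@bonds$kind %in% c("intra", "crosslink")))
      msg <- c(msg, "bond kind must be 'intra' or 'crosslink'")
  }
  if (any(object@consumed & !object@reactive))
    msg <- c(msg, "consumed sites must be reactive")
  if (length(msg)) msg else TRUE
})

#' EnergyModel: contact interactions for the Metropolis acceptance rule
#'
#' The only interaction in the model is a short-ranged contact energy
#' \code{epsilonPP} (in units of kT) between pairs of PEG monomers whose
#' minimum-image corner separation has squared length 4, 5 or 6 - the nearest
#' non-overlapping approach shells on the lattice. Heparin monomers carry no
#' interaction. An attractive \code{epsilonPP = -0.30} drives the
#' poor-solvent (ethanol) collapse; \code{epsilonPP = 0} is the athermal
#' good-solvent reference.
#'
#' @slot epsilonPP numeric, PEG-PEG contact energy in kT (<= 0 for
#'   deswelling runs).
#' @slot contactShell integer matrix k x 3 of relative offsets defining a
#'   contact; symmetric under negation.
#' @export
setClass("EnergyModel",
  representation(epsilonPP = "numeric", contactShell = "matrix")
)

setValidity("EnergyModel", function(object) {
  msg <- character()
  if (length(object@epsilonPP) != 1L || !is.finite(object@epsilonPP))
    msg <- c(msg, "epsilonPP must be a single finite number")
  sh <- object@contactShell
  if (ncol(sh) != 3L)
    msg <- c(msg, "contactShell must be a k x 3 matrix")
  key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
  if (nrow(sh) > 0 && !identical(key(sh), key(-sh)))
    msg <- c(msg, "contactShell must be symmetric under negation")
  if (length(msg)) msg else TRUE
})

#' MoleculeTemplate: topology recipe for one molecular species
#'
#' A template holds the relative lattice coordinates, intramolecular bonds
#' and reactive-site placement of one molecule: the tetra-functional starPEG
#' (1 central monomer + 4 arms of 29, reactive termini) or the bulky rod-like
#' heparin (90 monomers, 28 reactive sites).
#'
#' @slot species character, "PEG" or "HEP".
#' @slot positions integer matrix n x 3 of relative corner coordinates.
#' @slot bonds data.frame (i, j) of intramolecular bonds, 1-based.
#' @slot reactiveIndices integer vector of reactive monomer indices.
#' @slot rigidity character, "flexible" or "rod".
#' @slot molarMass numeric, nominal molar mass in g/mol (metadata).
#' @export
setClass("MoleculeTemplate",
  representation(
    species = "character",
    positions = "matrix",
    bonds = "data.frame",
    reactiveIndices = "integer",
    rigidity = "character",
    molarMass = "numeric"
  )
)

setValidity("MoleculeTemplate", function(object) {
  n <- nrow(object@positions)
  msg <- character()
  if (!object@species %in% c("PEG", "HEP"))
    msg <- c(msg, "species must be 'PEG' or 'HEP'")
  if (nrow(object@bonds) > 0 &&
      (min(object@bonds$i, object@bonds$j) < 1 ||
       max(object@bonds$i, object@bonds$j) > n))
    msg <- c(msg, "bond indices out of range")
  if (length(object@reactiveIndices) > 0 &&
      (min(object@reactiveIndices) < 1 || max(object@reactiveIndices) > n))
    msg <- c(msg, "reactive indices out of range")
  if (anyDuplicated(object@reactiveIndices))
    msg <- c(msg, "reactive indices must be distinct")
  if (length(msg)) msg else TRUE
})

#' GrayImage: a grayscale micrograph with physical pixel size
#'
#' @slot pixels numeric matrix of 8-bit intensities in \code{[0, 255]}
#'   (rows = y, columns = x).
#' @slot pixelSize numeric, nm per pixel.
#' @slot provenance character: "virtual_tem", "planted" or "external".
#' @export
setClass("GrayImage",
  representation(pixels = "matrix", pixelSize = "numeric",
                 provenance = "character")
)

setValidity("GrayImage", function(object) {
  msg <- character()
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number (nm/px)")
  px <- object@pixels
  if (length(px) && (min(px) < 0 || max(px) > 255))
    msg <- c(msg, "pixel intensities must lie in [0, 255]")
  if (!object@provenance %in% c("virtual_tem", "planted", "external"))
    msg <- c(msg, "unknown provenance")
  if (length(msg)) msg else TRUE
})

#' ScatteringProfile: I(q) on a strictly increasing q grid
#'
#' @slot q numeric vector, scattering vector in 1/nm, strictly increasing,
#'   all positive.
#' @slot intensity numeric vector, non-negative intensities (a.u.).
#' @slot label character, free-text label.
#' @export
setClass("ScatteringProfile",
  representation(q = "numeric", intensity = "numeric", label = "character")
)

setValidity("ScatteringProfile", function(object) {
  msg <- character()
  if (length(object@q) != length(object@intensity))
    msg <- c(msg, "q and intensity must have equal length")
  if (length(object@q) && (any(object@q <= 0) || is.unsorted(object@q, strictly = TRUE)))
    msg <- c(msg, "q must be positive and strictly increasing")
  if (length(object@intensity) && any(object@intensity < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' QuantResult: micrograph quantification output
#'
#' Branch-length and void-Feret distributions (nm) extracted by the image
#' pipeline, their Gaussian-fit summaries, and a snapshot of the settings
#' that produced them.
#'
#' @slot branchLengths numeric vector, skeleton branch lengths (nm).
#' @slot feretDiameters numeric vector, void maximum Feret diameters (nm).
#' @slot fitBranch numeric(2) c(mean, sd) of the Gaussian fit (nm), NA if
#'   not fitted.
#' @slot fitFeret numeric(2) c(mean, sd) of the Gaussian fit (nm), NA if
#'   not fitted.
#' @slot settings list, the analysis parameters used.
#' @export
setClass("QuantResult",
  representation(
    branchLengths = "numeric",
    feretDiameters = "numeric",
    fitBranch = "numeric",
    fitFeret = "numeric",
    settings = "list"
  )
)

#' BMCMetrics: quality metrics of the biggest molecule cluster
#'
#' @slot gammaBMC numeric, effective molar ratio nPEG/nHEP inside the BMC.
#' @slot fHepBMC numeric, mean crosslink bonds per heparin in the BMC.
#' @slot fHepBMCDistinct numeric, mean distinct PEG partners per heparin in
#'   the BMC (alternative functionality reading).
#' @slot incorporationPEG numeric in \code{[0,1]}.
#' @slot incorporationHEP numeric in \code{[0,1]}.
#' @slot cycleRank integer, E - V + 1 of the connected BMC multigraph.
#' @slot zetaPerStrand numeric, cycle rank per crosslink strand.
#' @slot defects list with counts \code{danglingPegArms}, \code{multiEdges},
#'   \code{unboundPeg}, \code{unboundHep}.
#' @export
setClass("BMCMetrics",
  representation(
    gammaBMC = "numeric",
    fHepBMC = "numeric",
    fHepBMCDistinct = "numeric",
    incorporationPEG = "numeric",
    incorporationHEP = "numeric",
    cycleRank = "integer",
    zetaPerStrand = "numeric",
    defects = "list"
  )
)

setValidity("BMCMetrics", function(object) {
  msg <- character()
  if (object@incorporationPEG < 0 || object@incorporationPEG > 1 ||
      object@incorporationHEP < 0 || object@incorporationHEP > 1)
    msg <- c(msg, "incorporation efficiencies must lie in [0, 1]")
  if (object@cycleRank < 0) msg <- c(msg, "cycle rank must be >= 0")
  if (length(msg)) msg else TRUE
})
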