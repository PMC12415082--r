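#' @rdname LatticeState-accessors
#' @export
setGeneric("boxEdge", function(x) standardGeneric("boxEdge"))
#' @rdname LatticeState-accessors
#' @export
setGeneric("monomerPositions", function(x) standardGeneric("monomerPositions"))
#' @rdname LatticeState-accessors
#' @export
setGeneric("monomerSpecies", function(x) standardGeneric("monomerSpecies"))
#' @rdname LatticeState-accessors
#' @export
setGeneric("moleculeIds", function(x) standardGeneric("moleculeIds"))
#' @rdname LatticeState-accessors
#' @export
setGeneric("bondTable", function(x) standardGeneric("bondTable"))
#' @rdname LatticeState-accessors
#' @export
setGeneric("nMonomers", function(x) standardGeneric("nMonomers"))
#' @rdname GrayImage-accessors
#' @export
setGeneric("imagePixels", function(x) standardGeneric("imagePixels"))
#' @rdname GrayImage-accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname ScatteringProfile-accessors
#' @export
setGeneric("qGrid", function(x) standardGeneric("qGrid"))
#' @rdname ScatteringProfile-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' Accessors for LatticeState
#'
#' @param x a [LatticeState-class] object.
#' @return \code{boxEdge}: integer box edge (lattice units);
#'   \code{monomerPositions}: n x 3 integer matrix of corner coordinates;
#'   \code{monomerSpecies}: character vector ("PEG"/"HEP");
#'   \code{moleculeIds}: integer vector; \code{bondTable}: data.frame
#'   (i, j, kind); \code{nMonomers}: integer count.
#' @name LatticeState-accessors
#' @aliases boxEdge monomerPositions monomerSpecies moleculeIds bondTable
#'   nMonomers
NULL

#' @rdname LatticeState-accessors
#' @export
setMethod("boxEdge", "LatticeState", function(x) x@boxEdge)
#' @rdname LatticeState-accessors
#' @export
setMethod("monomerPositions", "LatticeState", function(x) x@positions)
#' @rdname LatticeState-accessors
#' @export
setMethod("monomerSpecies", "LatticeState", function(x) x@species)
#' @rdname LatticeState-accessors
#' @export
setMethod("moleculeIds", "LatticeState", function(x) x@moleculeId)
#' @rdname LatticeState-accessors
#' @export
setMethod("bondTable", "LatticeState", function(x) x@bonds)
#' @rdname LatticeState-accessors
#' @export
setMethod("nMonomers", "LatticeState", function(x) nrow(x@positions))

#' Accessors for GrayImage
#'
#' @param x a [GrayImage-class] object.
#' @return \code{imagePixels}: numeric intensity matrix; \code{pixelSize}:
#'   nm per pixel.
#' @name GrayImage-accessors
#' @aliases imagePixels pixelSize
NULL

#' @rdname GrayImage-accessors
#' @export
setMethod("imagePixels", "GrayImage", function(x) x@pixels)
#' @rdname GrayImage-accessors
#' @export
setMethod("pixelSize", "GrayImage", function(x) x@pixelSize)

#' Accessors for ScatteringProfile
#'
#' @param x a [ScatteringProfile-class] object.
#' @return \code{qGrid}: numeric q values (1/nm); \code{intensities}:
#'   numeric intensities (a.u.).
#' @name ScatteringProfile-accessors
#' @aliases qGrid intensities
NULL

#' @rdname ScatteringProfile-accessors
#' @export
setMethod("qGrid", "ScatteringProfile", function(x) x@q)
#' @rdname ScatteringProfile-accessors
#' @export
setMethod("intensities", "ScatteringProfile", function(x) x@intensity)

setMethod("show", "LatticeState", function(object) {
  n <- nrow(object@positions)
  cat("LatticeState:", n, "monomers in a", object@boxEdge, "^3 periodic box\n")
  if (n > 0) {
    tab <- table(object@species)
    cat("  species:", paste(names(tab), tab, collapse = ", "), "\n")
    cat("  molecules:", length(unique(object@moleculeId)), "\n")
  }
  bk <- table(object@bonds$kind)
  cat("  bonds:", nrow(object@bonds),
      sprintf("(%s)", paste(names(bk), bk, collapse = ", ")), "\n")
  cat("  reactive:", sum(object@reactive),
      " consumed:", sum(object@consumed), "\n")
  frac <- 8 * n / as.numeric(object@boxEdge)^3
  cat(sprintf("  occupied volume fraction: %.3f\n", frac))
})

setMethod("show", "MoleculeTemplate", function(object) {
  cat("MoleculeTemplate:", object@species, "-", nrow(object@positions),
      "monomers,", nrow(object@bonds), "bonds,",
      length(object@reactiveIndices), "reactive sites,",
      object@rigidity, "\n")
})

setMethod("show", "GrayImage", function(object) {
  cat("GrayImage:", nrow(object@pixels), "x", ncol(object@pixels),
      "px at", object@pixelSize, "nm/px (", object@provenance, ")\n")
})

setMethod("show", "ScatteringProfile", function(object) {
  cat("ScatteringProfile '", object@label, "': ", length(object@q),
      " points, q in [", signif(min(object@q), 4), ", ",
      signif(max(object@q), 4), "] nm^-1\n", sep = "")
})

setMethod("show", "BMCMetrics", function(object) {
  cat("BMCMetrics:\n")
  cat(sprintf("  gammaBMC = %.3f, fHepBMC = %.3f (distinct %.3f)\n",
              object@gammaBMC, object@fHepBMC, object@fHepBMCDistinct))
  cat(sprintf("  incorporation: PEG %.3f, HEP %.3f\n",
              object@incorporationPEG, object@incorporationHEP))
  cat(sprintf("  cycle rank = %d (zeta per strand = %.3f)\n",
              object@cycleRank, object@zetaPerStrand))
  d <- object@defects
  cat(sprintf("  defects: %d dangling PEG arms, %d multi-edges, %d/%d unbound PEG/HEP\n",
              d$danglingPegArms, d$multiEdges, d$unboundPeg, d$unboundHep))
})

setMethod("show", "QuantResult", function(object) {
  cat("QuantResult:", length(object@branchLengths), "branches,",
      length(object@feretDiameters), "voids\n")
  if (!anyNA(object@fitBranch))
    cat(sprintf("  branch fit: mean %.2f nm, sd %.2f nm\n",
                object@fitBranch[1], object@fitBranch[2]))
  if (!anyNA(object@fitFeret))
    cat(sprintf("  Feret fit:  mean %.2f nm, sd %.2f nm\n",
                object@fitFeret[1], object@fitFeret[2]))
})
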