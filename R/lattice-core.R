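#' The allowed Bond Fluctuation Model bond-vector set
#'
#' All signed permutations of (2,0,0), (2,1,0), (2,1,1), (2,2,1), (3,0,0)
#' and (3,1,0): the classic 3D set of 108 vectors which, combined with
#' excluded volume, guarantees that chains can neither cross nor cut through
#' each other during single-monomer moves.
#'
#' @return integer matrix 108 x 3, closed under negation.
#' @examples
#' v <- allowedBondSet()
#' nrow(v)  # 108
#' @export
allowedBondSet <- function() {
  classes <- c("0,0,2", "0,1,2", "1,1,2", "1,2,2", "0,0,3", "0,1,3")
  g <- as.matrix(expand.grid(x = -3:3, y = -3:3, z = -3:3))
  keys <- apply(g, 1, function(v) paste(sort(abs(v)), collapse = ","))
  out <- g[keys %in% classes, , drop = FALSE]
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

#' Test displacement vectors for bond-set membership
#'
#' @param v integer vector of length 3 or matrix m x 3 of displacement
#'   vectors (already minimum-imaged).
#' @return logical vector.
#' @export
isAllowedBond <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  key(v) %in% key(allowedBondSet())
}

#' Contact-shell offsets of the PEG-PEG interaction
#'
#' All integer offsets with squared length 4, 5 or 6: the nearest approach
#' shells two non-overlapping monomer cubes can occupy.
#'
#' @return integer matrix 54 x 3, symmetric under negation.
#' @export
contactShellOffsets <- function() {
  g <- as.matrix(expand.grid(x = -2:2, y = -2:2, z = -2:2))
  d2 <- rowSums(g^2)
  out <- g[d2 >= 4 & d2 <= 6, , drop = FALSE]
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

#' Construct an EnergyModel
#'
#' @param epsilonPP PEG-PEG contact energy in units of kT; the default 0 is
#'   the athermal good solvent, -0.30 models the ethanol deswelling drive.
#' @param contactShell optional k x 3 offset matrix; defaults to
#'   [contactShellOffsets()].
#' @return an [EnergyModel-class] object.
#' @export
energyModel <- function(epsilonPP = 0, contactShell = contactShellOffsets()) {
  new("EnergyModel", epsilonPP = epsilonPP, contactShell = contactShell)
}

#' Construct a LatticeState
#'
#' Low-level constructor; most states come from [assembleSolution()] or the
#' fixture generators.
#'
#' @param boxEdge box edge in lattice units (>= 8).
#' @param positions integer n x 3 matrix of 0-based corner coordinates.
#' @param species character vector ("PEG"/"HEP") per monomer.
#' @param moleculeId integer vector per monomer.
#' @param bonds data.frame with columns i, j, kind; defaults to none.
#' @param reactive,consumed logical vectors per monomer.
#' @return a validated [LatticeState-class].
#' @export
latticeState <- function(boxEdge, positions, species,
                         moleculeId = rep(1L, nrow(positions)),
                         bonds = data.frame(i = integer(), j = integer(),
                                            kind = character()),
                         reactive = rep(FALSE, nrow(positions)),
                         consumed = rep(FALSE, nrow(positions))) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "integer"
  positions <- positions %% as.integer(boxEdge)
  new("LatticeState", boxEdge = as.integer(boxEdge),
      periodic = c(TRUE, TRUE, TRUE), positions = positions,
      species = as.character(species), moleculeId = as.integer(moleculeId),
      bonds = data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                         kind = as.character(bonds$kind)),
      reactive = as.logical(reactive), consumed = as.logical(consumed))
}

.bondMatrix0 <- function(state) {
  if (nrow(state@bonds) == 0) return(matrix(integer(), 0, 2))
  cbind(state@bonds$i - 1L, state@bonds$j - 1L)
}

.speciesCode <- function(state) {
  ifelse(state@species == "PEG", 0L, 1L)
}

#' Attempt a single Monte Carlo move
#'
#' Proposes a unit-lattice displacement of one monomer and applies the full
#' BFM acceptance rule: the four newly claimed sites of the 2x2x2 cube must
#' be empty, all incident bonds must remain in the allowed vector set, and a
#' Metropolis draw must succeed when the contact-energy change is positive.
#'
#' @param state a [LatticeState-class].
#' @param monomer 1-based monomer index.
#' @param direction one of \code{"+x","-x","+y","-y","+z","-z"}.
#' @param energy an [EnergyModel-class]; default athermal.
#' @param seed integer seed for the Metropolis draw.
#' @return list with elements \code{accepted} (logical) and \code{state}
#'   (updated on accept, unchanged on reject).
#' @export
attemptMove <- function(state, monomer, direction, energy = energyModel(),
                        seed = 1L) {
  dirs <- c("+x", "-x", "+y", "-y", "+z", "-z")
  if (!direction %in% dirs) stop("invalid direction: ", direction)
  if (length(monomer) != 1L || is.na(monomer) || monomer < 1 ||
      monomer > nMonomers(state))
    stop("invalid monomer index")
  res <- .bfm_attempt_move_cpp(boxEdge(state), state@positions,
                               .speciesCode(state), .bondMatrix0(state),
                               energy@epsilonPP, as.integer(monomer) - 1L,
                               match(direction, dirs) - 1L, as.double(seed))
  if (res$accepted) {
    state@positions <- res$pos
    storage.mode(state@positions) <- "integer"
  }
  list(accepted = res$accepted, state = state)
}

#' Run Monte Carlo sweeps
#'
#' One Monte Carlo step (MCS) is one attempted move per monomer on average:
#' \code{nMCS * nMonomers} proposals of a uniformly random monomer and one
#' of the six unit directions.
#'
#' @param state a [LatticeState-class].
#' @param nMCS number of Monte Carlo steps (>= 0).
#' @param energy an [EnergyModel-class].
#' @param seed integer seed.
#' @return the updated [LatticeState-class] with attributes
#'   \code{acceptanceRatio} and \code{mcsDone}.
#' @export
runMCS <- function(state, nMCS, energy = energyModel(), seed = 1L) {
  stopifnot(nMCS >= 0)
  if (nMCS == 0 || nMonomers(state) == 0) return(state)
  res <- .bfm_run_cpp(boxEdge(state), state@positions, .speciesCode(state),
                      .bondMatrix0(state), state@reactive, state@consumed,
                      as.double(nMCS), energy@epsilonPP, FALSE, 0L,
                      as.double(seed))
  state@positions <- res$pos
  storage.mode(state@positions) <- "integer"
  attr(state, "acceptanceRatio") <- res$accepted / res$attempts
  attr(state, "mcsDone") <- res$mcsDone
  state
}

#' Total contact energy of a state
#'
#' Sums \code{epsilonPP} over all unordered PEG-PEG pairs whose
#' minimum-image corner separation lies in the contact shell; heparin
#' contributes nothing.
#'
#' @inheritParams runMCS
#' @return numeric energy in kT.
#' @export
contactEnergy <- function(state, energy = energyModel(epsilonPP = -0.30)) {
  if (nMonomers(state) == 0) return(0)
  .contact_energy_cpp(boxEdge(state), state@positions, .speciesCode(state),
                      energy@epsilonPP)
}

#' Exhaustive invariant audit of a LatticeState
#'
#' Checks excluded volume (disjoint 2x2x2 blocks) and that every bond's
#' minimum-image displacement is in the allowed set.
#'
#' @param state a [LatticeState-class].
#' @return list with counts \code{overlaps} and \code{badBonds}; both zero
#'   for a valid state.
#' @export
auditState <- function(state) {
  .audit_cpp(boxEdge(state), state@positions, .bondMatrix0(state))
}

#' Unwrap monomer coordinates across periodic boundaries
#'
#' Traverses the bond graph and accumulates minimum-image displacements so
#' that bonded monomers get continuous coordinates. Components whose cycles
#' wind around the periodic box are flagged as inconsistent.
#'
#' @param state a [LatticeState-class].
#' @return list with \code{coords} (numeric n x 3), \code{component}
#'   (1-based component id per monomer) and \code{consistent} (logical per
#'   component).
#' @export
unwrapPositions <- function(state) {
  res <- .unwrap_cpp(boxEdge(state), state@positions, .bondMatrix0(state))
  list(coords = res$coords, component = res$component + 1L,
       consistent = res$consistent)
}
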