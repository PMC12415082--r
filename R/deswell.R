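# poor-solvent collapse of the extracted gel cluster and the observables
# (radius of gyration, PEG aggregates, void statistics) used to mirror the
# dehydrated, resin-embedded state

#' Extract the BMC into its own (larger) simulation box
#'
#' Keeps only the monomers of the molecules in the biggest molecule cluster,
#' unwraps the cluster across the periodic boundaries via its bond graph and
#' re-centres it in a fresh box (default twice the original edge). A gel
#' cluster formed at high conversion can wind around the periodic box, in
#' which case a consistent unwrap does not exist; the cluster is then kept
#' in a box of the original size and flagged (attribute \code{wrapped}).
#'
#' @param state the crosslinked [LatticeState-class].
#' @param bmc the BMC subgraph from [biggestMoleculeCluster()].
#' @param newBoxEdge edge of the deswelling box (default \code{2 *
#'   boxEdge(state)}).
#' @return a [LatticeState-class] containing only the BMC.
#' @export
extractBMCState <- function(state, bmc, newBoxEdge = 2L * boxEdge(state)) {
  keepMols <- as.integer(igraph::V(bmc)$name)
  keep <- which(state@moleculeId %in% keepMols)
  if (length(keep) == 0) stop("BMC contains no monomers")
  idxMap <- integer(nMonomers(state))
  idxMap[keep] <- seq_along(keep)
  b <- state@bonds
  bKeep <- b[b$i %in% keep & b$j %in% keep, , drop = FALSE]
  sub <- latticeState(boxEdge(state), state@positions[keep, , drop = FALSE],
                      state@species[keep], state@moleculeId[keep],
                      data.frame(i = idxMap[bKeep$i], j = idxMap[bKeep$j],
                                 kind = bKeep$kind),
                      state@reactive[keep], state@consumed[keep])
  uw <- unwrapPositions(sub)
  if (all(uw$consistent)) {
    L2 <- as.integer(newBoxEdge)
    ext <- apply(uw$coords, 2, function(v) diff(range(v))) + 2
    if (any(ext > L2))
      stop("deswelling box too small for the unwrapped cluster extent")
    offset <- round(colMeans(uw$coords))  # integer shift keeps the lattice intact
    shifted <- sweep(uw$coords, 2, offset - floor(L2 / 2)) %% L2
    out <- latticeState(L2, shifted, sub@species, sub@moleculeId, sub@bonds,
                        sub@reactive, sub@consumed)
    attr(out, "wrapped") <- FALSE
  } else {
    out <- sub
    attr(out, "wrapped") <- TRUE
  }
  audit <- auditState(out)
  if (audit$overlaps > 0 || audit$badBonds > 0)
    stop("internal error: extracted BMC fails the lattice audit")
  out
}

#' Deswelling (poor-solvent collapse) run
#'
#' Models the dehydration/fixation of the ethanol series: Monte Carlo under
#' an attractive PEG-PEG contact energy (default -0.30 kT) that drives
#' starPEG self-aggregation, with the final snapshot resembling the
#' resin-embedded network.
#'
#' @param bmcState the extracted BMC state ([extractBMCState()]).
#' @param epsilonPP attractive PEG-PEG contact energy in kT (default -0.30).
#' @param nMCS Monte Carlo step budget.
#' @param seed integer seed.
#' @param nSnapshots number of evenly spaced trajectory snapshots to record
#'   (default 10; the final snapshot is always included).
#' @return list with \code{state} (final snapshot), \code{trajectory}
#'   (data.frame mcs, contactEnergy, rgPeg) and \code{snapshots} (list of
#'   intermediate [LatticeState-class] objects).
#' @export
deswellRun <- function(bmcState, epsilonPP = -0.30, nMCS = 1e6, seed = 1L,
                       nSnapshots = 10L) {
  en <- energyModel(epsilonPP)
  chunks <- max(1L, as.integer(nSnapshots))
  per <- nMCS / chunks
  st <- bmcState
  traj <- data.frame(mcs = numeric(), contactEnergy = numeric(),
                     rgPeg = numeric())
  snaps <- vector("list", chunks)
  for (k in seq_len(chunks)) {
    st <- runMCS(st, per, en, seed = seed + k)
    snaps[[k]] <- st
    traj <- rbind(traj, data.frame(
      mcs = per * k,
      contactEnergy = contactEnergy(st, en),
      # Rg is undefined for clusters winding the periodic box
      rgPeg = tryCatch(radiusOfGyration(st, species = "PEG"),
                       error = function(e) NA_real_)))
  }
  audit <- auditState(st)
  if (audit$overlaps > 0 || audit$badBonds > 0)
    stop("lattice audit failed after deswelling run")
  list(state = st, trajectory = traj, snapshots = snaps)
}

#' Radius of gyration
#'
#' Rg = sqrt(mean squared distance to the centroid), computed on unwrapped
#' coordinates (bond-graph traversal across the periodic boundaries). For a
#' state whose cluster winds the box a consistent unwrap does not exist and
#' an error is raised.
#'
#' @param x a [LatticeState-class], or a numeric n x 3 matrix of already
#'   unwrapped coordinates (lattice units).
#' @param species optional species filter ("PEG" or "HEP") when \code{x} is
#'   a state.
#' @param units "lattice" (default) or "nm".
#' @return numeric Rg.
#' @export
radiusOfGyration <- function(x, species = NULL, units = c("lattice", "nm")) {
  units <- match.arg(units)
  if (is(x, "LatticeState")) {
    if (nMonomers(x) == 0) stop("state has no monomers")
    uw <- unwrapPositions(x)
    if (!all(uw$consistent))
      stop("cluster winds the periodic box; no consistent unwrap exists")
    coords <- uw$coords
    if (!is.null(species)) coords <- coords[x@species == species, , drop = FALSE]
  } else {
    coords <- as.matrix(x)
  }
  if (nrow(coords) == 0) stop("no positions to analyse")
  centred <- sweep(coords, 2, colMeans(coords))
  rg <- sqrt(mean(rowSums(centred^2)))
  if (units == "nm") latticeToNm(rg) else rg
}

#' Aggregate and void statistics of a (collapsed) state
#'
#' PEG aggregates are connected components of PEG monomers under the
#' contact-shell adjacency. Voids are characterised by largest-empty-sphere
#' sampling: the radius from each of \code{nProbes} random points to the
#' nearest occupied lattice site. A coarse-grid occupancy profile is
#' reported alongside.
#'
#' @param state a [LatticeState-class].
#' @param nProbes number of random probe points (default 1e4).
#' @param gridCells coarse density grid cells per axis (default 8).
#' @param seed integer seed for the probes.
#' @return list with \code{pegClusterSizes} (sorted decreasing),
#'   \code{voidRadii} (lattice units), \code{voidRadiiNm}, \code{capped}
#'   (TRUE when the probe radius cap, half the box, was reached - e.g. for
#'   an empty box) and \code{densityProfile} (3D array of monomer counts).
#' @export
aggregateVoidStats <- function(state, nProbes = 1e4, gridCells = 8L,
                               seed = 1L) {
  L <- boxEdge(state)
  isPeg <- state@species == "PEG"
  if (any(isPeg)) {
    lab <- .peg_clusters_cpp(L, state@positions, .speciesCode(state))
    sizes <- sort(as.integer(table(lab[lab > 0])), decreasing = TRUE)
  } else {
    sizes <- integer()
  }
  if (nMonomers(state) > 0) {
    radii <- .void_probe_cpp(L, state@positions, as.integer(nProbes),
                             as.double(seed))
  } else {
    radii <- rep(L / 2, nProbes)
  }
  capped <- any(radii >= L / 2 - 1e-9)
  cell <- L / gridCells
  bin <- floor(state@positions / cell) + 1
  dens <- array(0L, dim = rep(gridCells, 3))
  if (nMonomers(state) > 0)
    for (m in seq_len(nrow(bin)))
      dens[bin[m, 1], bin[m, 2], bin[m, 3]] <- dens[bin[m, 1], bin[m, 2], bin[m, 3]] + 1L
  list(pegClusterSizes = sizes, voidRadii = radii,
       voidRadiiNm = latticeToNm(radii), capped = capped,
       densityProfile = dens)
}
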