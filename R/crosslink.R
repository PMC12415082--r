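# Michael-type crosslinking as collision-triggered permanent bond formation

#' Extent of reaction
#'
#' p = (number of crosslink bonds) / (4 x number of starPEG molecules): the
#' fraction of starPEG terminal groups converted into crosslinks.
#'
#' @param state a [LatticeState-class].
#' @return numeric p in \code{[0, 1]}; 0 with a warning when the state
#'   contains no starPEG.
#' @export
extentOfReaction <- function(state) {
  pegMols <- unique(state@moleculeId[state@species == "PEG"])
  if (length(pegMols) == 0) {
    warning("state contains no starPEG molecules; extent of reaction is 0 by convention")
    return(0)
  }
  nCross <- sum(state@bonds$kind == "crosslink")
  nCross / (4 * length(pegMols))
}

#' Crosslink a solution up to a target extent of reaction
#'
#' Runs Monte Carlo sweeps in which, after each accepted move of a reactive
#' unconsumed monomer, partner sites of the other species one allowed bond
#' vector away ("direct collision") are scanned; one permanent crosslink
#' bond is formed per event (ties broken uniformly at random), consuming
#' both sites. The run stops when the extent of reaction reaches
#' \code{pTarget} or the MCS budget is exhausted.
#'
#' @param state a [LatticeState-class] holding reactive sites of both
#'   species.
#' @param pTarget target extent of reaction in \code{[0, 1]} (default 0.90).
#' @param maxMCS Monte Carlo step budget (default 1e7 for scaled boxes).
#' @param seed integer seed.
#' @param energy an [EnergyModel-class]; good-solvent (athermal) by default,
#'   matching the order of operations in which deswelling follows
#'   crosslinking.
#' @return list with \code{state} (crosslinks appended, consumed flags set)
#'   and \code{log}, a data.frame with columns \code{mcs}, \code{pegMonomer},
#'   \code{hepMonomer}, \code{p} (trajectory of the extent of reaction),
#'   plus attributes \code{reachedTarget} and \code{mcsDone}.
#' @export
crosslinkUntil <- function(state, pTarget = 0.90, maxMCS = 1e7, seed = 1L,
                           energy = energyModel(0)) {
  stopifnot(pTarget >= 0, pTarget <= 1)
  pegMols <- unique(state@moleculeId[state@species == "PEG"])
  nTermini <- 4L * length(pegMols)
  existing <- sum(state@bonds$kind == "crosslink")
  targetTotal <- ceiling(pTarget * nTermini - 1e-9)
  targetNew <- as.integer(targetTotal - existing)
  emptyLog <- data.frame(mcs = numeric(), pegMonomer = integer(),
                         hepMonomer = integer(), p = numeric())
  if (pTarget == 0 || targetNew <= 0) {
    attr(emptyLog, "reachedTarget") <- TRUE
    attr(emptyLog, "mcsDone") <- 0
    return(list(state = state, log = emptyLog))
  }
  freePeg <- sum(state@reactive & !state@consumed & state@species == "PEG")
  freeHep <- sum(state@reactive & !state@consumed & state@species == "HEP")
  if (min(freePeg, freeHep) < targetNew)
    stop(sprintf(
      "p target %.2f unreachable: %d new crosslinks needed but only %d free PEG and %d free HEP sites",
      pTarget, targetNew, freePeg, freeHep))
  res <- .bfm_run_cpp(boxEdge(state), state@positions, .speciesCode(state),
                      .bondMatrix0(state), state@reactive, state@consumed,
                      as.double(maxMCS), energy@epsilonPP, TRUE, targetNew,
                      as.double(seed))
  state@positions <- res$pos
  storage.mode(state@positions) <- "integer"
  state@consumed <- res$consumed
  nb <- res$newBonds
  if (nrow(nb) > 0)
    state@bonds <- rbind(state@bonds,
                         data.frame(i = nb[, 1], j = nb[, 2],
                                    kind = "crosslink"))
  log <- data.frame(mcs = res$eventMCS,
                    pegMonomer = if (nrow(nb)) nb[, 1] else integer(),
                    hepMonomer = if (nrow(nb)) nb[, 2] else integer())
  log$p <- (existing + seq_len(nrow(log))) / nTermini
  if (!res$reachedTarget)
    warning(sprintf("MCS budget exhausted at p = %.3f < target %.2f; partial result",
                    extentOfReaction(state), pTarget))
  attr(log, "reachedTarget") <- res$reachedTarget
  attr(log, "mcsDone") <- res$mcsDone
  list(state = state, log = log)
}
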