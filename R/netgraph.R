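# molecule-level multigraph of the crosslinked system and the gel-cluster
# (biggest molecule cluster) quality metrics

#' Molecule-level crosslink multigraph
#'
#' One vertex per molecule (attribute \code{species}), one edge per
#' crosslink bond; parallel edges are preserved. The graph is bipartite
#' PEG vs HEP by chemistry.
#'
#' @param state a [LatticeState-class] with molecule ids.
#' @return an \pkg{igraph} multigraph; vertex names are molecule ids.
#' @export
moleculeGraph <- function(state) {
  mols <- sort(unique(state@moleculeId))
  molSpecies <- state@species[match(mols, state@moleculeId)]
  cl <- state@bonds[state@bonds$kind == "crosslink", , drop = FALSE]
  if (nrow(cl) > 0) {
    si <- state@species[cl$i]
    sj <- state@species[cl$j]
    if (any(si == sj))
      stop("crosslink joining two molecules of the same species violates bipartite chemistry")
  }
  g <- igraph::make_empty_graph(n = length(mols), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(mols))
  g <- igraph::set_vertex_attr(g, "species", value = molSpecies)
  if (nrow(cl) > 0) {
    mi <- match(state@moleculeId[cl$i], mols)
    mj <- match(state@moleculeId[cl$j], mols)
    g <- igraph::add_edges(g, rbind(mi, mj))
  }
  g
}

#' Extract the biggest molecule cluster (BMC)
#'
#' The connected component with the most molecules - the gel-fraction proxy.
#' Ties are broken by more crosslink edges, then by the smallest contained
#' molecule id, so the choice is deterministic.
#'
#' @param graph a molecule graph from [moleculeGraph()].
#' @return the induced subgraph of the winning component.
#' @export
biggestMoleculeCluster <- function(graph) {
  if (igraph::vcount(graph) == 0) stop("empty graph has no molecule cluster")
  comp <- igraph::components(graph)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    edges <- vapply(best, function(k) {
      sub <- igraph::induced_subgraph(graph, which(comp$membership == k))
      igraph::ecount(sub)
    }, 0)
    best <- best[edges == max(edges)]
    if (length(best) > 1) {
      minid <- vapply(best, function(k)
        min(as.integer(igraph::V(graph)$name[comp$membership == k])), 0)
      best <- best[which.min(minid)]
    }
  }
  igraph::induced_subgraph(graph, which(comp$membership == best[1]))
}

#' Cycle rank of the BMC and cycle rank per strand
#'
#' For a connected multigraph the cycle rank (first Betti number) is
#' E - V + 1, with parallel edges counted. The per-strand normalisation
#' divides by the number of crosslink edges in the cluster, each edge
#' anchoring one elastically active arm.
#'
#' @param bmc a connected molecule (sub)graph.
#' @param strandCount strand normalisation; defaults to the crosslink edge
#'   count of \code{bmc}.
#' @return list with \code{cycleRank} (integer) and \code{zetaPerStrand}.
#' @export
cycleRank <- function(bmc, strandCount = igraph::ecount(bmc)) {
  if (!igraph::is_connected(bmc))
    stop("cycle rank is defined here for the connected BMC only")
  r <- igraph::ecount(bmc) - igraph::vcount(bmc) + 1L
  list(cycleRank = as.integer(r),
       zetaPerStrand = if (strandCount > 0) r / strandCount else NA_real_)
}

#' Census of primitive network defects
#'
#' Counts the elastically ineffective motifs: unreacted (dangling) arms on
#' starPEG molecules inside the BMC, multiple bonds between one starPEG and
#' a single heparin (one count per extra parallel edge, over the whole
#' graph), and molecules left outside the BMC.
#'
#' @param graph the full molecule graph.
#' @param bmc the biggest molecule cluster subgraph.
#' @return list with counts \code{danglingPegArms}, \code{multiEdges},
#'   \code{unboundPeg}, \code{unboundHep}.
#' @export
defectCensus <- function(graph, bmc) {
  inBmc <- igraph::V(graph)$name %in% igraph::V(bmc)$name
  sp <- igraph::V(graph)$species
  deg <- igraph::degree(graph)
  dangling <- sum(pmax(4L - deg[inBmc & sp == "PEG"], 0L))
  multi <- 0L
  if (igraph::ecount(graph) > 0) {
    el <- igraph::as_edgelist(graph)
    pairKey <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    cnt <- table(pairKey)
    multi <- sum(pmax(as.integer(cnt) - 1L, 0L))
  }
  list(danglingPegArms = as.integer(dangling),
       multiEdges = as.integer(multi),
       unboundPeg = sum(!inBmc & sp == "PEG"),
       unboundHep = sum(!inBmc & sp == "HEP"))
}

#' Quality metrics of the biggest molecule cluster
#'
#' Computes the effective molar ratio gamma_BMC = nPEG,BMC / nHEP,BMC, the
#' heparin functionality f_HEP,BMC (crosslink bonds per heparin in the BMC;
#' the distinct-partner reading is reported alongside), per-species
#' incorporation efficiencies (molecules in the BMC over molecules in the
#' reaction mixture), the cycle rank with its per-strand normalisation, and
#' the defect census.
#'
#' @param graph the full molecule graph.
#' @param bmc the biggest molecule cluster subgraph (default extracted from
#'   \code{graph}).
#' @param initialCounts optional list \code{list(nPEG =, nHEP =)} of the
#'   reaction-mixture composition; defaults to the counts in \code{graph}.
#' @return a [BMCMetrics-class] object.
#' @export
bmcMetrics <- function(graph, bmc = biggestMoleculeCluster(graph),
                       initialCounts = NULL) {
  spB <- igraph::V(bmc)$species
  nP <- sum(spB == "PEG"); nH <- sum(spB == "HEP")
  if (nH == 0) stop("BMC contains no heparin; metrics undefined")
  if (is.null(initialCounts)) {
    sp <- igraph::V(graph)$species
    initialCounts <- list(nPEG = sum(sp == "PEG"), nHEP = sum(sp == "HEP"))
  }
  edges <- igraph::ecount(bmc)
  hepDeg <- igraph::degree(bmc)[spB == "HEP"]
  simple <- igraph::simplify(bmc, remove.multiple = TRUE)
  hepDegDistinct <- igraph::degree(simple)[igraph::V(simple)$species == "HEP"]
  cr <- cycleRank(bmc)
  new("BMCMetrics",
      gammaBMC = nP / nH,
      fHepBMC = mean(hepDeg),
      fHepBMCDistinct = mean(hepDegDistinct),
      incorporationPEG = if (initialCounts$nPEG > 0) nP / initialCounts$nPEG else 0,
      incorporationHEP = nH / initialCounts$nHEP,
      cycleRank = cr$cycleRank,
      zetaPerStrand = cr$zetaPerStrand,
      defects = defectCensus(graph, bmc))
}
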