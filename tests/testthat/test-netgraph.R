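# molecule multigraph, BMC extraction, network-quality metrics

# hand-built molecule graphs for deterministic cases
.mkGraph <- function(edges, nPeg, nHep) {
  g <- igraph::make_empty_graph(nPeg + nHep, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(nPeg + nHep)))
  g <- igraph::set_vertex_attr(g, "species",
                               value = c(rep("PEG", nPeg), rep("HEP", nHep)))
  if (length(edges)) g <- igraph::add_edges(g, edges)
  g
}

test_that("moleculeGraph aggregates crosslinks to molecule level, preserving parallels", {
  st0 <- .lgTestMini(nPEG = 1, nHEP = 2, seed = 21)
  g0 <- moleculeGraph(st0)
  expect_equal(igraph::vcount(g0), 3)
  expect_equal(igraph::ecount(g0), 0)
  fx <- lgFixture("multi_edge_pair")
  expect_equal(igraph::ecount(fx$graph), 2)            # two parallel edges
  expect_true(igraph::any_multiple(fx$graph))
  # edge count equals the reaction-log length by conservation
  expect_equal(igraph::ecount(fx$graph),
               sum(fx$state@bonds$kind == "crosslink"))
  # same-species crosslink is chemically impossible and rejected
  bad <- fx$state
  bad@bonds$kind[1] <- "intra"
  hep2 <- which(bad@species == "HEP")[1:2]
  bad@bonds <- rbind(bad@bonds,
                     data.frame(i = hep2[1], j = hep2[2], kind = "crosslink"))
  expect_error(moleculeGraph(bad), "bipartite")
})

test_that("biggest molecule cluster picks by size, then edges, then smallest id", {
  # components of sizes 5, 3, 1
  g <- .mkGraph(c(1,6, 2,6, 3,7, 1,7,  4,8, 5,8), nPeg = 5, nHep = 4)
  # component {1,2,3,6,7} size 5; {4,5,8} size 3; {9} size 1
  bmc <- biggestMoleculeCluster(g)
  expect_setequal(igraph::V(bmc)$name, as.character(c(1, 2, 3, 6, 7)))
  # two 4-node components, 3 vs 4 edges: the 4-edge one wins
  g2 <- .mkGraph(c(1,5, 2,5, 2,6,   3,7, 4,7, 3,8, 4,8), nPeg = 4, nHep = 4)
  bmc2 <- biggestMoleculeCluster(g2)
  expect_setequal(igraph::V(bmc2)$name, as.character(c(3, 4, 7, 8)))
  # full tie: smallest molecule id decides
  g3 <- .mkGraph(c(1,3, 2,4), nPeg = 2, nHep = 2)
  expect_true("1" %in% igraph::V(biggestMoleculeCluster(g3))$name)
  expect_error(biggestMoleculeCluster(.mkGraph(integer(), 0, 0)), "empty")
})

test_that("cycle rank is E - V + 1 on the connected BMC and matches the GF(2) oracle", {
  expect_equal(cycleRank(.mkGraph(c(1,2), 1, 1))$cycleRank, 0)   # tree
  c4 <- .mkGraph(c(1,3, 3,2, 2,4, 4,1), 2, 2)                    # 4-cycle
  expect_equal(cycleRank(c4)$cycleRank, 1)
  par3 <- .mkGraph(c(1,2, 1,2, 1,2), 1, 1)                       # 3 parallel
  expect_equal(cycleRank(par3)$cycleRank, 2)
  expect_error(cycleRank(.mkGraph(c(1,3), 2, 2)), "connected")
  # oracle agreement on every fixture graph (all <= 8 molecules)
  for (preset in c("tree", "single_cycle", "multi_edge_pair", "mini_gel")) {
    fx <- lgFixture(preset)
    bmc <- biggestMoleculeCluster(fx$graph)
    el <- igraph::as_edgelist(bmc, names = FALSE)
    expect_equal(cycleRank(bmc)$cycleRank,
                 gf2CycleDim(el, igraph::vcount(bmc)),
                 info = preset)
  }
})

test_that("fixture networks realise their hand-computed metrics", {
  tr <- lgFixture("tree")
  expect_equal(cycleRank(biggestMoleculeCluster(tr$graph))$cycleRank,
               tr$expected$cycleRank)
  me <- lgFixture("multi_edge_pair")
  m <- bmcMetrics(me$graph)
  expect_equal(m@fHepBMC, 2)
  expect_equal(m@defects$multiEdges, 1L)
  expect_equal(m@defects$danglingPegArms, 2L)
  sc <- lgFixture("single_cycle")
  ms <- bmcMetrics(sc$graph)
  expect_equal(ms@gammaBMC, 1.0)
  expect_equal(ms@fHepBMC, 2.0)
  expect_equal(ms@cycleRank, 1L)
  tc <- lgFixture("two_components")
  expect_equal(sort(igraph::components(tc$graph)$csize, decreasing = TRUE),
               c(2, 1))
  mg <- lgFixture("mini_gel")
  expect_equal(cycleRank(biggestMoleculeCluster(mg$graph))$cycleRank, 6L)
})

test_that("incorporation, defect census and zeta follow their definitions", {
  # BMC = 2 PEG + 2 HEP with 4 edges; plus one unbound PEG and HEP
  g <- .mkGraph(c(1,4, 4,2, 2,5, 5,1), nPeg = 3, nHep = 3)
  bmc <- biggestMoleculeCluster(g)
  m <- bmcMetrics(g, bmc)
  expect_equal(m@gammaBMC, 1.0)
  expect_equal(m@fHepBMC, 2.0)
  expect_equal(m@incorporationPEG, 2 / 3)
  expect_equal(m@incorporationHEP, 2 / 3)
  expect_equal(m@defects$unboundPeg, 1L)
  expect_equal(m@defects$unboundHep, 1L)
  expect_equal(m@defects$danglingPegArms, 2L + 2L)  # two arms free per PEG
  expect_equal(m@zetaPerStrand, 1 / 4)
  # all molecules inside: incorporation 1
  mAll <- bmcMetrics(g, bmc, initialCounts = list(nPEG = 2, nHEP = 2))
  expect_equal(mAll@incorporationPEG, 1.0)
  # fully reacted PEG contributes no defects
  gFull <- .mkGraph(c(1,2, 1,3, 1,4, 1,5), nPeg = 1, nHep = 4)
  mFull <- bmcMetrics(gFull)
  expect_equal(mFull@defects$danglingPegArms, 0L)
  expect_equal(mFull@defects$multiEdges, 0L)
})

test_that("gamma_BMC approaches gamma at full conversion with abundant sites", {
  run <- miniPipelineGraph(0.5, boxEdge = 64, seed = 31)
  # push conversion to 1: every PEG reacts, so the BMC contains all PEG
  st <- run$state
  res <- suppressWarnings(crosslinkUntil(st, pTarget = 1, maxMCS = 5e5,
                                         seed = 32))
  expect_true(attr(res$log, "reachedTarget"))
  g <- moleculeGraph(res$state)
  bmc <- biggestMoleculeCluster(g)
  m <- bmcMetrics(g, bmc, initialCounts = run$counts)
  gammaEff <- run$counts$nPEG / sum(igraph::V(bmc)$species == "HEP")
  expect_equal(m@gammaBMC, gammaEff)
  expect_equal(m@incorporationPEG, 1.0)
})
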