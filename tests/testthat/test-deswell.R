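# BMC extraction, poor-solvent collapse, aggregate/void observables

test_that("radius of gyration matches closed forms", {
  expect_equal(radiusOfGyration(matrix(c(3, 4, 5), 1)), 0)
  two <- rbind(c(0, 0, 0), c(6, 0, 0))
  expect_equal(radiusOfGyration(two), 3)          # two points: d/2
  # N collinear points at spacing a: Rg = a*sqrt((N^2-1)/12); N=4, a=2
  four <- cbind(seq(0, by = 2, length.out = 4), 0, 0)
  expect_equal(radiusOfGyration(four), 2 * sqrt(15 / 12))
  expect_equal(radiusOfGyration(four, units = "nm"), 0.6 * sqrt(15 / 12))
})

test_that("unwrapped Rg is periodic-boundary safe", {
  # dimer straddling the boundary: wrapped coordinates are far apart,
  # unwrapped distance is one bond
  st <- latticeState(16, rbind(c(15L, 0L, 0L), c(1L, 0L, 0L)), c("PEG", "PEG"),
                     bonds = data.frame(i = 1L, j = 2L, kind = "intra"))
  expect_equal(radiusOfGyration(st), 1)
})

test_that("BMC extraction recentres the cluster in a larger box and audits clean", {
  run <- miniPipelineGraph(0.75, boxEdge = 64, seed = 41)
  bmc <- biggestMoleculeCluster(run$graph)
  st2 <- extractBMCState(run$state, bmc, newBoxEdge = 128L)
  keepMols <- as.integer(igraph::V(bmc)$name)
  expect_setequal(unique(moleculeIds(st2)), keepMols)
  expect_equal(nMonomers(st2),
               sum(moleculeIds(run$state) %in% keepMols))
  if (!attr(st2, "wrapped")) expect_equal(boxEdge(st2), 128L)
  audit <- auditState(st2)
  expect_equal(audit$overlaps, 0)
  expect_equal(audit$badBonds, 0)
  # crosslink bond count is preserved by extraction
  expect_equal(sum(bondTable(st2)$kind == "crosslink"), igraph::ecount(bmc))
})

test_that("attractive contacts collapse a single star below its athermal size", {
  tpl <- buildStarPEG(seed = 51)
  st <- latticeState(96, tpl@positions + 40L, rep("PEG", 117),
                     bonds = cbind(tpl@bonds, kind = "intra"))
  rg <- function(state, eps, seed) {
    en <- energyModel(eps)
    s <- state
    vals <- vapply(1:80, function(k) {
      s <<- runMCS(s, 2500, en, seed = seed + k)
      radiusOfGyration(s)
    }, 0)
    mean(vals[-(1:35)])
  }
  rgAthermal <- rg(st, 0, seed = 100)
  rgCollapsed <- rg(st, -0.30, seed = 200)
  expect_lt(rgCollapsed, rgAthermal)
})

test_that("contact energy decreases to a plateau during deswelling", {
  st <- lgSmallBMC()
  e0 <- contactEnergy(st, energyModel(-0.30))       # pre-collapse energy
  dw <- deswellRun(st, epsilonPP = -0.30, nMCS = 3e4, seed = 43,
                   nSnapshots = 6L)
  en <- dw$trajectory$contactEnergy
  expect_lt(mean(utils::tail(en, 3)), e0)           # net downhill
  # plateau: the late trajectory no longer drifts like the initial drop
  expect_lt(abs(en[6] - en[4]), abs(min(en) - e0) / 2 + 1e-9)
  expect_true(all(diff(dw$trajectory$mcs) > 0))
  # final state keeps every lattice invariant (audited inside deswellRun too)
  audit <- auditState(dw$state)
  expect_equal(audit$overlaps + audit$badBonds, 0)
})

test_that("athermal control leaves the PEG size statistically unchanged", {
  st <- lgSmallBMC()
  dw <- deswellRun(st, epsilonPP = 0, nMCS = 1e4, seed = 45, nSnapshots = 4L)
  rg0 <- radiusOfGyration(st, species = "PEG")
  rg1 <- dw$trajectory$rgPeg
  expect_lt(abs(mean(rg1) - rg0) / rg0, 0.25)
})

test_that("aggregate and void statistics match hand-built fixtures", {
  # two 10-monomer PEG blobs far apart: exactly 2 clusters of size 10
  blob <- function(ox) {
    g <- as.matrix(expand.grid(x = 0:1, y = 0:4, z = 0))
    cbind(ox + 2L * g[, 1], 2L * g[, 2], 0L)
  }
  pos <- rbind(blob(0L), blob(30L))
  st <- latticeState(64, pos, rep("PEG", 20))
  stats <- aggregateVoidStats(st, nProbes = 500, seed = 3)
  expect_equal(stats$pegClusterSizes, c(10L, 10L))
  expect_true(all(stats$voidRadii >= 0 & stats$voidRadii <= 32))
  # all monomers pairwise beyond the shell: every cluster has size 1
  far <- latticeState(64, rbind(c(0L,0L,0L), c(10L,0L,0L), c(20L,0L,0L)),
                      rep("PEG", 3))
  expect_equal(aggregateVoidStats(far, nProbes = 10, seed = 1)$pegClusterSizes,
               c(1L, 1L, 1L))
  # empty box: probe radius cap with flag
  empty <- latticeState(32, matrix(integer(), 0, 3), character())
  es <- aggregateVoidStats(empty, nProbes = 10, seed = 1)
  expect_true(es$capped)
  expect_true(all(es$voidRadii == 16))
})

test_that("collapse grows voids and PEG aggregates relative to the pre-deswelling state", {
  st <- lgSmallBMC()
  before <- aggregateVoidStats(st, nProbes = 3000, seed = 5)
  dw <- deswellRun(st, epsilonPP = -0.30, nMCS = 5e4, seed = 47,
                   nSnapshots = 5L)
  after <- aggregateVoidStats(dw$state, nProbes = 3000, seed = 5)
  expect_gt(mean(after$voidRadii), mean(before$voidRadii))
  expect_gt(max(after$pegClusterSizes), max(before$pegClusterSizes))
})
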