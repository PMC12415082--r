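# independent oracles used across the suite

# cycle-space dimension of a multigraph = E - rank(incidence matrix over GF(2));
# parallel edges contribute zero columns pairwise, handled by the rank
gf2CycleDim <- function(edgelist, nVertices) {
  E <- nrow(edgelist)
  if (E == 0) return(0L)
  M <- matrix(0L, nVertices, E)
  for (e in seq_len(E)) {
    i <- edgelist[e, 1]; j <- edgelist[e, 2]
    if (i != j) { M[i, e] <- 1L; M[j, e] <- 1L }
  }
  rank <- 0L
  row <- 1L
  for (col in seq_len(E)) {
    piv <- which(M[row:nVertices, col] == 1L)
    if (length(piv) == 0) next
    piv <- piv[1] + row - 1L
    if (piv != row) M[c(row, piv), ] <- M[c(piv, row), ]
    for (r in seq_len(nVertices)) {
      if (r != row && M[r, col] == 1L)
        M[r, ] <- (M[r, ] + M[row, ]) %% 2L
    }
    rank <- rank + 1L
    row <- row + 1L
    if (row > nVertices) break
  }
  as.integer(E - rank)
}

# brute-force O(N^2) count of PEG-PEG contact pairs (squared minimum-image
# distance in {4,5,6})
bruteContactPairs <- function(state) {
  pos <- monomerPositions(state)
  L <- boxEdge(state)
  peg <- which(monomerSpecies(state) == "PEG")
  cnt <- 0L
  mi <- function(d) {
    d <- d %% L
    ifelse(d > L / 2, d - L, d)
  }
  for (a in seq_along(peg)) {
    for (b in seq_len(a - 1L)) {
      d <- mi(pos[peg[a], ] - pos[peg[b], ])
      d2 <- sum(d^2)
      if (d2 >= 4 && d2 <= 6) cnt <- cnt + 1L
    }
  }
  cnt
}

# place k monomers on a line along x at a given spacing, all PEG
lineState <- function(k, spacing = 2L, L = 64L) {
  pos <- cbind(seq(0L, by = spacing, length.out = k), 0L, 0L)
  latticeState(L, pos, rep("PEG", k))
}

# numeric orientation-average of the rod form factor by quadrature over the
# polar angle: P(q) = int_0^1 [sin(qLu/2)/(qLu/2)]^2 du
rodFormFactorQuad <- function(q, L, n = 20001) {
  vapply(q, function(qq) {
    u <- seq(0, 1, length.out = n)
    x <- qq * L * u / 2
    f <- ifelse(x < 1e-12, 1, sin(x) / x)^2
    # trapezoid rule
    sum((f[-1] + f[-n]) / 2) * (u[2] - u[1])
  }, 0)
}

# fixtures are expensive to generate; cache them across test files
.lgFixtureCache <- new.env(parent = emptyenv())
lgFixture <- function(preset, seed = 2L) {
  key <- paste(preset, seed)
  if (is.null(.lgFixtureCache[[key]]))
    .lgFixtureCache[[key]] <- fixtureNetwork(preset, seed = seed)
  .lgFixtureCache[[key]]
}

# assemble a solution with explicit molecule counts (internal assembler)
.lgTestMini <- function(nPEG, nHEP, hepReactive = 28L, boxEdge = 64L,
                        seed = 1L, equilibrationMCS = 100) {
  LatticeGel:::.assembleCounts(nPEG, nHEP, as.integer(boxEdge),
                               equilibrationMCS = equilibrationMCS,
                               seed = seed, hepReactive = hepReactive)
}

# a small, guaranteed-unwrappable BMC state for collapse observables;
# scans mini-gel seeds until the cluster does not wind the periodic box
lgSmallBMC <- function() {
  if (is.null(.lgFixtureCache[["smallBMC"]])) {
    for (s in 2:12) {
      fx <- fixtureNetwork("mini_gel", seed = s)
      bmc <- biggestMoleculeCluster(fx$graph)
      st <- extractBMCState(fx$state, bmc)
      if (!attr(st, "wrapped")) { .lgFixtureCache[["smallBMC"]] <- st; break }
    }
  }
  .lgFixtureCache[["smallBMC"]]
}

# tiny helper: run the full scaled pipeline chain up to the molecule graph
miniPipelineGraph <- function(gamma, boxEdge = 64L, seed = 1L,
                              equilibrationMCS = 1000, maxMCS = 2e5) {
  sol <- assembleSolution(gamma, 1.5, boxEdge, equilibrationMCS, seed = seed)
  cl <- suppressWarnings(
    crosslinkUntil(sol, 0.9, maxMCS = maxMCS, seed = seed + 101L))
  list(state = cl$state, log = cl$log, graph = moleculeGraph(cl$state),
       counts = list(nPEG = attr(sol, "nPEG"), nHEP = attr(sol, "nHEP")))
}
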