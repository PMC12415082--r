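# the BFM move kernel: bond-vector set, excluded volume, Metropolis rule

test_that("allowed bond-vector set contains exactly the 108 classic vectors", {
  v <- allowedBondSet()
  expect_equal(nrow(v), 108)
  expect_true(isAllowedBond(c(2, 0, 0)))
  expect_true(isAllowedBond(c(-3, 1, 0)))
  expect_false(isAllowedBond(c(2, 2, 2)))   # length^2 = 12 is not a class
  expect_true(all(isAllowedBond(-v)))       # closed under negation
  expect_true(all(rowSums(v^2) %in% c(4, 5, 6, 9, 10)))
})

test_that("contact shell holds the 54 nearest non-overlap offsets, negation-symmetric", {
  sh <- contactShellOffsets()
  expect_equal(nrow(sh), 54)
  expect_true(all(rowSums(sh^2) %in% 4:6))
  expect_equal(energyModel()@epsilonPP, 0)
  expect_error(energyModel(contactShell = matrix(c(2, 0, 0), 1)),
               "negation")
})

test_that("a single unbonded monomer moves freely in all six directions", {
  st <- latticeState(16, matrix(c(5L, 5L, 5L), 1), "PEG")
  for (d in c("+x", "-x", "+y", "-y", "+z", "-z")) {
    res <- attemptMove(st, 1, d)
    expect_true(res$accepted)
  }
})

test_that("moves stretching a bond out of the allowed set are rejected", {
  # dimer with bond (3,1,0); +x move of monomer 2 would give (4,1,0)
  st <- latticeState(16, rbind(c(2L, 2L, 2L), c(5L, 3L, 2L)), c("PEG", "PEG"),
                     bonds = data.frame(i = 1L, j = 2L, kind = "intra"))
  res <- attemptMove(st, 2, "+x")
  expect_false(res$accepted)
  expect_identical(res$state@positions, st@positions)
  # perpendicular move keeps the bond allowed: (3,2,0) is not a class -> rejected
  expect_false(attemptMove(st, 2, "+y")$accepted)
  # -x gives (2,1,0): allowed
  expect_true(attemptMove(st, 2, "-x")$accepted)
})

test_that("excluded volume blocks moves into occupied sites", {
  # cubes [4,5] and [8,9] on x: two +x moves close the gap, the third would
  # claim the occupied x=8 plane
  st <- latticeState(16, rbind(c(4L, 4L, 4L), c(8L, 4L, 4L)), c("PEG", "PEG"))
  r1 <- attemptMove(st, 1, "+x")
  expect_true(r1$accepted)
  r2 <- attemptMove(r1$state, 1, "+x", seed = 2)
  expect_true(r2$accepted)
  r3 <- attemptMove(r2$state, 1, "+x", seed = 3)
  expect_false(r3$accepted)
})

test_that("invalid move requests error", {
  st <- latticeState(16, matrix(c(5L, 5L, 5L), 1), "PEG")
  expect_error(attemptMove(st, 2, "+x"), "index")
  expect_error(attemptMove(st, 1, "northwest"), "direction")
})

test_that("Metropolis factor for breaking one PEG-PEG contact is exp(-0.30)", {
  # two PEG monomers at contact offset (2,0,0); +x move of monomer 2 breaks
  # the single contact (new offset (3,0,0), d2=9 outside the shell)
  st <- latticeState(16, rbind(c(4L, 4L, 4L), c(6L, 4L, 4L)), c("PEG", "PEG"))
  en <- energyModel(-0.30)
  expect_equal(contactEnergy(st, en), -0.30)
  n <- 2e4
  acc <- vapply(seq_len(n), function(s)
    attemptMove(st, 2, "+x", energy = en, seed = s)$accepted, TRUE)
  pHat <- mean(acc)
  p <- exp(-0.30)
  expect_lt(abs(pHat - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("contact energy matches the brute-force pair oracle", {
  st <- lineState(10, spacing = 2L)
  en <- energyModel(-0.30)
  expect_equal(contactEnergy(st, en), -0.30 * bruteContactPairs(st))
  # heparin-only state contributes nothing
  st2 <- latticeState(32, rbind(c(0L, 0L, 0L), c(2L, 0L, 0L)), c("HEP", "HEP"))
  expect_equal(contactEnergy(st2, en), 0)
  # mixed state counts only the PEG pair
  st3 <- latticeState(32, rbind(c(0L, 0L, 0L), c(2L, 0L, 0L), c(0L, 4L, 0L)),
                      c("PEG", "PEG", "HEP"))
  expect_equal(contactEnergy(st3, en), -0.30)
})

test_that("runMCS with zero steps is the identity and long runs keep all invariants", {
  st <- assembleSolution(0.5, 1.5, 64, equilibrationMCS = 0, seed = 11)
  expect_identical(monomerPositions(runMCS(st, 0)), monomerPositions(st))
  st2 <- runMCS(st, 500, seed = 12)
  audit <- auditState(st2)
  expect_equal(audit$overlaps, 0)
  expect_equal(audit$badBonds, 0)
  # topology preservation: the bond table is untouched by moves
  expect_identical(bondTable(st2), bondTable(st))
})

test_that("free-chain mean-square bond length is stationary and matches a pure-R oracle", {
  set.seed(2024)
  # kernel route: free 30-mer, long run
  pos <- cbind(seq(0L, by = 2L, length.out = 30L), 0L, 0L)
  st <- latticeState(128, pos, rep("PEG", 30),
                     bonds = data.frame(i = 1:29, j = 2:30, kind = "intra"))
  msb <- replicate(40, {
    st <<- runMCS(st, 2500, seed = sample.int(1e6, 1))
    uw <- unwrapPositions(st)
    mean(rowSums(diff(uw$coords)^2))
  })
  kernelVal <- mean(msb[-(1:10)])
  # stationarity: first and second half of the tail agree
  tail1 <- mean(msb[11:25]); tail2 <- mean(msb[26:40])
  expect_lt(abs(tail1 - tail2), 0.25)
  # sanity band for a dilute athermal BFM chain
  expect_gt(kernelVal, 6.8)
  expect_lt(kernelVal, 7.6)
  # independent route: the same move rules implemented from scratch in R
  oracleVal <- local({
    set.seed(99)
    N <- 12L
    p <- cbind(seq(0, by = 2, length.out = N), 0, 0)
    bv <- allowedBondSet()
    bvKey <- paste(bv[, 1], bv[, 2], bv[, 3])
    dirs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
    overlaps <- function(a, b) all(abs(a - b) < 2)
    samples <- numeric()
    for (t in seq_len(6e4)) {
      i <- sample(N, 1)
      cand <- p[i, ] + dirs[sample(6, 1), ]
      ok <- TRUE
      for (j in seq_len(N)) {
        if (j != i && overlaps(cand, p[j, ])) { ok <- FALSE; break }
      }
      if (ok && i > 1 &&
          !(paste(cand[1] - p[i-1,1], cand[2] - p[i-1,2], cand[3] - p[i-1,3]) %in% bvKey))
        ok <- FALSE
      if (ok && i < N &&
          !(paste(p[i+1,1] - cand[1], p[i+1,2] - cand[2], p[i+1,3] - cand[3]) %in% bvKey))
        ok <- FALSE
      if (ok) p[i, ] <- cand
      if (t > 2e4 && t %% 500 == 0)
        samples <- c(samples, mean(rowSums(diff(p)^2)))
    }
    mean(samples)
  })
  # same N for the kernel route, compared at matched chain length
  pos12 <- cbind(seq(0L, by = 2L, length.out = 12L), 0L, 0L)
  st12 <- latticeState(64, pos12, rep("PEG", 12),
                       bonds = data.frame(i = 1:11, j = 2:12, kind = "intra"))
  k12 <- replicate(40, {
    st12 <<- runMCS(st12, 2000, seed = sample.int(1e6, 1))
    mean(rowSums(diff(unwrapPositions(st12)$coords)^2))
  })
  expect_lt(abs(mean(k12[-(1:10)]) - oracleVal), 0.2)
})

test_that("free chains show self-avoiding (superlinear) end-to-end scaling", {
  set.seed(7)
  r2 <- vapply(c(8L, 16L, 32L), function(N) {
    pos <- cbind(seq(0L, by = 2L, length.out = N), 0L, 0L)
    st <- latticeState(64, pos, rep("PEG", N),
                       bonds = data.frame(i = 1:(N - 1), j = 2:N,
                                          kind = "intra"))
    vals <- replicate(180, {
      st <<- runMCS(st, 2000, seed = sample.int(1e6, 1))
      uw <- unwrapPositions(st)
      sum((uw$coords[N, ] - uw$coords[1, ])^2)
    })
    mean(vals[-(1:40)])
  }, 0)
  # R^2 ~ N^(2*0.588): doubling N should grow R^2 by ~2.25, clearly above 2
  expect_gt(r2[2] / r2[1], 2)
  expect_gt(r2[3] / r2[2], 2)
})

test_that("dimer sampling is uniform over the 108 bond vectors (detailed balance)", {
  st <- latticeState(16, rbind(c(0L, 0L, 0L), c(2L, 0L, 0L)), c("PEG", "PEG"),
                     bonds = data.frame(i = 1L, j = 2L, kind = "intra"))
  bv <- allowedBondSet()
  key <- paste(bv[, 1], bv[, 2], bv[, 3])
  counts <- stats::setNames(numeric(108), key)
  L <- 16
  mi <- function(d) ifelse(d > L / 2, d - L, ifelse(d < -L / 2, d + L, d))
  for (rep in 1:2500) {
    st <- runMCS(st, 400, seed = rep)
    d <- mi(monomerPositions(st)[2, ] - monomerPositions(st)[1, ])
    k <- paste(d[1], d[2], d[3])
    counts[k] <- counts[k] + 1
  }
  # chi-square goodness of fit against the uniform distribution
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 1e-4)
  expect_true(all(counts > 0))   # ergodic over all 108 states
})

test_that("with zero contact energy the acceptance never consults the Metropolis draw", {
  st <- latticeState(16, rbind(c(4L, 4L, 4L), c(6L, 4L, 4L)), c("PEG", "PEG"))
  res <- vapply(1:50, function(s)
    attemptMove(st, 2, "+x", energy = energyModel(0), seed = s)$accepted, TRUE)
  expect_true(all(res))   # identical decision for every seed
})
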