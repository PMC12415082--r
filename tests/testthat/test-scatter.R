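# Debye profiles, rod form factor, power-law slopes, peak d-spacings

test_that("Debye profile reproduces closed forms for one and two points", {
  q <- seq(0.1, 5, by = 0.1)
  one <- intensityProfile(matrix(c(1, 2, 3), 1), weights = 2, qGrid = q)
  expect_equal(intensities(one), rep(4, length(q)))   # w^2, flat
  d <- 3.2
  two <- intensityProfile(rbind(c(0, 0, 0), c(d, 0, 0)), qGrid = q)
  expect_equal(intensities(two), 2 * (1 + sin(q * d) / (q * d)),
               tolerance = 1e-12)
  expect_error(intensityProfile(rbind(c(0,0,0), c(1,0,0)), qGrid = c(-1, 1)),
               "positive")
})

test_that("rod form factor has the exact limits and matches quadrature", {
  expect_equal(rodFormFactor(1e-9, 15), 1.0)
  # large-qL asymptote pi/(qL): log-log slope -1
  x <- 50
  expect_lt(abs(rodFormFactor(x / 15, 15) - pi / x) / (pi / x), 0.05)
  # independent quadrature oracle at qL = 1 (and a few more)
  for (qL in c(0.5, 1, 3, 10)) {
    expect_lt(abs(rodFormFactor(qL / 7, 7) - rodFormFactorQuad(qL / 7, 7)),
              1e-6)
  }
})

test_that("Debye sum over a dense rod converges to the analytic rod form factor", {
  L <- 15
  n <- 400
  pts <- cbind(seq(0, L, length.out = n), 0, 0)
  q <- exp(seq(log(2 / L), log(30 / L), length.out = 40))
  prof <- intensityProfile(pts, qGrid = q, nSubsample = n)
  pNum <- intensities(prof) / n^2
  pAna <- rodFormFactor(q, L)
  rms <- sqrt(mean((pNum / pAna - 1)^2))
  expect_lt(rms, 0.03)
})

test_that("power-law slopes are exact on exact power laws", {
  q <- seq(1, 4, length.out = 50)
  expect_equal(powerlawSlope(scatteringProfile(q, 5 / q), 1, 4)$slope, -1,
               tolerance = 1e-10)
  expect_equal(powerlawSlope(scatteringProfile(q, rep(2, 50)), 1, 4)$slope, 0,
               tolerance = 1e-10)
  expect_error(powerlawSlope(scatteringProfile(q, 1 / q), 3.9, 4), "5 points")
  # thin rod of 15 nm over q in [1,4]: the rod signature within [-1.1, -0.9]
  qq <- seq(0.5, 5, length.out = 200)
  rod <- scatteringProfile(qq, rodFormFactor(qq, 15))
  sl <- powerlawSlope(rod, 1, 4)$slope
  expect_gt(sl, -1.1)
  expect_lt(sl, -0.9)
})

test_that("peak detection and d-spacing invert each other", {
  # d = 2pi/q identities
  q <- seq(10, 18, by = 0.02)
  synth <- syntheticScattering("peak_background",
                               list(qPeak = 14.2, peakHeight = 10,
                                    peakWidth = 0.5, bgAmplitude = 30,
                                    bgSlope = -2),
                               qGrid = q)
  pk <- peakAndDspacing(synth$profile, qWindow = c(12, 16))
  expect_lt(abs(pk$qPeak - 14.2), 0.05)
  expect_equal(pk$dSpacing, 2 * pi / pk$qPeak)
  # exact arithmetic: q = 2pi -> d = 1 nm
  expect_equal(2 * pi / (2 * pi), 1)
  # no interior maximum errors
  mono <- scatteringProfile(q, 100 / q^2)
  expect_error(peakAndDspacing(mono, qWindow = c(12, 16)), "maximum")
})

test_that("rod length is recoverable by form-factor fitting", {
  q <- exp(seq(log(0.2), log(3), length.out = 60))
  synth <- syntheticScattering("rod", list(L = 15, amplitude = 7), qGrid = q)
  fit <- fitRodLength(synth$profile, Lstart = 8)
  expect_lt(abs(fit$L - 15) / 15, 0.05)
  expect_lt(fit$rmsLogResidual, 1e-4)
})

test_that("deswollen snapshots gain low-q intensity relative to the swollen state", {
  st <- lgSmallBMC()
  dw <- deswellRun(st, epsilonPP = -0.30, nMCS = 5e4, seed = 49,
                   nSnapshots = 5L)
  q <- exp(seq(log(0.08), log(2), length.out = 30))
  profOf <- function(state) {
    uw <- unwrapPositions(state)
    peg <- monomerSpecies(state) == "PEG"
    intensityProfile(latticeToNm(uw$coords[peg, , drop = FALSE]),
                     qGrid = q, nSubsample = 1500, seed = 5)
  }
  I0 <- intensities(profOf(st))
  I1 <- intensities(profOf(dw$state))
  lowq <- q < 0.3
  expect_gt(mean(I1[lowq] / I0[lowq]), 1)
})
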