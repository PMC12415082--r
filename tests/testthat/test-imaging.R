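# virtual TEM, binarization, skeleton branch lengths, void Feret analysis

test_that("virtual TEM renders heparin dark with projection additivity", {
  # no heparin in the slab: uniformly bright
  tpl <- buildStarPEG(seed = 61)
  st <- latticeState(64, tpl@positions + 20L, rep("PEG", 117),
                     bonds = cbind(tpl@bonds, kind = "intra"))
  img <- virtualTEM(st, slabThicknessNm = 19, blurSigmaPx = 0, noiseLevel = 0)
  expect_true(all(imagePixels(img) == 255))
  # a single heparin rod parallel to the plane renders as a dark rod of the
  # mapped length
  tph <- buildHeparin(seed = 62)
  sth <- latticeState(64, tph@positions + 4L, rep("HEP", 90),
                      bonds = cbind(tph@bonds, kind = "intra"))
  img2 <- virtualTEM(sth, slabThicknessNm = 19, blurSigmaPx = 0,
                     noiseLevel = 0, pixelSizeNm = 0.5)
  dark <- imagePixels(img2) < 128
  expect_true(any(dark))
  cols <- range(which(apply(dark, 2, any)))
  lengthNm <- (cols[2] - cols[1] + 1) * 0.5
  expect_lt(abs(lengthNm - 15.6), 2 * 0.5)   # within +-2 px of mapped extent
  # two stacked heparins darken more than one (projection additivity)
  st2 <- latticeState(64, rbind(c(10L, 10L, 4L), c(10L, 10L, 8L)),
                      c("HEP", "HEP"))
  st1 <- latticeState(64, matrix(c(10L, 10L, 4L), 1), "HEP")
  i1 <- virtualTEM(st1, slabThicknessNm = 19, blurSigmaPx = 0,
                   noiseLevel = 0, darkPerMonomer = 60)
  i2 <- virtualTEM(st2, slabThicknessNm = 19, blurSigmaPx = 0,
                   noiseLevel = 0, darkPerMonomer = 60)
  expect_lt(min(imagePixels(i2)), min(imagePixels(i1)))
  # undersampled pixel size errors
  expect_error(virtualTEM(st1, pixelSizeNm = 1.0), "undersampled")
})

test_that("binarization recovers a clean rod mask and handles polarity exactly", {
  img <- matrix(230, 128, 128)
  img[60:67, 20:100] <- 30
  gi <- grayImage(img, 0.5, "planted")
  mask <- binarizePreprocess(gi, gaussSigmaPx = 1)
  truth <- matrix(FALSE, 128, 128); truth[60:67, 20:100] <- TRUE
  # agreement within a 1-px boundary tolerance
  core <- matrix(FALSE, 128, 128); core[61:66, 21:99] <- TRUE
  halo <- matrix(FALSE, 128, 128); halo[59:68, 19:101] <- TRUE
  expect_true(all(mask[core]))
  expect_true(!any(mask & !halo))
  # inverted-contrast input with the polarity flag gives the identical mask
  giInv <- grayImage(255 - img, 0.5, "planted")
  maskInv <- binarizePreprocess(giInv, gaussSigmaPx = 1, polarity = "bright")
  expect_identical(unclass(mask), unclass(maskInv))
  expect_error(binarizePreprocess(grayImage(matrix(7, 16, 16), 1)),
               "constant")
})

test_that("pure-noise images are flagged as weak-contrast, real features are not", {
  set.seed(8)
  noise <- matrix(pmax(0, pmin(255, stats::rnorm(128^2, 128, 12))), 128, 128)
  mask <- binarizePreprocess(grayImage(noise, 1, "planted"))
  expect_true(mean(mask) < 0.05 ||
                identical(attr(mask, "flag"), "weak-contrast"))
  rod <- matrix(230, 128, 128); rod[60:67, 20:100] <- 30
  maskRod <- binarizePreprocess(grayImage(rod, 1, "planted"))
  expect_null(attr(maskRod, "flag"))
})

test_that("branch lengths follow skeleton geometry on constructed masks", {
  expect_equal(branchLengthAnalysis(matrix(FALSE, 32, 32), 1), numeric())
  # one straight horizontal rod: 50 px long, 4 px wide at 0.5 nm/px
  m <- matrix(FALSE, 64, 128)
  m[30:33, 21:70] <- TRUE
  bl <- branchLengthAnalysis(m, 0.5, pruneLenPx = 3)
  expect_equal(length(bl), 1)
  expect_gte(bl, 24 - 2)     # 50 px minus endpoint erosion, in nm
  expect_lte(bl, 25)
  # a "+" of two 51-px rods: 4 branches from one junction, each ~ half-arm
  p <- matrix(FALSE, 101, 101)
  p[49:52, 26:76] <- TRUE
  p[26:76, 49:52] <- TRUE
  blp <- branchLengthAnalysis(p, 1, pruneLenPx = 3)
  expect_equal(length(blp), 4)
  expect_true(all(blp > 15 & blp < 27))
})

test_that("void Feret diameters recover planted discs by rotating calipers", {
  # single centred disc void of radius 20 px at 1 nm/px in a polymer field
  m <- matrix(TRUE, 128, 128)
  ctr <- 64.5
  for (i in 1:128) for (j in 1:128)
    if ((i - ctr)^2 + (j - ctr)^2 <= 20^2) m[i, j] <- FALSE
  fd <- voidFeretAnalysis(m, 1, minDistancePx = 10)
  expect_equal(length(fd), 1)
  expect_lt(abs(fd - 40), 1.5)
  # two well-separated discs, radii 10 and 20
  m2 <- matrix(TRUE, 256, 256)
  for (i in 1:256) for (j in 1:256) {
    if ((i - 60)^2 + (j - 60)^2 <= 10^2) m2[i, j] <- FALSE
    if ((i - 170)^2 + (j - 170)^2 <= 20^2) m2[i, j] <- FALSE
  }
  fd2 <- sort(voidFeretAnalysis(m2, 1, minDistancePx = 8))
  expect_equal(length(fd2), 2)
  expect_lt(abs(fd2[1] - 20), 1.5)
  expect_lt(abs(fd2[2] - 40), 1.5)
  # fully black (all polymer): empty with flag
  fd3 <- voidFeretAnalysis(matrix(TRUE, 32, 32), 1)
  expect_equal(length(fd3), 0)
  expect_equal(attr(fd3, "flag"), "no-void")
})

test_that("border-touching voids are excluded by default but kept on request", {
  m <- matrix(TRUE, 64, 64)
  m[1:20, 1:20] <- FALSE              # corner void touches the border
  fd <- voidFeretAnalysis(m, 1)
  expect_equal(length(fd), 0)
  fdAll <- voidFeretAnalysis(m, 1, excludeBorder = FALSE)
  expect_equal(length(fdAll), 1)
})

test_that("gaussianFit recovers parameters and flags degenerate input", {
  set.seed(33)
  x <- stats::rnorm(1000, 15, 3)
  fit <- gaussianFit(x)
  expect_lt(abs(fit$mean - 15), 0.3)
  expect_lt(abs(fit$sd - 3), 0.5)
  expect_false(fit$poorFit)
  # n < 20 errors
  expect_error(gaussianFit(stats::rnorm(10)), "20 values")
  # identical values: degenerate error carrying the sample mean
  err <- tryCatch(gaussianFit(rep(7, 50)), error = function(e) e)
  expect_s3_class(err, "latticeGelFitError")
  expect_equal(err$sampleMean, 7)
  # well-separated mixture: diagnostics flag a poor fit
  mix <- c(stats::rnorm(600, 10, 1), stats::rnorm(600, 20, 1))
  fitMix <- gaussianFit(mix)
  expect_true(fitMix$poorFit)
})

test_that("planted rods are recovered end to end within the stated tolerance", {
  pr <- plantedRodImage(nRods = 60, lengthMeanNm = 15.5, lengthSdNm = 0.5,
                        pixelSizeNm = 0.5, imagePx = 1024, seed = 71)
  expect_equal(nrow(pr$truth), 60)
  q <- quantifyImage(pr$image)
  expect_gt(length(q@branchLengths), 40)
  # |fit mean - planted length| <= max(1.5 nm, 2 px)
  expect_lt(abs(q@fitBranch[1] - 15.5), max(1.5, 2 * 0.5))
})

test_that("planted voids are recovered within 10% for discs >= 10 px radius", {
  pv <- plantedVoidImage(nVoids = 12, diameterPx = c(24, 30, 40),
                         pixelSizeNm = 1, imagePx = 512, seed = 72)
  # the dark matrix is the polymer phase; voids are the bright background
  q <- quantifyImage(pv$image, polarity = "dark", minDistancePx = 8)
  expect_equal(length(q@feretDiameters), 12)
  got <- sort(q@feretDiameters)
  want <- sort(pv$truth$feretNm)
  expect_true(all(abs(got - want) / want <= 0.10))
})

test_that("nm-valued outputs are equivariant under joint pixel-size rescaling", {
  mkMask <- function(px, scale) {
    m <- matrix(FALSE, px, px)
    m[(40 * scale):(40 * scale + 4 * scale - 1),
      (20 * scale):(80 * scale)] <- TRUE
    m
  }
  bl1 <- branchLengthAnalysis(mkMask(128, 1), 1)
  bl2 <- branchLengthAnalysis(mkMask(256, 2), 0.5)
  expect_lt(abs(bl1 - bl2) / bl1, 0.02)
})
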