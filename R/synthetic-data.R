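# seeded ground-truthed generators: planted-rod and planted-void
# micrographs, analytic scattering curves, miniature network fixtures

# draw a dark capsule (segment with round caps) into an intensity matrix;
# lengthPx is the backbone (centerline) length - the skeleton estimand -
# and the stroke width renders as a stain/blur halo around it, so the dark
# feature extends ~widthPx/2 beyond each backbone end
.paintCapsule <- function(img, cx, cy, angle, lengthPx, widthPx, value) {
  half <- max(0, lengthPx / 2)
  ex <- half * cos(angle); ey <- half * sin(angle)
  x1 <- cx - ex; y1 <- cy - ey; x2 <- cx + ex; y2 <- cy + ey
  r <- widthPx / 2
  i0 <- max(1, floor(min(y1, y2) - r)); i1 <- min(nrow(img), ceiling(max(y1, y2) + r))
  j0 <- max(1, floor(min(x1, x2) - r)); j1 <- min(ncol(img), ceiling(max(x1, x2) + r))
  if (i0 > i1 || j0 > j1) return(list(img = img, hits = cbind(integer(), integer())))
  ii <- i0:i1; jj <- j0:j1
  X <- matrix(rep(jj, each = length(ii)), length(ii))
  Y <- matrix(rep(ii, length(jj)), length(ii))
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- if (len2 > 0) pmax(0, pmin(1, ((X - x1) * dx + (Y - y1) * dy) / len2)) else 0
  d2 <- (X - (x1 + t * dx))^2 + (Y - (y1 + t * dy))^2
  hit <- d2 <= r^2
  img[cbind(Y[hit], X[hit])] <- value
  list(img = img, hits = cbind(Y[hit], X[hit]))
}

#' Planted-rod micrograph with ground truth
#'
#' Dark rods (emulating uranyl-acetate-stained heparin) at uniform random
#' positions and orientations on a bright background, with Gaussian blur and
#' shot noise. The planted length is the rod backbone (centerline) length -
#' the quantity the skeleton pipeline estimates; the stroke width renders as
#' a stain halo around the backbone, as in stained micrographs. The truth
#' table carries each rod's center, angle and backbone length, sufficient to
#' score the branch-length pipeline without re-reading the image.
#'
#' @param nRods number of rods.
#' @param lengthMeanNm,lengthSdNm Gaussian length distribution (nm).
#' @param pixelSizeNm nm per pixel (default 0.5).
#' @param imagePx image edge in px (default 2048).
#' @param widthPx rod width in px (default 4).
#' @param blurSigmaPx Gaussian blur sigma (default 1).
#' @param noiseLevel shot-noise scale as in [virtualTEM()] (default 2).
#' @param allowOverlap permit rod overlaps (default FALSE).
#' @param seed integer seed.
#' @return list with \code{image} ([GrayImage-class]) and \code{truth}
#'   (data.frame cx, cy, angle, lengthNm).
#' @export
plantedRodImage <- function(nRods = 200, lengthMeanNm = 15.5,
                            lengthSdNm = 0.5, pixelSizeNm = 0.5,
                            imagePx = 2048, widthPx = 4, blurSigmaPx = 1,
                            noiseLevel = 2, allowOverlap = FALSE,
                            seed = 1L) {
  .withSeed(seed, {
    img <- matrix(220, imagePx, imagePx)
    painted <- matrix(FALSE, imagePx, imagePx)
    truth <- data.frame(cx = numeric(), cy = numeric(), angle = numeric(),
                        lengthNm = numeric())
    margin <- (lengthMeanNm + 4 * lengthSdNm) / pixelSizeNm / 2 + widthPx
    maxTries <- 300L
    for (k in seq_len(nRods)) {
      placed <- FALSE
      for (t in seq_len(maxTries)) {
        len <- max(widthPx * pixelSizeNm,
                   stats::rnorm(1, lengthMeanNm, lengthSdNm))
        ang <- stats::runif(1, 0, pi)
        cx <- stats::runif(1, margin, imagePx - margin)
        cy <- stats::runif(1, margin, imagePx - margin)
        trial <- .paintCapsule(img, cx, cy, ang, len / pixelSizeNm,
                               widthPx, 40)
        if (!allowOverlap && nrow(trial$hits) > 0) {
          # demand a 2-px clearance to keep rods separable
          ii <- trial$hits[, 1]; jj <- trial$hits[, 2]
          clear <- TRUE
          for (di in -2:2) for (dj in -2:2) {
            i2 <- pmin(pmax(ii + di, 1), imagePx)
            j2 <- pmin(pmax(jj + dj, 1), imagePx)
            if (any(painted[cbind(i2, j2)])) { clear <- FALSE; break }
          }
          if (!clear) next
        }
        img <- trial$img
        painted[trial$hits] <- TRUE
        truth <- rbind(truth, data.frame(cx = cx, cy = cy, angle = ang,
                                         lengthNm = len))
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf(
          "rod placement failed at rod %d of %d; reduce the density (achieved %.1f%% coverage)",
          k, nRods, 100 * mean(painted)))
    }
    if (blurSigmaPx > 0)
      img <- matrix(as.numeric(EBImage::gblur(img, sigma = blurSigmaPx)),
                    nrow(img))
    if (noiseLevel > 0)
      img <- matrix(stats::rpois(length(img), pmax(img, 0) / noiseLevel),
                    nrow(img)) * noiseLevel
    img[img < 0] <- 0; img[img > 255] <- 255
    list(image = grayImage(img, pixelSizeNm, "planted"), truth = truth)
  })
}

#' Planted-void micrograph with ground truth
#'
#' Bright elliptical voids in a dark textured matrix (the inverse contrast
#' of the planted rods: here the polymer-rich matrix is dark). The truth
#' table lists each void's maximum Feret diameter in nm (the major axis).
#'
#' @param nVoids number of voids.
#' @param diameterPx numeric vector of major-axis diameters in px, recycled
#'   to \code{nVoids}, or a function \code{function(n)} drawing them.
#' @param axisRatio minor/major axis ratio (default 1 = discs).
#' @param pixelSizeNm nm per pixel (default 1).
#' @param imagePx image edge (default 512).
#' @param matrixMean,matrixSd background texture intensity (default 60, 8).
#' @param seed integer seed.
#' @return list with \code{image} ([GrayImage-class]) and \code{truth}
#'   (data.frame cx, cy, feretNm).
#' @export
plantedVoidImage <- function(nVoids = 10, diameterPx = 40, axisRatio = 1,
                             pixelSizeNm = 1, imagePx = 512,
                             matrixMean = 60, matrixSd = 8, seed = 1L) {
  .withSeed(seed, {
    d <- if (is.function(diameterPx)) diameterPx(nVoids)
         else rep(diameterPx, length.out = nVoids)
    img <- matrix(pmax(0, pmin(255, stats::rnorm(imagePx^2, matrixMean, matrixSd))),
                  imagePx, imagePx)
    occ <- matrix(FALSE, imagePx, imagePx)
    truth <- data.frame(cx = numeric(), cy = numeric(), feretNm = numeric())
    for (k in seq_len(nVoids)) {
      a <- d[k] / 2; b <- a * axisRatio
      placed <- FALSE
      for (t in 1:300) {
        cx <- stats::runif(1, a + 2, imagePx - a - 2)
        cy <- stats::runif(1, a + 2, imagePx - a - 2)
        ii <- max(1, floor(cy - a)):min(imagePx, ceiling(cy + a))
        jj <- max(1, floor(cx - a)):min(imagePx, ceiling(cx + a))
        X <- matrix(rep(jj, each = length(ii)), length(ii))
        Y <- matrix(rep(ii, length(jj)), length(ii))
        # pixel centers within the ellipse; half-pixel shrink so the pixel
        # extent matches the nominal diameter
        hit <- ((X - cx) / (a - 0.5))^2 + ((Y - cy) / (b - 0.5))^2 <= 1
        idx <- cbind(Y[hit], X[hit])
        pad <- 3L
        ii2 <- max(1, min(ii) - pad):min(imagePx, max(ii) + pad)
        jj2 <- max(1, min(jj) - pad):min(imagePx, max(jj) + pad)
        if (any(occ[ii2, jj2])) next
        img[idx] <- 230
        occ[idx] <- TRUE
        truth <- rbind(truth, data.frame(cx = cx, cy = cy,
                                         feretNm = d[k] * pixelSizeNm))
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf("void placement failed at void %d of %d; reduce density",
                     k, nVoids))
    }
    list(image = grayImage(img, pixelSizeNm, "planted"), truth = truth)
  })
}

#' Synthetic analytic scattering curves with ground truth
#'
#' @param kind "power_law" (params: \code{slope}, \code{amplitude}), "rod"
#'   (params: \code{L}, \code{amplitude}) or "peak_background" (params:
#'   \code{qPeak}, \code{peakHeight}, \code{peakWidth}, \code{bgAmplitude},
#'   \code{bgSlope}).
#' @param params named list, see \code{kind}.
#' @param qGrid positive q grid (1/nm).
#' @param noise multiplicative log-normal noise sd (0 = none).
#' @param seed integer seed.
#' @return list with \code{profile} ([ScatteringProfile-class]) and
#'   \code{truth} (named list echoing the generating parameters, including
#'   \code{dSpacing} for the peak kind).
#' @export
syntheticScattering <- function(kind = c("power_law", "rod", "peak_background"),
                                params = list(), qGrid, noise = 0,
                                seed = 1L) {
  kind <- match.arg(kind)
  q <- as.numeric(qGrid)
  I <- switch(kind,
    power_law = {
      a <- params$amplitude %||% 1
      a * q^(params$slope %||% -1)
    },
    rod = {
      a <- params$amplitude %||% 1
      a * rodFormFactor(q, params$L %||% 15)
    },
    peak_background = {
      a <- params$bgAmplitude %||% 1
      m <- params$bgSlope %||% -2
      h <- params$peakHeight %||% 5
      w <- params$peakWidth %||% 0.5
      q0 <- params$qPeak %||% 14.2
      a * q^m + h * exp(-(q - q0)^2 / (2 * w^2))
    })
  if (noise > 0)
    I <- I * exp(.withSeed(seed, stats::rnorm(length(q), 0, noise)))
  truth <- params
  if (kind == "peak_background")
    truth$dSpacing <- 2 * pi / (params$qPeak %||% 14.2)
  list(profile = scatteringProfile(q, I, label = kind), truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run a small crosslinking simulation with fixed molecule counts; used by
# the network fixtures
.miniGelRun <- function(nPEG, nHEP, bondsTarget, hepReactive = 28L,
                        boxEdge = 56L, seed = 1L, maxMCS = 2e5) {
  st <- .assembleCounts(nPEG, nHEP, boxEdge, equilibrationMCS = 100,
                        seed = seed, armLength = 29L,
                        hepReactive = hepReactive)
  pTarget <- bondsTarget / (4 * nPEG)
  res <- suppressWarnings(
    crosslinkUntil(st, pTarget = pTarget, maxMCS = maxMCS, seed = seed + 13L))
  res$state
}

#' Miniature network fixtures with known metrics
#'
#' Small crosslinked systems whose molecule graphs realise hand-computable
#' topologies, generated by the real assembly/crosslinking machinery under
#' deterministic seed scans:
#' \describe{
#'   \item{tree}{1 starPEG + 2 single-site heparins, 2 bonds: cycle rank 0.}
#'   \item{single_cycle}{2 starPEG + 2 two-site heparins, all four sites
#'     consumed and connected: cycle rank exactly 1, gamma_BMC 1, f_HEP 2.}
#'   \item{multi_edge_pair}{1 starPEG double-bonded to 1 heparin: one
#'     multi-edge, 2 dangling arms, f_HEP 2.}
#'   \item{two_components}{1 starPEG bonded to one of 2 heparins: component
#'     sizes 2 and 1.}
#'   \item{mini_gel}{4 starPEG + 3 heparins with 12 bonds, connected:
#'     cycle rank 12 - 7 + 1 = 6.}
#' }
#'
#' @param preset fixture name.
#' @param seed base seed for the deterministic scan.
#' @return list with \code{state} ([LatticeState-class]), \code{graph}
#'   (molecule multigraph) and \code{expected} (named list of known metric
#'   values).
#' @export
fixtureNetwork <- function(preset = c("tree", "single_cycle",
                                      "multi_edge_pair", "two_components",
                                      "mini_gel"),
                           seed = 1L) {
  preset <- match.arg(preset)
  scan <- function(build, accept, tries = 40L) {
    for (k in seq_len(tries)) {
      st <- tryCatch(build(seed * 1000L + k), error = function(e) NULL)
      if (is.null(st)) next
      g <- moleculeGraph(st)
      if (accept(g)) return(list(state = st, graph = g))
    }
    stop("fixture generation failed for preset after deterministic seed scan")
  }
  if (preset == "tree") {
    fx <- scan(function(s) .miniGelRun(1, 2, 2, hepReactive = 1L, seed = s),
               function(g) igraph::ecount(g) == 2 &&
                 max(igraph::degree(g)) <= 2 &&
                 igraph::components(g)$no == 1)
    expected <- list(cycleRank = 0L, edges = 2L)
  } else if (preset == "single_cycle") {
    # two 2-site heparins fully consumed by two stars: any connected outcome
    # has E = 4, V = 4, hence cycle rank exactly 1, gamma_BMC 1, f_HEP 2
    fx <- scan(function(s) .miniGelRun(2, 2, 4, hepReactive = 2L, seed = s),
               function(g) igraph::ecount(g) == 4 &&
                 igraph::components(g)$no == 1)
    expected <- list(cycleRank = 1L, gammaBMC = 1, fHepBMC = 2, edges = 4L)
  } else if (preset == "multi_edge_pair") {
    fx <- scan(function(s) .miniGelRun(1, 1, 2, seed = s),
               function(g) igraph::ecount(g) == 2)
    expected <- list(multiEdges = 1L, danglingPegArms = 2L, fHepBMC = 2)
  } else if (preset == "two_components") {
    fx <- scan(function(s) .miniGelRun(1, 2, 1, seed = s),
               function(g) igraph::ecount(g) == 1)
    expected <- list(componentSizes = c(2L, 1L))
  } else {
    fx <- scan(function(s) .miniGelRun(4, 3, 12, seed = s,
                                       boxEdge = 64L, maxMCS = 2e5),
               function(g) igraph::ecount(g) == 12 &&
                 igraph::components(g)$no == 1)
    expected <- list(cycleRank = 6L, edges = 12L, vertices = 7L)
  }
  c(fx, list(expected = expected))
}
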