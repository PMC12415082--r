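# virtual TEM projection and the automated micrograph quantification chain
# (reimplementation of the ImageJ-macro analysis: contrast enhancement,
# Gaussian filter, binarization, skeleton branch lengths, distance-map /
# local-maxima void segmentation with Feret diameters)

#' Construct a GrayImage
#'
#' @param pixels numeric matrix of intensities in \code{[0, 255]}.
#' @param pixelSize nm per pixel.
#' @param provenance one of "virtual_tem", "planted", "external".
#' @return a [GrayImage-class].
#' @export
grayImage <- function(pixels, pixelSize, provenance = "external") {
  new("GrayImage", pixels = pixels, pixelSize = pixelSize,
      provenance = provenance)
}

#' Virtual TEM projection of a simulation snapshot
#'
#' Emulates the uranyl-acetate contrast of the micrographs: heparin monomers
#' inside a thin slab (default 70 nm, the section thickness) are projected
#' onto the image plane and rendered dark with occupancy-proportional
#' darkening, while starPEG and empty space stay bright (PEG is unstained).
#' Gaussian blur and Poisson-type shot noise complete the forward model.
#'
#' @param state a [LatticeState-class] snapshot.
#' @param slabOrigin z origin of the slab in lattice units (default 0).
#' @param slabThicknessNm slab thickness in nm (default 70).
#' @param pixelSizeNm nm per pixel (default 0.5); must not exceed the 0.6 nm
#'   monomer footprint.
#' @param blurSigmaPx Gaussian blur sigma in px (default 1).
#' @param noiseLevel shot-noise scale: intensities are resampled as
#'   \code{rpois(I / noiseLevel) * noiseLevel}; 0 disables noise.
#' @param seed integer seed for the noise.
#' @param darkPerMonomer intensity removed per projected heparin monomer
#'   (default 80).
#' @return a [GrayImage-class] with provenance "virtual_tem".
#' @export
virtualTEM <- function(state, slabOrigin = 0L, slabThicknessNm = 70,
                       pixelSizeNm = 0.5, blurSigmaPx = 1, noiseLevel = 0,
                       seed = 1L, darkPerMonomer = 80) {
  if (pixelSizeNm > 2 * .NM_PER_LATTICE)
    stop("pixel size exceeds the monomer footprint (0.6 nm); image would be undersampled")
  L <- boxEdge(state)
  thick <- round(mapLength(slabThicknessNm))
  if (thick > L) stop("slab does not fit in the box")
  npx <- floor(latticeToNm(L) / pixelSizeNm)
  counts <- matrix(0, npx, npx)
  hep <- which(state@species == "HEP")
  pos <- state@positions
  inSlab <- hep[((pos[hep, 3] - slabOrigin) %% L) < thick]
  for (m in inSlab) {
    # cube footprint [x, x+2) lattice units on each image axis
    x0 <- latticeToNm(pos[m, 1]); y0 <- latticeToNm(pos[m, 2])
    cx <- (floor(x0 / pixelSizeNm):floor((x0 + 0.6 - 1e-9) / pixelSizeNm)) %% npx + 1
    cy <- (floor(y0 / pixelSizeNm):floor((y0 + 0.6 - 1e-9) / pixelSizeNm)) %% npx + 1
    counts[cy, cx] <- counts[cy, cx] + 1
  }
  img <- .clampMat(255 - darkPerMonomer * counts, 0, 255)
  if (blurSigmaPx > 0)
    img <- .asMat(EBImage::gblur(img, sigma = blurSigmaPx), nrow(img))
  if (noiseLevel > 0) {
    img <- .withSeed(seed, matrix(
      stats::rpois(length(img), .clampMat(img, 0, Inf) / noiseLevel),
      nrow(img)) * noiseLevel)
  }
  grayImage(.clampMat(img, 0, 255), pixelSizeNm, "virtual_tem")
}

#' Contrast enhancement, smoothing and binarization
#'
#' Contrast stretch, Gaussian filter, and a global (Otsu) threshold; the
#' foreground of the returned mask is the dark (stained heparin) phase.
#' Inputs whose features are bright instead are handled by the
#' \code{polarity} flag (integer-exact inversion first, then the identical
#' pipeline). The default stretch is a non-saturating min-max
#' normalization: Otsu is affine-invariant, and a saturating percentile
#' stretch clips sparse features while amplifying background noise, which
#' can flip the threshold into the background class on images whose
#' features cover well under 1 percent of the pixels. Saturating stretches
#' remain available through \code{contrastPercentiles}.
#'
#' @param image a [GrayImage-class].
#' @param gaussSigmaPx Gaussian smoothing sigma (px), default 1.
#' @param contrastPercentiles two percentiles (fractions) for the stretch,
#'   default c(0, 1) (min-max).
#' @param thresholdMethod currently "otsu".
#' @param polarity "dark" (default) when features are dark on bright,
#'   "bright" otherwise.
#' @return logical matrix mask (TRUE = feature) with attribute
#'   \code{threshold}.
#' @export
binarizePreprocess <- function(image, gaussSigmaPx = 1,
                               contrastPercentiles = c(0, 1),
                               thresholdMethod = c("otsu"),
                               polarity = c("dark", "bright")) {
  thresholdMethod <- match.arg(thresholdMethod)
  polarity <- match.arg(polarity)
  px <- imagePixels(image)
  if (polarity == "bright") px <- 255 - px
  if (diff(range(px)) == 0)
    stop("constant image cannot be thresholded")
  x <- px / 255
  qs <- stats::quantile(x, contrastPercentiles, names = FALSE)
  if (qs[2] > qs[1]) x <- .clampMat((x - qs[1]) / (qs[2] - qs[1]), 0, 1)
  if (gaussSigmaPx > 0)
    x <- .asMat(EBImage::gblur(x, sigma = gaussSigmaPx), nrow(x))
  x <- .clampMat(x, 0, 1)
  thr <- EBImage::otsu(x, range = c(0, 1))
  mask <- x < thr
  attr(mask, "threshold") <- thr
  # separation quality: Otsu's between-class over total variance; a pure
  # noise field peaks near 0.64, well-contrasted features approach 1
  w1 <- mean(mask)
  if (w1 > 0 && w1 < 1) {
    mu1 <- mean(x[mask]); mu2 <- mean(x[!mask])
    ratio <- w1 * (1 - w1) * (mu1 - mu2)^2 / stats::var(as.numeric(x))
    attr(mask, "separation") <- ratio
    if (ratio < 0.75) attr(mask, "flag") <- "weak-contrast"
  }
  mask
}

# clamp while preserving matrix structure (pmin/pmax would drop dims)
.clampMat <- function(x, lo, hi) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

# EBImage returns Image objects; keep plain matrices internally
.asMat <- function(x, nr) matrix(as.numeric(x), nr)

# along-path length of 8-connected steps
.stepLen <- function(di, dj) ifelse(di != 0 & dj != 0, sqrt(2), 1)

# decompose a 1-px skeleton into branches between endpoints/junctions;
# adjacent junction pixels are merged into one junction cluster (the ImageJ
# skeleton-analysis convention); returns path lengths in px
.traceBranches <- function(S) {
  nr <- nrow(S); nc <- ncol(S)
  P <- matrix(FALSE, nr + 2, nc + 2)
  P[2:(nr + 1), 2:(nc + 1)] <- S != 0
  offs <- cbind(di = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dj = c(-1, 0, 1, -1, 1, -1, 0, 1))
  # crossing number (Hilditch): 0->1 transitions around the neighbor ring.
  # Robust to thinning staircase artifacts, where the raw neighbor count
  # misclassifies path pixels as junctions: C=1 tip, C=2 path, C>=3 junction
  ring <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  core <- function(o) P[2:(nr + 1) + o[1], 2:(nc + 1) + o[2]]
  C <- matrix(0L, nr + 2, nc + 2)
  cc <- matrix(0L, nr, nc)
  for (k in 1:8)
    cc <- cc + (!core(ring[[k]]) & core(ring[[if (k == 8) 1 else k + 1]]))
  C[2:(nr + 1), 2:(nc + 1)] <- cc
  isNode <- P & (C != 2L)
  nbrOf <- function(i, j) {
    ii <- i + offs[, 1]; jj <- j + offs[, 2]
    on <- P[cbind(ii, jj)]
    cbind(ii, jj)[on, , drop = FALSE]
  }
  # label 8-connected clusters of node pixels
  cluster <- matrix(0L, nr + 2, nc + 2)
  nodeIdx <- which(isNode)
  ncl <- 0L
  for (p in nodeIdx) {
    if (cluster[p] != 0L) next
    ncl <- ncl + 1L
    stack <- p
    while (length(stack)) {
      q <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (cluster[q] != 0L) next
      cluster[q] <- ncl
      qi <- (q - 1) %% (nr + 2) + 1; qj <- (q - 1) %/% (nr + 2) + 1
      nb <- nbrOf(qi, qj)
      for (m in seq_len(nrow(nb)))
        if (isNode[nb[m, 1], nb[m, 2]] &&
            cluster[nb[m, 1], nb[m, 2]] == 0L)
          stack <- c(stack, (nb[m, 2] - 1) * (nr + 2) + nb[m, 1])
    }
  }
  # a cluster is an endpoint if it holds any free tip (crossing number <= 1)
  clusterHasTip <- logical(ncl)
  for (p in nodeIdx)
    if (C[p] <= 1L) clusterHasTip[cluster[p]] <- TRUE
  visited <- matrix(FALSE, nr + 2, nc + 2)
  lengths <- numeric()
  kinds <- character()
  for (p in nodeIdx) {
    i <- (p - 1) %% (nr + 2) + 1; j <- (p - 1) %/% (nr + 2) + 1
    nb <- nbrOf(i, j)
    for (q in seq_len(nrow(nb))) {
      qi <- nb[q, 1]; qj <- nb[q, 2]
      if (isNode[qi, qj]) next          # intra/inter-cluster contact, no path
      if (visited[qi, qj]) next
      len <- .stepLen(qi - i, qj - j)
      pi <- i; pj <- j; ci <- qi; cj <- qj
      endsAtTip <- FALSE
      repeat {
        visited[ci, cj] <- TRUE
        nb2 <- nbrOf(ci, cj)
        nxt <- nb2[!(nb2[, 1] == pi & nb2[, 2] == pj), , drop = FALSE]
        # prefer a node ending; otherwise continue along unvisited path pixels
        if (nrow(nxt) == 0) { endsAtTip <- TRUE; break }
        nodeHit <- which(isNode[cbind(nxt[, 1], nxt[, 2])])
        if (length(nodeHit)) {
          ni <- nxt[nodeHit[1], 1]; nj <- nxt[nodeHit[1], 2]
          len <- len + .stepLen(ni - ci, nj - cj)
          ci <- ni; cj <- nj
          break
        }
        open <- which(!visited[cbind(nxt[, 1], nxt[, 2])])
        if (length(open) == 0) { endsAtTip <- TRUE; break }
        # prefer orthogonal steps so staircase corners are not skipped
        ortho <- open[(nxt[open, 1] == ci) | (nxt[open, 2] == cj)]
        pickN <- if (length(ortho)) ortho[1] else open[1]
        ni <- nxt[pickN, 1]; nj <- nxt[pickN, 2]
        len <- len + .stepLen(ni - ci, nj - cj)
        pi <- ci; pj <- cj; ci <- ni; cj <- nj
      }
      startCl <- cluster[i, j]
      endCl <- if (!endsAtTip) cluster[ci, cj] else 0L
      free <- clusterHasTip[startCl] || endsAtTip ||
        (endCl > 0L && clusterHasTip[endCl])
      lengths <- c(lengths, len)
      kinds <- c(kinds, if (free) "spur" else "bridge")
    }
  }
  # isolated cycles: leftover unvisited path pixels
  left <- which(P & !visited & !isNode)
  for (p in left) {
    i <- (p - 1) %% (nr + 2) + 1; j <- (p - 1) %/% (nr + 2) + 1
    if (visited[i, j]) next
    visited[i, j] <- TRUE
    len <- 0
    pi <- NA; pj <- NA; ci <- i; cj <- j
    repeat {
      nb2 <- nbrOf(ci, cj)
      if (!is.na(pi))
        nb2 <- nb2[!(nb2[, 1] == pi & nb2[, 2] == pj), , drop = FALSE]
      nb2 <- nb2[!visited[cbind(nb2[, 1], nb2[, 2])] |
                   (nb2[, 1] == i & nb2[, 2] == j), , drop = FALSE]
      if (nrow(nb2) == 0) break
      ni <- nb2[1, 1]; nj <- nb2[1, 2]
      len <- len + .stepLen(ni - ci, nj - cj)
      if (ni == i && nj == j) break
      visited[ni, nj] <- TRUE
      pi <- ci; pj <- cj; ci <- ni; cj <- nj
    }
    if (len > 0) { lengths <- c(lengths, len); kinds <- c(kinds, "cycle") }
  }
  data.frame(lengthPx = lengths, kind = kinds)
}

#' Skeleton branch lengths of a binary mask
#'
#' Morphological (Zhang-Suen) skeletonization followed by decomposition of
#' the skeleton into branches connecting endpoints and junctions. Branch
#' length is the along-path length with sqrt(2)-weighted diagonal steps,
#' converted to nm. Spurs (branches with a free end) shorter than the prune
#' length are discarded.
#'
#' @param binary logical matrix (TRUE = feature).
#' @param pixelSize nm per pixel.
#' @param pruneLenPx prune length in px (default 3).
#' @return numeric vector of branch lengths in nm (empty for an empty
#'   mask).
#' @export
branchLengthAnalysis <- function(binary, pixelSize, pruneLenPx = 3) {
  if (!any(binary)) return(numeric())
  skel <- .skeletonize_cpp(matrix(as.integer(binary), nrow(binary)))
  br <- .traceBranches(skel)
  keep <- !(br$kind == "spur" & br$lengthPx < pruneLenPx)
  br$lengthPx[keep] * pixelSize
}

# maximum caliper (Feret) diameter of a pixel region, measured over the
# convex hull of the pixel corner points (ImageJ convention)
.feretPx <- function(ij) {
  pts <- rbind(cbind(ij[, 1] - 0.5, ij[, 2] - 0.5),
               cbind(ij[, 1] - 0.5, ij[, 2] + 0.5),
               cbind(ij[, 1] + 0.5, ij[, 2] - 0.5),
               cbind(ij[, 1] + 0.5, ij[, 2] + 0.5))
  h <- grDevices::chull(pts)
  max(stats::dist(pts[h, , drop = FALSE]))
}

#' Void sizes as maximum Feret diameters
#'
#' The mask is inverted (voids = non-polymer), a Euclidean distance
#' transform is computed, its local maxima (with a minimum separation) seed
#' a marker-based segmentation of the void space, and each void region is
#' measured by its maximum caliper (Feret) diameter. Regions touching the
#' image border are excluded by default.
#'
#' @param binary logical matrix, TRUE = polymer (foreground).
#' @param pixelSize nm per pixel.
#' @param minDistancePx minimum separation of the seeding maxima (default
#'   10).
#' @param excludeBorder drop border-touching voids (default TRUE).
#' @return numeric vector of Feret diameters in nm; empty with attribute
#'   \code{flag = "no-void"} for a fully-foreground mask.
#' @export
voidFeretAnalysis <- function(binary, pixelSize, minDistancePx = 10,
                              excludeBorder = TRUE) {
  inv <- !binary
  if (!any(inv)) {
    out <- numeric()
    attr(out, "flag") <- "no-void"
    return(out)
  }
  edt <- EBImage::distmap(matrix(as.numeric(inv), nrow(inv)))
  edt <- matrix(as.numeric(edt), nrow(inv))
  # local maxima under a (2r+1) square max filter
  r <- max(1L, as.integer(minDistancePx) %/% 2L)
  mx <- .maxFilter(edt, r)
  cand <- which(edt > 0 & edt >= mx - 1e-9)
  ord <- cand[order(edt[cand], decreasing = TRUE)]
  ci <- (ord - 1) %% nrow(edt) + 1; cj <- (ord - 1) %/% nrow(edt) + 1
  keep <- logical(length(ord))
  ki <- numeric(0); kj <- numeric(0)
  for (k in seq_along(ord)) {
    if (length(ki) == 0 ||
        min((ki - ci[k])^2 + (kj - cj[k])^2) >= minDistancePx^2) {
      keep[k] <- TRUE
      ki <- c(ki, ci[k]); kj <- c(kj, cj[k])
    }
  }
  seeds <- matrix(0L, nrow(edt), ncol(edt))
  seeds[cbind(ci[keep], cj[keep])] <- seq_len(sum(keep))
  lab <- EBImage::propagate(edt, seeds, mask = inv)
  lab <- matrix(as.integer(lab), nrow(edt))
  out <- numeric()
  for (k in seq_len(max(lab))) {
    px <- which(lab == k)
    if (length(px) == 0) next
    i <- (px - 1) %% nrow(lab) + 1; j <- (px - 1) %/% nrow(lab) + 1
    if (excludeBorder &&
        (min(i) == 1 || min(j) == 1 || max(i) == nrow(lab) || max(j) == ncol(lab)))
      next
    # boundary pixels suffice for the hull
    bnd <- .regionBoundary(lab, k, i, j)
    out <- c(out, .feretPx(bnd) * pixelSize)
  }
  out
}

# square max filter of radius r (via EBImage dilation with a box brush)
.maxFilter <- function(x, r) {
  k <- 2L * r + 1L
  br <- matrix(1, k, k)
  d <- EBImage::dilate(x, br)
  matrix(as.numeric(d), nrow(x))
}

.regionBoundary <- function(lab, k, i, j) {
  nr <- nrow(lab); nc <- ncol(lab)
  inside <- rep(TRUE, length(i))
  for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    ii <- i + o[1]; jj <- j + o[2]
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    v <- rep(FALSE, length(i))
    v[ok] <- lab[cbind(ii[ok], jj[ok])] == k
    inside <- inside & v
  }
  cbind(i, j)[!inside, , drop = FALSE]
}

#' Least-squares Gaussian fit to a histogram
#'
#' Bins the values, fits a Gaussian a*exp(-(x-mu)^2/(2 sd^2)) to the bin
#' counts by nonlinear least squares, and reports the fitted mean and sd
#' together with fit diagnostics (reduced chi-square against Poisson
#' counting errors; \code{poorFit} flags clearly non-Gaussian samples such
#' as well-separated mixtures).
#'
#' @param values numeric vector (>= 20 values).
#' @param bins histogram bin count passed to \code{hist} (default 30).
#' @return list with \code{mean}, \code{sd}, \code{amplitude},
#'   \code{redChisq}, \code{poorFit}, \code{n}.
#' @export
gaussianFit <- function(values, bins = 30) {
  if (length(values) < 20)
    stop(errorCondition(
      sprintf("need at least 20 values for a Gaussian fit (got %d)", length(values)),
      sampleMean = if (length(values)) mean(values) else NA_real_,
      class = c("latticeGelFitError", "error", "condition")))
  if (stats::sd(values) == 0)
    stop(errorCondition(
      "degenerate sample (zero spread); Gaussian fit impossible",
      sampleMean = mean(values),
      class = c("latticeGelFitError", "error", "condition")))
  h <- graphics::hist(values, breaks = bins, plot = FALSE)
  x <- h$mids; y <- h$counts
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * s^2)),
                      start = list(a = max(y), mu = mean(values),
                                   s = stats::sd(values)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    stop(errorCondition(
      "Gaussian fit did not converge",
      sampleMean = mean(values),
      class = c("latticeGelFitError", "error", "condition")))
  cf <- stats::coef(fit)
  pred <- stats::predict(fit)
  redChisq <- sum((y - pred)^2 / pmax(pred, 1)) / max(length(y) - 3, 1)
  list(mean = unname(cf["mu"]), sd = abs(unname(cf["s"])),
       amplitude = unname(cf["a"]), redChisq = redChisq,
       poorFit = redChisq > 3, n = length(values))
}

#' Full micrograph quantification
#'
#' Convenience wrapper running the complete quantification chain on one
#' image: binarize, skeleton branch lengths, void Feret diameters, and
#' Gaussian fits of both distributions.
#'
#' @param image a [GrayImage-class].
#' @param gaussSigmaPx,contrastPercentiles,polarity passed to
#'   [binarizePreprocess()].
#' @param pruneLenPx passed to [branchLengthAnalysis()].
#' @param minDistancePx,excludeBorder passed to [voidFeretAnalysis()].
#' @param bins histogram bins for the fits.
#' @return a [QuantResult-class].
#' @export
quantifyImage <- function(image, gaussSigmaPx = 1,
                          contrastPercentiles = c(0, 1),
                          polarity = "dark", pruneLenPx = 3,
                          minDistancePx = 10, excludeBorder = TRUE,
                          bins = 30) {
  mask <- binarizePreprocess(image, gaussSigmaPx, contrastPercentiles,
                             polarity = polarity)
  bl <- branchLengthAnalysis(mask, pixelSize(image), pruneLenPx)
  fd <- voidFeretAnalysis(mask, pixelSize(image), minDistancePx,
                          excludeBorder)
  fitB <- tryCatch(gaussianFit(bl, bins), error = function(e) NULL)
  fitF <- tryCatch(gaussianFit(fd, bins), error = function(e) NULL)
  new("QuantResult",
      branchLengths = bl, feretDiameters = as.numeric(fd),
      fitBranch = if (is.null(fitB)) c(NA_real_, NA_real_)
                  else c(fitB$mean, fitB$sd),
      fitFeret = if (is.null(fitF)) c(NA_real_, NA_real_)
                 else c(fitF$mean, fitF$sd),
      settings = list(gaussSigmaPx = gaussSigmaPx,
                      contrastPercentiles = contrastPercentiles,
                      polarity = polarity, pruneLenPx = pruneLenPx,
                      minDistancePx = minDistancePx,
                      excludeBorder = excludeBorder, bins = bins,
                      pixelSize = pixelSize(image)))
}
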