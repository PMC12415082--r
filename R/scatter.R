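# scattering observables: Debye profiles from coordinates, the thin-rod
# form factor, power-law slopes, and peak positions / d-spacings

#' Construct a ScatteringProfile
#'
#' @param q scattering vector grid (1/nm), strictly increasing, positive.
#' @param intensity non-negative intensities (a.u.).
#' @param label free-text label.
#' @return a [ScatteringProfile-class].
#' @export
scatteringProfile <- function(q, intensity, label = "") {
  new("ScatteringProfile", q = as.numeric(q), intensity = as.numeric(intensity),
      label = label)
}

#' Orientation-averaged Debye intensity profile
#'
#' I(q) = sum_ij w_i w_j sin(q r_ij) / (q r_ij) over a seeded subsample of
#' at most \code{nSubsample} points; the exact isotropic average for a
#' rigid arrangement of point scatterers.
#'
#' @param positions numeric n x 3 matrix of coordinates in nm.
#' @param weights scattering weights per point (default 1).
#' @param qGrid positive q grid (1/nm).
#' @param nSubsample cap on the number of points entering the O(n^2) sum
#'   (default 2000).
#' @param seed integer seed for the subsample.
#' @return a [ScatteringProfile-class].
#' @export
intensityProfile <- function(positions, weights = rep(1, nrow(positions)),
                             qGrid, nSubsample = 2000, seed = 1L) {
  positions <- as.matrix(positions)
  weights <- as.numeric(weights)   # force before any subsetting
  if (nrow(positions) < 1) stop("need at least one position")
  if (length(weights) != nrow(positions))
    stop("weights must match the number of positions")
  if (any(qGrid <= 0)) stop("q grid must be positive")
  if (nrow(positions) > nSubsample) {
    pick <- .withSeed(seed, sample(nrow(positions), nSubsample))
    positions <- positions[pick, , drop = FALSE]
    weights <- weights[pick]
  }
  I <- .debye_cpp(positions, as.numeric(weights), as.numeric(qGrid))
  scatteringProfile(qGrid, I, label = sprintf("debye n=%d", nrow(positions)))
}

#' Thin-rod form factor
#'
#' P(q) = (2/(qL)) Si(qL) - 4 sin^2(qL/2) / (qL)^2 with Si the sine
#' integral; P -> 1 as qL -> 0 and P ~ pi/(qL) at large qL (the log-log
#' slope of -1 characteristic of rod scattering).
#'
#' @param q scattering vector (1/nm), positive.
#' @param L rod length (nm), positive.
#' @return numeric P(q).
#' @export
rodFormFactor <- function(q, L) {
  if (any(q < 0) || L <= 0) stop("q must be >= 0 and L > 0")
  x <- q * L
  out <- numeric(length(x))
  small <- x < 1e-3
  out[small] <- 1 - x[small]^2 / 36      # series limit, exact to O(x^4)
  if (any(!small)) {
    xs <- x[!small]
    si <- vapply(xs, pracma::Si, 0)
    out[!small] <- 2 * si / xs - 4 * sin(xs / 2)^2 / xs^2
  }
  out
}

#' Power-law slope of a scattering profile
#'
#' Least-squares slope of log I versus log q over \code{[qMin, qMax]}.
#'
#' @param profile a [ScatteringProfile-class].
#' @param qMin,qMax fitting window (1/nm).
#' @return list with \code{slope} and \code{se} (standard error).
#' @export
powerlawSlope <- function(profile, qMin, qMax) {
  sel <- profile@q >= qMin & profile@q <= qMax
  if (sum(sel) < 5)
    stop("need at least 5 points in the fitting window")
  if (any(profile@intensity[sel] <= 0))
    stop("intensities must be positive for a log-log fit")
  lx <- log(profile@q[sel]); ly <- log(profile@intensity[sel])
  fit <- stats::lm(ly ~ lx)
  res <- stats::residuals(fit)
  n <- length(lx)
  se <- sqrt(sum(res^2) / (n - 2) / sum((lx - mean(lx))^2))
  list(slope = unname(stats::coef(fit)[2]), se = se)
}

#' Peak position and d-spacing
#'
#' Finds the maximum of a locally smoothed intensity (5-point moving
#' average) inside a q window, refines it by a parabolic fit through the
#' three points around the discrete maximum, and reports the real-space
#' periodicity d = 2 pi / q_peak.
#'
#' @param profile a [ScatteringProfile-class].
#' @param qWindow numeric(2) window inside the grid; defaults to the full
#'   grid.
#' @param smoothPoints moving-average width (odd, default 5).
#' @return list with \code{qPeak} (1/nm) and \code{dSpacing} (nm).
#' @export
peakAndDspacing <- function(profile, qWindow = range(profile@q),
                            smoothPoints = 5L) {
  q <- profile@q; I <- profile@intensity
  if (qWindow[1] < min(q) || qWindow[2] > max(q))
    stop("window must lie inside the q grid")
  k <- as.integer(smoothPoints)
  if (k > 1) {
    sm <- stats::filter(I, rep(1 / k, k), sides = 2)
    sm[is.na(sm)] <- I[is.na(sm)]
    I <- as.numeric(sm)
  }
  sel <- which(q >= qWindow[1] & q <= qWindow[2])
  if (length(sel) < 3) stop("window too narrow")
  m <- sel[which.max(I[sel])]
  if (m == sel[1] || m == sel[length(sel)] || m == 1 || m == length(q))
    stop("no interior maximum in the window")
  # parabolic sub-grid refinement through (q, I) at m-1, m, m+1
  qs <- q[(m - 1):(m + 1)]; Is <- I[(m - 1):(m + 1)]
  denom <- (qs[1] - qs[2]) * (qs[1] - qs[3]) * (qs[2] - qs[3])
  a <- (qs[3] * (Is[2] - Is[1]) + qs[2] * (Is[1] - Is[3]) +
          qs[1] * (Is[3] - Is[2])) / denom
  b <- (qs[3]^2 * (Is[1] - Is[2]) + qs[2]^2 * (Is[3] - Is[1]) +
          qs[1]^2 * (Is[2] - Is[3])) / denom
  qPeak <- if (a < 0) -b / (2 * a) else q[m]
  if (qPeak < qs[1] || qPeak > qs[3]) qPeak <- q[m]
  list(qPeak = qPeak, dSpacing = 2 * pi / qPeak)
}

#' Fit a rod length to a scattering profile
#'
#' Least-squares fit of \code{scale * rodFormFactor(q, L)} on a log scale;
#' the package's estimator for the thin-rod length scale, reported with fit
#' diagnostics.
#'
#' @param profile a [ScatteringProfile-class].
#' @param Lstart starting rod length (nm).
#' @return list with \code{L}, \code{scale}, \code{rmsLogResidual}.
#' @export
fitRodLength <- function(profile, Lstart = 10) {
  q <- profile@q; I <- profile@intensity
  if (any(I <= 0)) stop("intensities must be positive")
  obj <- function(p) {
    L <- exp(p[1]); s <- p[2]
    sum((log(I) - s - log(rodFormFactor(q, L)))^2)
  }
  opt <- stats::optim(c(log(Lstart), log(I[1])), obj)
  rms <- sqrt(opt$value / length(q))
  list(L = exp(opt$par[1]), scale = exp(opt$par[2]), rmsLogResidual = rms)
}
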