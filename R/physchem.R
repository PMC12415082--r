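# closed-form physical characterization: swelling degree, rubber-elasticity
# mesh size, modulus conversion

.N_AVOGADRO <- 6.02214076e23   # 1/mol (CODATA)
.R_GAS <- 8.31446261815324     # J/(mol K) (CODATA)

#' Volume swelling degree
#'
#' Q = (d / d0)^3 from the swollen and cast gel diameters.
#'
#' @param d swollen diameter (any length unit).
#' @param d0 cast diameter (same unit).
#' @return numeric Q.
#' @examples
#' swellingDegree(11.7, 9.0)  # 2.197
#' @export
swellingDegree <- function(d, d0) {
  if (any(d <= 0) || any(d0 <= 0)) stop("diameters must be positive")
  (d / d0)^3
}

#' Mesh size from the storage modulus (rubber elasticity)
#'
#' xi = (G' N_A / (R T))^(-1/3) = (R T / (N_A G'))^(1/3): the classical
#' rubber-elasticity estimate of the network strand spacing.
#'
#' @param GPrime storage modulus in Pa.
#' @param temperature absolute temperature in K (default 298.15, room
#'   temperature).
#' @return mesh size in nm.
#' @examples
#' meshSizeFromModulus(1000)  # ~16 nm
#' @export
meshSizeFromModulus <- function(GPrime, temperature = 298.15) {
  if (any(GPrime <= 0) || any(temperature <= 0))
    stop("modulus and temperature must be positive")
  xiM <- (.R_GAS * temperature / (.N_AVOGADRO * GPrime))^(1 / 3)
  xiM * 1e9
}

#' Storage modulus from a mesh size (inverse of [meshSizeFromModulus()])
#'
#' @param xiNm mesh size in nm.
#' @param temperature absolute temperature in K.
#' @return storage modulus in Pa.
#' @export
modulusFromMeshSize <- function(xiNm, temperature = 298.15) {
  if (any(xiNm <= 0) || any(temperature <= 0))
    stop("mesh size and temperature must be positive")
  .R_GAS * temperature / (.N_AVOGADRO * (xiNm * 1e-9)^3)
}

#' Shear modulus from Young's modulus
#'
#' G = E / (2 (1 + nu)); for an incompressible gel (nu = 0.5), G = E / 3.
#'
#' @param E Young's modulus (Pa).
#' @param nu Poisson's ratio in \code{[0, 0.5]} (default 0.5).
#' @return shear modulus (Pa).
#' @examples
#' youngToShear(3000)        # 1000
#' @export
youngToShear <- function(E, nu = 0.5) {
  if (any(E <= 0)) stop("modulus must be positive")
  if (any(nu < 0) || any(nu > 0.5)) stop("Poisson's ratio must lie in [0, 0.5]")
  E / (2 * (1 + nu))
}
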