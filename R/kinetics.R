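#' Supersaturation ratio
#'
#' The thermodynamic driving force of crystallization: solute
#' concentration divided by the saturation concentration, S = c / c_sat.
#'
#' @param c solute concentration, kg m^-3 (vectorized).
#' @param constants a [physicalConstants()] object.
#' @return The dimensionless supersaturation ratio.
#' @examples
#' supersaturation(15, physicalConstants(csat = 3))  # 5
#' @export
supersaturation <- function(c, constants) {
  stopifnot(inherits(constants, "physicalConstants"))
  if (any(c < 0)) stop("concentration must be >= 0")
  c / constants$csat
}

#' Classical nucleation theory rate
#'
#' Primary homogeneous nucleation rate
#' \deqn{B_0 = e^{A_j}\, S\, \exp\!\left(-\frac{16\pi\gamma^3 v_0^2}
#'   {3 k_B^3 T^3 \ln^2 S}\right)}
#' with the surface energy converted from mJ m^-2 to J m^-2 internally.
#' For S <= 1 the barrier diverges and the rate is zero: subsaturated
#' solutions do not nucleate.
#'
#' @param S supersaturation ratio (vectorized).
#' @param params a [kineticParams()] object.
#' @param constants a [physicalConstants()] object.
#' @return Nucleation rate, # m^-3 s^-1.
#' @export
nucleationRate <- function(S, params, constants) {
  stopifnot(inherits(params, "kineticParams"),
            inherits(constants, "physicalConstants"))
  k <- paramsSI(params, constants)
  out <- numeric(length(S))
  pos <- S > 1
  out[pos] <- k$expAj * S[pos] * exp(-k$barrier / log(S[pos])^2)
  out
}

#' Power-law crystal growth rate
#'
#' Empirical size-independent growth kinetics G = A_g (S - 1)^g, clamped
#' to zero for S <= 1 (no dissolution is modeled).
#'
#' @param S supersaturation ratio (vectorized).
#' @param params a [kineticParams()] object.
#' @param units `"m/s"` (SI, solver convention) or `"nm/min"` (the unit
#'   A_g is specified in).
#' @return Growth rate in the requested units.
#' @examples
#' p <- kineticParams(37.7, 0.881, 0.682, 2.40)
#' growthRate(2, p, units = "nm/min")  # A_g itself
#' @export
growthRate <- function(S, params, units = c("m/s", "nm/min")) {
  stopifnot(inherits(params, "kineticParams"))
  units <- match.arg(units)
  out <- numeric(length(S))
  pos <- S > 1
  out[pos] <- params$Ag * (S[pos] - 1)^params$g
  if (units == "m/s") out <- out * 1e-9 / 60
  out
}

#' Superbee flux limiter
#'
#' The compressive TVD limiter used for the high-resolution face-flux
#' correction: phi(r) = max(0, min(2r, 1), min(r, 2)), where r is the
#' ratio of consecutive solution gradients.
#'
#' @param r gradient ratio (vectorized; may be +/-Inf).
#' @return Limiter values in \[0, 2\].
#' @examples
#' superbeeLimiter(c(-1, 0.4, 1, 3))  # 0, 0.8, 1, 2
#' @export
superbeeLimiter <- function(r) {
  pmax(0, pmax(pmin(2 * r, 1), pmin(r, 2)))
}
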