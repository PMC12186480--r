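#' Kinetic parameters of the crystallization model
#'
#' Bundles the four regressed kinetic parameters of the nucleation and
#' growth laws. The nucleation pre-exponential is carried on a natural-log
#' scale (`Aj` multiplies the rate as `exp(Aj)`), which keeps its magnitude
#' comparable to the other parameters during optimization.
#'
#' @param Aj log pre-exponential nucleation constant, log(# m^-3 s^-1).
#' @param gamma crystal-solution surface energy, mJ m^-2. Must be positive.
#' @param Ag growth pre-exponential, nm min^-1. Must be non-negative.
#' @param g growth exponent (dimensionless). Must be non-negative.
#' @return An object of class `kineticParams`.
#' @examples
#' kineticParams(Aj = 37.7, gamma = 0.881, Ag = 0.682, g = 2.40)
#' @export
kineticParams <- function(Aj, gamma, Ag, g) {
  stopifnot(is.numeric(Aj), is.numeric(gamma), is.numeric(Ag), is.numeric(g))
  v <- c(Aj = unname(Aj)[1], gamma = unname(gamma)[1],
         Ag = unname(Ag)[1], g = unname(g)[1])
  if (!all(is.finite(v))) stop("kinetic parameters must be finite")
  if (gamma <= 0) stop("surface energy gamma must be > 0")
  if (Ag < 0) stop("growth pre-exponential Ag must be >= 0")
  if (g < 0) stop("growth exponent g must be >= 0")
  structure(as.list(v), class = "kineticParams")
}

#' @export
print.kineticParams <- function(x, ...) {
  cat("Kinetic parameters:\n")
  cat(sprintf("  A_j   = %.4g  [log # m^-3 s^-1]\n", x$Aj))
  cat(sprintf("  gamma = %.4g  [mJ m^-2]\n", x$gamma))
  cat(sprintf("  A_g   = %.4g  [nm min^-1]\n", x$Ag))
  cat(sprintf("  g     = %.4g  [-]\n", x$g))
  invisible(x)
}

# SI view used by the solver: gamma mJ/m^2 -> J/m^2, Ag nm/min -> m/s
paramsSI <- function(p, constants) {
  gammaSI <- p$gamma * 1e-3
  list(
    expAj = exp(p$Aj),
    barrier = 16 * pi * gammaSI^3 * constants$v0^2 /
      (3 * constants$kB^3 * constants$T^3),
    Ag = p$Ag * 1e-9 / 60,
    g = p$g
  )
}

#' Physical constants of the crystallizing system
#'
#' Well-known (not regressed) constants of the protein/antisolvent system.
#' The saturation concentration `csat` has no universal value - it depends
#' on buffer, pH, precipitant load and temperature - and must always be
#' supplied by the user.
#'
#' @param csat saturation concentration, kg m^-3 (numerically equal to
#'   mg/mL). Required; no default.
#' @param kv volume shape factor (dimensionless).
#' @param rhoc crystal density, kg m^-3.
#' @param v0 molecular volume, m^3.
#' @param T temperature, K.
#' @param kB Boltzmann constant, J K^-1.
#' @return An object of class `physicalConstants`.
#' @examples
#' physicalConstants(csat = 2.0)
#' @export
physicalConstants <- function(csat, kv = 0.81, rhoc = 1240, v0 = 2.97e-26,
                              T = 293.15, kB = 1.380649e-23) {
  if (missing(csat)) {
    stop("the saturation concentration 'csat' is system-specific and must ",
         "be supplied explicitly (kg m^-3)")
  }
  v <- c(csat = csat, kv = kv, rhoc = rhoc, v0 = v0, T = T, kB = kB)
  if (!all(is.finite(v)) || any(v <= 0)) {
    stop("all physical constants must be finite and strictly positive")
  }
  structure(as.list(v), class = "physicalConstants")
}

#' @export
print.physicalConstants <- function(x, ...) {
  cat("Physical constants:\n")
  cat(sprintf("  c_sat = %.4g kg m^-3, k_v = %.3g, rho_c = %.4g kg m^-3\n",
              x$csat, x$kv, x$rhoc))
  cat(sprintf("  v_0 = %.3g m^3, T = %.2f K\n", x$v0, x$T))
  invisible(x)
}

#' Batch run conditions
#'
#' @param c0 initial solute concentration, kg m^-3.
#' @param duration batch duration, s.
#' @param constants a [physicalConstants()] object.
#' @return An object of class `batchConditions`.
#' @examples
#' batchConditions(c0 = 15, duration = 240 * 60,
#'                 constants = physicalConstants(csat = 2.0))
#' @export
batchConditions <- function(c0, duration, constants) {
  stopifnot(inherits(constants, "physicalConstants"))
  if (!is.finite(c0) || c0 < 0) stop("c0 must be finite and >= 0")
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  structure(list(c0 = c0, duration = duration, constants = constants),
            class = "batchConditions")
}

#' Default kinetic-parameter bounds
#'
#' Literature-derived bounds for the four kinetic parameters, in the units
#' of [kineticParams()]. The `"gsa"` set spans published lysozyme values
#' and is used for sensitivity analysis; the `"fit"` set is the widened
#' search box used by the differential-evolution optimizer and as the
#' uniform prior support for posterior recovery.
#'
#' @param purpose `"gsa"` for the sensitivity-analysis box or `"fit"` for
#'   the optimizer search box.
#' @return A data.frame with columns `parameter`, `lower`, `upper`.
#' @examples
#' defaultBounds("fit")
#' @export
defaultBounds <- function(purpose = c("gsa", "fit")) {
  purpose <- match.arg(purpose)
  if (purpose == "gsa") {
    data.frame(parameter = c("Aj", "gamma", "Ag", "g"),
               lower = c(22.7, 0.32, 0.394, 2),
               upper = c(32.9, 1.0, 0.876, 3))
  } else {
    data.frame(parameter = c("Aj", "gamma", "Ag", "g"),
               lower = c(10, 0.15, 0.15, 1),
               upper = c(60, 1.2, 2.5, 4))
  }
}

checkBounds <- function(bounds) {
  stopifnot(is.data.frame(bounds),
            all(c("parameter", "lower", "upper") %in% names(bounds)))
  if (any(!is.finite(bounds$lower)) || any(!is.finite(bounds$upper)) ||
      any(bounds$lower >= bounds$upper)) {
    stop("degenerate parameter bounds: need finite lower < upper")
  }
  bounds
}

vecToParams <- function(v) kineticParams(v[1], v[2], v[3], v[4])
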