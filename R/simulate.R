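#' Semi-discrete population-balance right-hand side
#'
#' One application of the high-resolution finite-volume spatial operator:
#' upwind face fluxes of G*n with a Superbee-limited MUSCL correction,
#' the nucleation source entering the first cell as B0/width\[1\] (the
#' conservative reading of the boundary delta source), zero-flux outflow
#' at Lmax, and the solute mass balance
#' dc/dt = -3 rho_c k_v G sum n_i L_i^2 w_i.
#'
#' Exposed mainly for testing and for building custom integrators; batch
#' runs should use [simulateBatch()].
#'
#' @param n number density per bin, # m^-3 m^-1 (length `grid$nBins`).
#' @param c solute concentration, kg m^-3.
#' @param params a [kineticParams()] object.
#' @param grid a [sizeGrid()] object.
#' @param constants a [physicalConstants()] object.
#' @return A list with `dn` (d n/dt), `dc` (d c/dt), and the current
#'   growth rate `G` (m/s) and nucleation rate `B0` (# m^-3 s^-1).
#' @export
fvmRHS <- function(n, c, params, grid, constants) {
  stopifnot(inherits(grid, "sizeGrid"), length(n) == grid$nBins)
  if (!all(is.finite(n)) || !is.finite(c)) {
    stop("integration failure: non-finite state passed to the PBM ",
         "right-hand side")
  }
  cpp_fvm_rhs(n, c, grid$centers, grid$edges, grid$widths,
              paramsSI(params, constants), constants$csat,
              3 * constants$rhoc * constants$kv)
}

#' Simulate an unseeded batch crystallization
#'
#' Integrates the method-of-lines population balance (crystal-free,
#' clear-liquor initial condition) over the batch duration with an
#' adaptive three-stage strong-stability-preserving Runge-Kutta scheme.
#' The step size satisfies both an embedded second-order error estimate
#' at the requested tolerances and the advective CFL restriction
#' `cfl * min(width) / G`. Negative densities produced at the tolerance
#' level by the limited scheme are clipped to zero after each accepted
#' step and the clipped number is tracked in `stats`.
#'
#' @param conditions a [batchConditions()] object.
#' @param params a [kineticParams()] object.
#' @param grid a [sizeGrid()] object.
#' @param reportTimes times (s) at which outputs are recorded; defaults
#'   to 61 evenly spaced points including 0 and the batch end.
#' @param solverOpts list overriding any of `rtol` (1e-4), `atol` (1e-6),
#'   `cfl` (0.9), `maxSteps` (5e6), `maxStep` (duration/100 upper bound on
#'   the step when kinetics are inactive).
#' @param quantiles size-distribution quantiles to track (volume
#'   weighted), default D10/D50/D90.
#' @param keepDensity keep the full number-density snapshot at every
#'   report time (needed for quantile trajectories; disable to save
#'   memory on large ensembles where only concentration is used).
#' @param initialCSD optional initial number density per bin. The batch
#'   protocol itself is unseeded (`n = 0`); this hook exists for solver
#'   validation (e.g. advecting a known pulse against its exact
#'   translation).
#' @return An object of class `simulationResult` with fields `times`,
#'   `c`, `S`, `quantiles` (matrix, m; NA before any crystal mass
#'   exists), `finalCSD`, `stats`, `conditions`, `params`, `grid`.
#' @examples
#' cst <- physicalConstants(csat = 2.0)
#' cond <- batchConditions(c0 = 15, duration = 60 * 60, constants = cst)
#' p <- kineticParams(37.7, 0.70, 0.682, 2.40)
#' res <- simulateBatch(cond, p, sizeGrid(nBins = 40),
#'                      reportTimes = seq(0, 3600, by = 600))
#' res$c
#' @export
simulateBatch <- function(conditions, params, grid,
                          reportTimes = NULL, solverOpts = list(),
                          quantiles = c(0.1, 0.5, 0.9),
                          keepDensity = TRUE, initialCSD = NULL) {
  stopifnot(inherits(conditions, "batchConditions"),
            inherits(params, "kineticParams"),
            inherits(grid, "sizeGrid"))
  cst <- conditions$constants
  opts <- list(rtol = 1e-4, atol = 1e-6, cfl = 0.9, maxSteps = 5e6,
               maxStep = conditions$duration / 100)
  opts[names(solverOpts)] <- solverOpts
  if (is.null(reportTimes)) {
    reportTimes <- seq(0, conditions$duration, length.out = 61)
  }
  reportTimes <- sort(unique(as.numeric(reportTimes)))
  if (any(reportTimes < 0) || max(reportTimes) > conditions$duration + 1e-9) {
    stop("reportTimes must lie within [0, duration]")
  }

  if (is.null(initialCSD)) {
    initialCSD <- numeric(0)
  } else {
    stopifnot(length(initialCSD) == grid$nBins, all(is.finite(initialCSD)),
              all(initialCSD >= 0))
  }
  raw <- cpp_simulate(conditions$c0, grid$centers, grid$edges, grid$widths,
                      paramsSI(params, cst), cst$csat,
                      3 * cst$rhoc * cst$kv, reportTimes,
                      opts$rtol, opts$atol, opts$cfl, opts$maxStep,
                      as.integer(opts$maxSteps), TRUE, initialCSD)

  nt <- length(reportTimes)
  qmat <- matrix(NA_real_, nt, length(quantiles),
                 dimnames = list(NULL, paste0("D", round(100 * quantiles))))
  for (j in seq_len(nt)) {
    nj <- raw$density[, j]
    if (sum(nj * grid$widths) > 0) {
      qmat[j, ] <- vapply(quantiles, function(q)
        csdQuantile(nj, grid, q), numeric(1))
    }
  }

  structure(list(
    times = reportTimes,
    c = raw$c,
    S = raw$c / cst$csat,
    quantiles = qmat,
    density = if (keepDensity) raw$density else NULL,
    finalCSD = list(n = raw$finalDensity, grid = grid),
    stats = list(steps = raw$steps, rejected = raw$rejected,
                 clippedNumber = raw$clippedNumber),
    conditions = conditions, params = params, grid = grid
  ), class = "simulationResult")
}

#' @export
print.simulationResult <- function(x, ...) {
  cat(sprintf("Batch PBM simulation: c0 = %.3g kg m^-3, %.0f s, %d bins\n",
              x$conditions$c0, x$conditions$duration, x$grid$nBins))
  cat(sprintf("  final c = %.4g kg m^-3 (S = %.3g), final D50 = %s\n",
              tail(x$c, 1), tail(x$S, 1),
              if (is.na(tail(x$quantiles[, "D50"], 1))) "undefined" else
                sprintf("%.3g um", 1e6 * tail(x$quantiles[, "D50"], 1))))
  cat(sprintf("  %d steps (%d rejected)\n", x$stats$steps, x$stats$rejected))
  invisible(x)
}

#' Moment of a discrete crystal size distribution
#'
#' mu_k = sum_i n_i L_i^k w_i over the grid cells.
#'
#' @param n number density per bin.
#' @param grid a [sizeGrid()] object.
#' @param k moment order.
#' @return The k-th moment (units m^(k-3) per m^3 slurry... i.e. m^k m^-3).
#' @export
csdMoment <- function(n, grid, k) {
  sum(n * grid$centers^k * grid$widths)
}

#' Quantile of a discrete crystal size distribution
#'
#' Returns the size below which a fraction `q` of the chosen weight lies.
#' The cumulative weight is assigned to bin centers with the half-bin
#' (Hazen) convention - each bin contributes half its weight at its own
#' center - and inverted by linear interpolation between centers of
#' occupied bins; beyond the outermost occupied centers the nearest
#' center is returned. Volume weighting (n L^3 w) is the default, the
#' convention of laser-diffraction size analyzers; number weighting
#' (n w) is available.
#'
#' @param n number density per bin (or a `simulationResult`, whose final
#'   CSD is then used).
#' @param grid a [sizeGrid()] object.
#' @param q quantile fraction in (0, 1); 0.5 gives the median size D50.
#' @param weighting `"volume"` or `"number"`.
#' @return Size, m.
#' @export
csdQuantile <- function(n, grid, q = 0.5,
                        weighting = c("volume", "number")) {
  if (inherits(n, "simulationResult")) {
    grid <- n$finalCSD$grid
    n <- n$finalCSD$n
  }
  weighting <- match.arg(weighting)
  stopifnot(inherits(grid, "sizeGrid"), length(n) == grid$nBins)
  if (any(q <= 0) || any(q >= 1)) stop("q must lie in (0, 1)")
  u <- if (weighting == "volume") n * grid$centers^3 * grid$widths
       else n * grid$widths
  tot <- sum(u)
  if (tot <= 0) stop("undefined quantile: the distribution holds no mass")
  cum <- (cumsum(u) - u / 2) / tot
  keep <- u > 0
  if (sum(keep) == 1) return(grid$centers[keep])
  vapply(q, function(qq)
    approx(cum[keep], grid$centers[keep], xout = qq, rule = 2,
           ties = "ordered")$y,
    numeric(1))
}

#' Write simulation outputs as delimited tables
#'
#' Writes the trajectory table (one row per report time: `t_s`, `c`,
#' `S`, one column per tracked quantile in m) and, optionally, the final
#' CSD table (`center_m`, `width_m`, `n`).
#'
#' @param res a `simulationResult`.
#' @param trajPath path for the trajectory table (tab-separated).
#' @param csdPath optional path for the final CSD table.
#' @return Invisibly, `res`.
#' @export
writeSimulationResult <- function(res, trajPath, csdPath = NULL) {
  stopifnot(inherits(res, "simulationResult"))
  tab <- data.frame(t_s = res$times, c = res$c, S = res$S,
                    res$quantiles, check.names = FALSE)
  write.table(tab, trajPath, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(csdPath)) {
    csd <- data.frame(center_m = res$grid$centers,
                      width_m = res$grid$widths,
                      n = res$finalCSD$n)
    write.table(csd, csdPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(res)
}
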