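# Variance-weighted maximum-likelihood estimation: measurement containers,
# the MLE loss, differential-evolution minimization and the
# Fisher-distribution confidence-region bound.

#' Pooled replicate variance with a relative floor
#'
#' Unbiased sample variance across replicates at each measurement point,
#' floored at `floorRel` times the squared replicate mean so that points
#' where the replicates happen to agree exactly do not blow up the
#' variance-weighted loss.
#'
#' @param x replicate values: a vector (one measurement point) or a
#'   matrix with one row per replicate and one column per point.
#' @param floorRel relative variance floor (default 1e-4 of mean^2).
#' @return Variance estimate(s), one per measurement point.
#' @examples
#' pooledVariance(c(4, 6))        # 2
#' pooledVariance(c(5, 5, 5))     # floor: 1e-4 * 25
#' @export
pooledVariance <- function(x, floorRel = 1e-4) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (nrow(x) < 2) {
    stop("pooled variance needs >= 2 replicates; supply an external ",
         "variance for single measurements")
  }
  v <- apply(x, 2, var)
  m <- colMeans(x)
  pmax(v, floorRel * m^2)
}

#' Assemble a measurement set
#'
#' The container consumed by the loss function: per experiment, the
#' replicate-averaged concentration series with its variances, plus one
#' endpoint D50 with its variance, and the initial concentration needed
#' to simulate that experiment.
#'
#' @param experiments a list; each element a list with fields `id`,
#'   `c0` (kg m^-3), `concTimes` (s), `concMean` (kg m^-3), `concVar`,
#'   `d50Time` (s), `d50Mean` (m), `d50Var` (m^2).
#' @return An object of class `measurementSet`.
#' @export
measurementSet <- function(experiments) {
  for (e in experiments) {
    need <- c("id", "c0", "concTimes", "concMean", "concVar",
              "d50Time", "d50Mean", "d50Var")
    if (!all(need %in% names(e))) {
      stop("experiment is missing fields: ",
           paste(setdiff(need, names(e)), collapse = ", "))
    }
    if (length(e$concTimes) != length(e$concMean) ||
        length(e$concMean) != length(e$concVar)) {
      stop("experiment ", e$id, ": concentration fields differ in length")
    }
    if (any(e$concVar <= 0) || e$d50Var <= 0) {
      stop("experiment ", e$id, ": variances must be > 0")
    }
    if (any(e$concTimes < 0) || e$d50Time <= 0) {
      stop("experiment ", e$id, ": measurement times must be positive")
    }
  }
  structure(list(experiments = experiments), class = "measurementSet")
}

#' @export
print.measurementSet <- function(x, ...) {
  cat(sprintf("Measurement set: %d experiment(s), nu = %d measurements\n",
              length(x$experiments), measurementCount(x)))
  for (e in x$experiments) {
    cat(sprintf("  %s: c0 = %.3g, %d concentration points, D50 = %.3g um at %.0f min\n",
                e$id, e$c0, length(e$concTimes), 1e6 * e$d50Mean,
                e$d50Time / 60))
  }
  invisible(x)
}

#' Total measurement count nu
#'
#' The degrees-of-freedom count entering the Fisher bound: the sum over
#' experiments of the number of concentration measurements plus one for
#' each experiment's endpoint D50.
#'
#' @param set a [measurementSet()].
#' @return Integer nu.
#' @export
measurementCount <- function(set) {
  stopifnot(inherits(set, "measurementSet"))
  sum(vapply(set$experiments,
             function(e) length(e$concTimes) + 1L, integer(1)))
}

#' Simulation configuration for the loss function
#'
#' Bundles everything the loss needs to simulate an experiment besides
#' its kinetic parameters.
#'
#' @param constants a [physicalConstants()] object (carries csat).
#' @param grid a [sizeGrid()] object.
#' @param solverOpts passed to [simulateBatch()].
#' @param reportFactor the model is reported on a grid at least this many
#'   times denser than the measurement schedule and interpolated
#'   piecewise-linearly to the measurement times.
#' @return A list of class `simConfig`.
#' @export
simConfig <- function(constants, grid = sizeGrid(), solverOpts = list(),
                      reportFactor = 4) {
  stopifnot(inherits(constants, "physicalConstants"),
            inherits(grid, "sizeGrid"), reportFactor >= 1)
  structure(list(constants = constants, grid = grid,
                 solverOpts = solverOpts, reportFactor = reportFactor),
            class = "simConfig")
}

# simulate one experiment and return model values at its measurement times
.modelAtMeasurements <- function(theta, exper, config) {
  duration <- max(exper$concTimes, exper$d50Time)
  nRep <- max(length(exper$concTimes), 1) * config$reportFactor
  rep0 <- seq(0, duration, length.out = nRep + 1)
  reportTimes <- sort(unique(c(rep0, exper$concTimes, exper$d50Time)))
  cond <- batchConditions(exper$c0, duration, config$constants)
  res <- simulateBatch(cond, theta, config$grid, reportTimes = reportTimes,
                       solverOpts = config$solverOpts, keepDensity = FALSE)
  cAt <- approx(res$times, res$c, xout = exper$concTimes)$y
  d50 <- unname(res$quantiles[which.min(abs(res$times - exper$d50Time)),
                              "D50"])
  # a parameter set that nucleates nothing predicts no measurable solid;
  # score it at the smallest resolvable size rather than failing
  if (is.na(d50)) d50 <- config$grid$Lmin
  list(c = cAt, d50 = d50)
}

#' Variance-weighted MLE loss
#'
#' The negative log-likelihood (up to constants) under Gaussian
#' measurement error: summed squared mispredictions of each concentration
#' point and of the endpoint D50, each scaled by its experimental
#' variance. Concentration terms are summed, not averaged, so every
#' measurement keeps its own variance weight. A failed simulation yields
#' `+Inf` (with the reason attached as an attribute), keeping the loss
#' total for the optimizers.
#'
#' @param theta a [kineticParams()] object or numeric vector
#'   (Aj, gamma, Ag, g).
#' @param set a [measurementSet()].
#' @param config a [simConfig()].
#' @return The scalar loss; `+Inf` with attribute `reason` on simulation
#'   failure.
#' @export
mleLoss <- function(theta, set, config) {
  stopifnot(inherits(set, "measurementSet"), inherits(config, "simConfig"))
  if (!inherits(theta, "kineticParams")) theta <- vecToParams(theta)
  total <- 0
  for (e in set$experiments) {
    mod <- tryCatch(.modelAtMeasurements(theta, e, config),
                    error = function(err) err)
    if (inherits(mod, "error")) {
      out <- Inf
      attr(out, "reason") <- paste0(e$id, ": ", conditionMessage(mod))
      return(out)
    }
    total <- total +
      sum((e$concMean - mod$c)^2 / e$concVar) +
      (e$d50Mean - mod$d50)^2 / e$d50Var
  }
  total
}

#' Differential evolution (rand/1/bin) minimizer
#'
#' Classic DE with a fixed generation budget: mutation
#' `v = x_r1 + F (x_r2 - x_r3)`, binomial crossover with rate `CR`,
#' greedy selection, and reflection at the search bounds. Deterministic
#' for a fixed `seed`.
#'
#' @param fn objective, mapping a numeric vector to a scalar (may return
#'   `Inf`).
#' @param lower,upper search bounds.
#' @param nPop population size.
#' @param nGen number of generations.
#' @param F mutation step size (default 0.7).
#' @param CR crossover rate (default 0.5).
#' @param seed RNG seed (optional).
#' @return A list with `par`, `value`, and `trace` (best loss per
#'   generation, non-increasing).
#' @export
deOptimize <- function(fn, lower, upper, nPop = 512, nGen = 512,
                       F = 0.7, CR = 0.5, seed = NULL) {
  stopifnot(length(lower) == length(upper), all(lower < upper), nPop >= 4)
  if (!is.null(seed)) set.seed(seed)
  p <- length(lower)
  span <- upper - lower
  pop <- matrix(lower, nPop, p, byrow = TRUE) +
    matrix(runif(nPop * p), nPop, p) * matrix(span, nPop, p, byrow = TRUE)
  cost <- apply(pop, 1, function(v) as.numeric(fn(v)))
  trace <- numeric(nGen)
  for (gen in seq_len(nGen)) {
    for (i in seq_len(nPop)) {
      r <- sample(seq_len(nPop)[-i], 3)
      v <- pop[r[1], ] + F * (pop[r[2], ] - pop[r[3], ])
      v <- reflectIntoBounds(v, lower, upper)
      jrand <- sample.int(p, 1)
      cross <- runif(p) < CR
      cross[jrand] <- TRUE
      trial <- ifelse(cross, v, pop[i, ])
      tc <- as.numeric(fn(trial))
      if (tc <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- tc
      }
    }
    trace[gen] <- min(cost)
  }
  best <- which.min(cost)
  list(par = pop[best, ], value = cost[best], trace = trace)
}

# reflect a proposal into [lower, upper] (preserves volume near bounds)
reflectIntoBounds <- function(v, lower, upper) {
  span <- upper - lower
  for (k in 1:10) {
    below <- v < lower
    v[below] <- 2 * lower[below] - v[below]
    above <- v > upper
    v[above] <- 2 * upper[above] - v[above]
    if (!any(v < lower | v > upper)) break
  }
  pmin(pmax(v, lower), upper)
}

#' Fisher-distribution confidence-region bound
#'
#' The loss threshold defining the finite-sample confidence region
#' around the optimum:
#' \deqn{MLE_{bound} = MLE_{min}\left(1 + \frac{p}{\nu - p}
#'   F^{\alpha}_{p,\,\nu-p}\right)}
#' with `p` estimated parameters, `nu` total measurements and confidence
#' level `alpha`. The F (Fisher) distribution, rather than chi-squared,
#' accounts for the variances being estimated from few replicates.
#'
#' @param mleMin loss value at the optimum.
#' @param p number of estimated parameters.
#' @param nu total measurement count (see [measurementCount()]).
#' @param alpha confidence level in (0, 1).
#' @return The loss upper bound.
#' @examples
#' fisherBound(193.2, p = 4, nu = 27, alpha = 0.95)  # about 287.1
#' @export
fisherBound <- function(mleMin, p, nu, alpha = 0.95) {
  if (nu <= p) stop("nu must exceed p: no residual degrees of freedom")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  mleMin * (1 + p / (nu - p) * qf(alpha, p, nu - p))
}

#' Fit kinetic parameters by differential evolution
#'
#' Minimizes the variance-weighted MLE loss over the kinetic-parameter
#' search box and attaches the Fisher confidence-region bound.
#'
#' @param set a [measurementSet()].
#' @param config a [simConfig()].
#' @param bounds search bounds (default [defaultBounds()] `"fit"` box).
#' @param nPop,nGen,F,CR differential-evolution settings (defaults 512
#'   particles, 512 generations, step 0.7, crossover 0.5).
#' @param alpha confidence level for the region bound.
#' @param seed RNG seed.
#' @return An object of class `mleFit`: `thetaOpt`, `mleMin`, `p`, `nu`,
#'   `alpha`, `mleBound`, `trace`, `bounds`.
#' @export
fitDE <- function(set, config, bounds = defaultBounds("fit"),
                  nPop = 512, nGen = 512, F = 0.7, CR = 0.5,
                  alpha = 0.95, seed = NULL) {
  stopifnot(inherits(set, "measurementSet"), inherits(config, "simConfig"))
  bounds <- checkBounds(bounds)
  p <- nrow(bounds)
  nu <- measurementCount(set)
  if (p >= nu) {
    stop("refusing to fit: ", p, " parameters but only ", nu,
         " measurements (no residual degrees of freedom)")
  }
  fn <- function(v) mleLoss(v, set, config)
  opt <- deOptimize(fn, bounds$lower, bounds$upper,
                    nPop = nPop, nGen = nGen, F = F, CR = CR, seed = seed)
  structure(list(thetaOpt = vecToParams(opt$par), mleMin = opt$value,
                 p = p, nu = nu, alpha = alpha,
                 mleBound = fisherBound(opt$value, p, nu, alpha),
                 trace = opt$trace, bounds = bounds),
            class = "mleFit")
}

#' @export
print.mleFit <- function(x, ...) {
  cat("Variance-weighted MLE fit (differential evolution)\n")
  print(x$thetaOpt)
  cat(sprintf("  MLE_min = %.4g, %.0f%% region bound = %.4g (p = %d, nu = %d)\n",
              x$mleMin, 100 * x$alpha, x$mleBound, x$p, x$nu))
  invisible(x)
}

#' Write an MLE fit summary
#'
#' Writes the fitted parameters and region bound as a small JSON-like
#' key-value file plus the per-generation best-loss trace as a
#' tab-separated table.
#'
#' @param fit an `mleFit`.
#' @param path summary file path.
#' @param tracePath optional trace table path.
#' @return Invisibly, `fit`.
#' @export
writeMLEFit <- function(fit, path, tracePath = NULL) {
  stopifnot(inherits(fit, "mleFit"))
  th <- fit$thetaOpt
  lines <- c("{",
             sprintf('  "Aj": %.10g,', th$Aj),
             sprintf('  "gamma": %.10g,', th$gamma),
             sprintf('  "Ag": %.10g,', th$Ag),
             sprintf('  "g": %.10g,', th$g),
             sprintf('  "mleMin": %.10g,', fit$mleMin),
             sprintf('  "mleBound": %.10g,', fit$mleBound),
             sprintf('  "p": %d,', fit$p),
             sprintf('  "nu": %d,', fit$nu),
             sprintf('  "alpha": %.10g', fit$alpha),
             "}")
  writeLines(lines, path)
  if (!is.null(tracePath)) {
    write.table(data.frame(generation = seq_along(fit$trace),
                           best = fit$trace),
                tracePath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fit)
}
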