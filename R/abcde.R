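# Likelihood-free posterior recovery inside the Fisher confidence region:
# Approximate Bayesian Computation with differential-evolution moves.

#' ABC sampler with differential-evolution proposals
#'
#' Recovers the parameter population filling the confidence region
#' `{theta : loss(theta) <= bound}`. The population is initialized from
#' the uniform prior over the search box and evolved with two
#' differential-evolution moves:
#'
#' * members already inside the current threshold propose the symmetric
#'   DE-MC move `theta* = theta_i + gammaDE * (theta_m - theta_n) + eps`
#'   with distinct random partners m, n, a small multiplicative jitter
#'   on the step size and a small additive uniform jitter. Because this
#'   proposal is symmetric, the stationary distribution of the
#'   in-region population is uniform over the region - the
#'   confidence-region reading of the fitted loss surface;
#' * members still above the threshold propose a descent move pulled
#'   toward the population's current best,
#'   `theta* = theta_i + 0.8 (theta_best - theta_i) +
#'   0.3 gammaDE (theta_m - theta_n) + eps`, which migrates stragglers
#'   into the region within a few generations instead of leaving them
#'   stranded in the prior box.
#'
#' Proposals reflect at the prior bounds and are accepted when their
#' loss is at or below the current threshold or (for members above it)
#' strictly below the member's own loss. The threshold anneals
#' geometrically from the initial population's worst finite loss down to
#' `bound` by generation `ceiling(annealFrac * nGen)` and holds there.
#'
#' @param lossFn scalar loss function of a parameter vector; must be
#'   total (return `Inf` rather than fail).
#' @param bound loss threshold defining the region (see [fisherBound()]).
#' @param bounds prior/search box: a data.frame as from
#'   [defaultBounds()].
#' @param popSize population size (default 4096).
#' @param nGen number of generations (default 128).
#' @param gammaDE base DE step size; default `2.38 / sqrt(2 p)`.
#' @param jitterFrac multiplicative step-size jitter (default 0.1).
#' @param epsFrac additive uniform jitter as a fraction of each
#'   parameter's prior range (default 1e-4).
#' @param annealFrac fraction of the generation budget by which the
#'   threshold reaches `bound` (default 0.75).
#' @param seed RNG seed; fixed seed gives a bit-identical table.
#' @return An object of class `posteriorTable`: a data.frame of accepted
#'   parameter vectors with their loss (`mle` column), with attributes
#'   `bound`, `seed`, `config`. A warning (not an error) is raised if
#'   any member remains outside the region at termination.
#' @export
abcdeSample <- function(lossFn, bound, bounds, popSize = 4096, nGen = 128,
                        gammaDE = NULL, jitterFrac = 0.1, epsFrac = 1e-4,
                        annealFrac = 0.75, seed = NULL) {
  bounds <- checkBounds(bounds)
  p <- nrow(bounds)
  if (popSize < 4 * p) stop("popSize must be at least 4 * p")
  if (nGen < 1) stop("nGen must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(gammaDE)) gammaDE <- 2.38 / sqrt(2 * p)
  lower <- bounds$lower
  upper <- bounds$upper
  span <- upper - lower

  pop <- matrix(lower, popSize, p, byrow = TRUE) +
    matrix(runif(popSize * p), popSize, p) *
    matrix(span, popSize, p, byrow = TRUE)
  loss <- apply(pop, 1, function(v) as.numeric(lossFn(v)))
  if (!any(is.finite(loss))) {
    stop("every prior draw has infinite loss: the simulator fails across ",
         "the whole prior box; check bounds and configuration")
  }
  thr0 <- max(loss[is.finite(loss)])
  thr0 <- max(thr0, bound)
  tAnneal <- max(1, ceiling(annealFrac * nGen))

  for (gen in seq_len(nGen)) {
    frac <- min(1, gen / tAnneal)
    thr <- bound * (thr0 / bound)^(1 - frac)
    for (i in seq_len(popSize)) {
      mn <- sample(seq_len(popSize)[-i], 2)
      diffv <- pop[mn[1], ] - pop[mn[2], ]
      if (loss[i] > thr) {
        # descent move toward the current best member
        best <- which.min(loss)
        prop <- pop[i, ] + 0.8 * (pop[best, ] - pop[i, ]) +
          0.3 * gammaDE * diffv + runif(p, -1, 1) * 10 * epsFrac * span
      } else {
        # symmetric in-region move (uniform stationary law on the region)
        step <- gammaDE * (1 + runif(1, -jitterFrac, jitterFrac))
        prop <- pop[i, ] + step * diffv + runif(p, -1, 1) * epsFrac * span
      }
      prop <- reflectIntoBounds(prop, lower, upper)
      pl <- as.numeric(lossFn(prop))
      if (pl <= thr || pl < loss[i]) {
        pop[i, ] <- prop
        loss[i] <- pl
      }
    }
  }
  nOut <- sum(loss > bound)
  if (nOut > 0) {
    warning(nOut, " of ", popSize, " members remain outside the ",
            "confidence region; increase nGen or check the bound")
  }
  tab <- as.data.frame(pop)
  names(tab) <- bounds$parameter
  tab$mle <- loss
  structure(tab, class = c("posteriorTable", "data.frame"),
            bound = bound, seed = seed,
            config = list(popSize = popSize, nGen = nGen,
                          gammaDE = gammaDE, jitterFrac = jitterFrac,
                          epsFrac = epsFrac, annealFrac = annealFrac))
}

#' @export
print.posteriorTable <- function(x, ...) {
  cat(sprintf("ABCDE posterior table: %d members, loss bound %.4g (max loss %.4g)\n",
              nrow(x), attr(x, "bound"), max(x$mle)))
  print(posteriorQuantiles(x))
  invisible(x)
}

#' Posterior quantiles per parameter
#'
#' Empirical quantiles of each parameter column (the linear-interpolation
#' convention of [stats::quantile()] type 7).
#'
#' @param table a `posteriorTable` (or any data.frame whose non-`mle`
#'   columns are parameters).
#' @param probs quantile levels (default 16, 50 and 84 percent).
#' @return A matrix, parameters x quantiles.
#' @export
posteriorQuantiles <- function(table, probs = c(0.16, 0.50, 0.84)) {
  stopifnot(nrow(table) >= 1)
  cols <- setdiff(names(table), "mle")
  out <- t(vapply(cols, function(cn)
    quantile(table[[cn]], probs = probs, names = FALSE, type = 7),
    numeric(length(probs))))
  colnames(out) <- paste0("q", round(100 * probs))
  out
}

#' Spearman rank-correlation matrix of the posterior
#'
#' Pairwise Spearman coefficients over all parameter columns, with ties
#' handled by average ranks. Columns with zero variance yield `NA` for
#' their pairs.
#'
#' @param table a `posteriorTable`.
#' @return A symmetric correlation matrix.
#' @export
spearmanMatrix <- function(table) {
  stopifnot(nrow(table) >= 3)
  cols <- setdiff(names(table), "mle")
  m <- as.matrix(table[cols])
  degenerate <- apply(m, 2, function(x) var(x) == 0)
  rho <- suppressWarnings(cor(m, method = "spearman"))
  if (any(degenerate)) {
    rho[degenerate, ] <- NA_real_
    rho[, degenerate] <- NA_real_
    diag(rho)[degenerate] <- NA_real_
    warning("zero-variance column(s): ",
            paste(cols[degenerate], collapse = ", "),
            "; their correlations are undefined")
  }
  rho
}

#' Corner-plot dataset from a posterior table
#'
#' Prepares everything a corner (pair) plot needs without plotting:
#' per-parameter histogram densities (integrating to one), a scatter
#' subsample for the off-diagonal panels, and 1-sigma/2-sigma density
#' contour levels from a Gaussian kernel density estimate on
#' standardized coordinates (levels enclose 39.35 and 86.47 percent of
#' probability mass, the bivariate-normal conventions).
#'
#' @param table a `posteriorTable`.
#' @param bins histogram bin count per parameter.
#' @param scatterMax maximum scatter points per panel.
#' @param gridSize kernel-density grid resolution per axis.
#' @return A list with `histograms` (per parameter: `mids`, `density`,
#'   `breaks`), `scatter` (row indices), and `contours` (per pair: KDE
#'   grid and `levels`, ordered descending in density).
#' @export
exportCorner <- function(table, bins = 40, scatterMax = 1000,
                         gridSize = 64) {
  stopifnot(nrow(table) >= 2)
  cols <- setdiff(names(table), "mle")
  hists <- lapply(cols, function(cn) {
    h <- graphics::hist(table[[cn]], breaks = bins, plot = FALSE)
    list(parameter = cn, mids = h$mids, density = h$density,
         breaks = h$breaks)
  })
  names(hists) <- cols
  idx <- if (nrow(table) > scatterMax) {
    round(seq(1, nrow(table), length.out = scatterMax))
  } else {
    seq_len(nrow(table))
  }
  pairs <- utils::combn(cols, 2, simplify = FALSE)
  contours <- lapply(pairs, function(pr) {
    x <- scale(table[[pr[1]]])[, 1]
    y <- scale(table[[pr[2]]])[, 1]
    if (!requireNamespace("MASS", quietly = TRUE)) {
      return(list(pair = pr, kde = NULL, levels = NULL))
    }
    kde <- MASS::kde2d(x, y, n = gridSize)
    cell <- diff(kde$x[1:2]) * diff(kde$y[1:2])
    dens <- sort(as.vector(kde$z), decreasing = TRUE)
    cum <- cumsum(dens) * cell
    lvl <- function(massFrac) dens[max(1, which(cum >= massFrac)[1])]
    levels <- c(sigma1 = lvl(0.3935), sigma2 = lvl(0.8647))
    list(pair = pr, kde = kde, levels = sort(levels, decreasing = TRUE))
  })
  names(contours) <- vapply(pairs, paste, character(1), collapse = ":")
  list(histograms = hists, scatter = idx, contours = contours)
}

#' Write a posterior table
#'
#' Tab-separated parameter columns plus the loss, with the region bound,
#' seed and configuration recorded in `#`-prefixed header lines.
#'
#' @param table a `posteriorTable`.
#' @param path output path.
#' @return Invisibly, `table`.
#' @export
writePosterior <- function(table, path) {
  stopifnot(inherits(table, "posteriorTable"))
  cfg <- attr(table, "config")
  hdr <- c(sprintf("# mle_bound = %.10g", attr(table, "bound")),
           sprintf("# seed = %s", deparse(attr(table, "seed"))),
           sprintf("# config = popSize:%d nGen:%d gammaDE:%.6g",
                   cfg$popSize, cfg$nGen, cfg$gammaDE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(table)
}
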