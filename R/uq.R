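# Monte Carlo propagation of the recovered parameter population to
# output uncertainty bands.

#' Propagate a posterior population through the simulator
#'
#' Simulates every row of the posterior table (or a subsample) under the
#' given batch conditions and collapses the concentration and D50
#' trajectories into centered empirical bands: the X percent band spans
#' the (50 - X/2) to (50 + X/2) percentiles at each report time, and the
#' full envelope is the pointwise min-max. The endpoint D50 is
#' summarized as mean plus/minus one sample standard deviation.
#'
#' @param table a `posteriorTable` (or data.frame with columns Aj,
#'   gamma, Ag, g).
#' @param conditions a [batchConditions()] object.
#' @param grid a [sizeGrid()] object.
#' @param reportTimes output times, s.
#' @param thetaOpt optional [kineticParams()] whose trajectory is
#'   overlaid (e.g. the MLE optimum).
#' @param levels centered band levels (default 25, 50, 75 percent).
#' @param subsample optional row count; rows are taken evenly through
#'   the table so the result is deterministic.
#' @param solverOpts passed to [simulateBatch()].
#' @return An object of class `uqBands`: per output (`c`, `d50`) the
#'   band arrays (`lower`/`upper`, levels x times), the `envelope`, the
#'   optimal overlay, `endpointD50` (mean, sd) and the count of excluded
#'   (failed) rows.
#' @export
propagatePosterior <- function(table, conditions, grid, reportTimes,
                               thetaOpt = NULL,
                               levels = c(0.25, 0.50, 0.75),
                               subsample = NULL, solverOpts = list()) {
  cols <- c("Aj", "gamma", "Ag", "g")
  stopifnot(all(cols %in% names(table)), nrow(table) >= 1)
  X <- as.matrix(table[cols])
  if (!is.null(subsample) && subsample < nrow(X)) {
    X <- X[round(seq(1, nrow(X), length.out = subsample)), , drop = FALSE]
  }
  reportTimes <- sort(unique(as.numeric(reportTimes)))
  ens <- evaluateEnsemble(X, conditions, grid, reportTimes,
                          solverOpts = solverOpts)
  ok <- ens$ok
  if (!any(ok)) stop("every posterior member failed to simulate")
  cm <- ens$c[ok, , drop = FALSE]
  dm <- ens$d50[ok, , drop = FALSE]

  bandsOf <- function(M) {
    qRow <- function(p) apply(M, 2, quantile, probs = p, na.rm = TRUE,
                              names = FALSE)
    lo <- t(vapply(levels, function(L) qRow(0.5 - L / 2),
                   numeric(ncol(M))))
    hi <- t(vapply(levels, function(L) qRow(0.5 + L / 2),
                   numeric(ncol(M))))
    list(lower = lo, upper = hi,
         envelope = rbind(
           lower = suppressWarnings(apply(M, 2, min, na.rm = TRUE)),
           upper = suppressWarnings(apply(M, 2, max, na.rm = TRUE))),
         median = apply(M, 2, median, na.rm = TRUE))
  }
  cb <- bandsOf(cm)
  db <- bandsOf(dm)
  db$envelope[!is.finite(db$envelope)] <- NA_real_

  optimal <- NULL
  if (!is.null(thetaOpt)) {
    res <- simulateBatch(conditions, thetaOpt, grid,
                         reportTimes = reportTimes,
                         solverOpts = solverOpts)
    optimal <- list(c = res$c, d50 = res$quantiles[, "D50"])
  }
  endT <- ncol(dm)
  dEnd <- dm[, endT]
  dSd <- if (sum(!is.na(dEnd)) > 1) sd(dEnd, na.rm = TRUE) else 0
  structure(list(times = reportTimes, levels = levels,
                 c = cb, d50 = db, optimal = optimal,
                 endpointD50 = c(mean = mean(dEnd, na.rm = TRUE),
                                 sd = dSd),
                 nUsed = sum(ok), nExcluded = sum(!ok)),
            class = "uqBands")
}

#' @export
print.uqBands <- function(x, ...) {
  cat(sprintf("Output uncertainty bands: %d trajectories (%d excluded), %d report times\n",
              x$nUsed, x$nExcluded, length(x$times)))
  cat(sprintf("  endpoint D50 = %.3g +/- %.3g um\n",
              1e6 * x$endpointD50["mean"], 1e6 * x$endpointD50["sd"]))
  invisible(x)
}

#' Envelope asymmetry about the reference trajectory
#'
#' Signed skew of the full envelope about the optimal (or, if absent,
#' median) trajectory at each report time:
#' `(upper_width - lower_width) / (upper_width + lower_width)`.
#' Positive values mean the uncertainty extends further above the
#' reference than below - the non-Gaussian signature of propagating a
#' skewed parameter posterior through nonlinear kinetics. Zero total
#' width returns 0 by convention.
#'
#' @param bands a [propagatePosterior()] result.
#' @param output `"c"` or `"d50"`.
#' @return A data.frame with columns `time`, `output`, `asymmetry`.
#' @export
asymmetryReport <- function(bands, output = c("c", "d50")) {
  stopifnot(inherits(bands, "uqBands"))
  output <- match.arg(output)
  env <- bands[[output]]$envelope
  ref <- if (!is.null(bands$optimal)) bands$optimal[[output]] else
    bands[[output]]$median
  uw <- env["upper", ] - ref
  lw <- ref - env["lower", ]
  tot <- uw + lw
  asym <- ifelse(is.na(tot) | tot == 0, 0, (uw - lw) / tot)
  data.frame(time = bands$times, output = output, asymmetry = asym,
             row.names = NULL)
}

#' Write uncertainty bands in long format
#'
#' One row per (output, time, band): columns `output`, `time_s`, `band`
#' (level in percent, or `envelope`), `lower`, `upper`.
#'
#' @param bands a `uqBands` object.
#' @param path output path (tab-separated).
#' @return Invisibly, the long-format data.frame.
#' @export
writeBands <- function(bands, path) {
  stopifnot(inherits(bands, "uqBands"))
  rows <- list()
  for (out in c("c", "d50")) {
    b <- bands[[out]]
    for (li in seq_along(bands$levels)) {
      rows[[length(rows) + 1]] <- data.frame(
        output = out, time_s = bands$times,
        band = sprintf("%g%%", 100 * bands$levels[li]),
        lower = b$lower[li, ], upper = b$upper[li, ])
    }
    rows[[length(rows) + 1]] <- data.frame(
      output = out, time_s = bands$times, band = "envelope",
      lower = b$envelope["lower", ], upper = b$envelope["upper", ])
  }
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
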