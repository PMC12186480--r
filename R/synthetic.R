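# Synthetic measurement generator: emulates the sparse offline sampling
# regime of stirred batch antisolvent protein crystallization - solute
# concentration drawn roughly every 30 minutes with a few replicates, one
# endpoint laser-diffraction D50, heteroscedastic Gaussian noise.

#' Synthetic-world ground truth
#'
#' The documented reference kinetics and saturation concentration of the
#' package's synthetic test world. These are NOT measured values for any
#' real protein system: the saturation concentration of a given
#' buffer/precipitant system must be characterized experimentally, and
#' the kinetic parameters here were chosen once, inside the
#' literature-derived bounds of [defaultBounds()], so that an unseeded
#' batch at the default protocol conditions nucleates, consumes a
#' substantial fraction of the initial supersaturation within four
#' hours, and ends with crystals in the 5-15 um range - the qualitative
#' behavior of stirred antisolvent lysozyme batches.
#'
#' @return A list with `theta` (a [kineticParams()]) and `constants`
#'   (a [physicalConstants()] with the synthetic csat of 2 kg m^-3).
#' @export
syntheticTruth <- function() {
  list(theta = kineticParams(Aj = 37.7, gamma = 0.70, Ag = 0.682, g = 2.40),
       constants = physicalConstants(csat = 2.0))
}

#' Experimental protocol specification
#'
#' Describes the measurement campaign the generator emulates: which
#' initial concentrations are run (estimation conditions, plus held-out
#' validation conditions), the offline sampling interval, the batch
#' duration, the replicate count, and the relative measurement noise on
#' concentration and endpoint D50.
#'
#' @param conditions estimation initial concentrations, kg m^-3.
#' @param validation held-out validation initial concentrations (must be
#'   disjoint from `conditions`).
#' @param intervalMin sampling interval, minutes.
#' @param durationMin batch duration, minutes.
#' @param replicates replicate experiments per condition (>= 2).
#' @param concNoiseSd relative (fraction-of-truth) Gaussian noise s.d.
#'   on concentration measurements.
#' @param d50NoiseSd relative Gaussian noise s.d. on D50 measurements.
#' @return An object of class `protocolSpec`.
#' @export
protocolSpec <- function(conditions = c(15, 18, 19),
                         validation = c(16, 20),
                         intervalMin = 30, durationMin = 240,
                         replicates = 3,
                         concNoiseSd = 0.02, d50NoiseSd = 0.10) {
  if (intervalMin <= 0 || durationMin < intervalMin) {
    stop("need 0 < intervalMin <= durationMin")
  }
  if (replicates < 2) stop("need >= 2 replicates for pooled variances")
  if (concNoiseSd < 0 || d50NoiseSd < 0) stop("noise s.d. must be >= 0")
  if (length(intersect(conditions, validation)) > 0) {
    stop("estimation and validation conditions must be disjoint")
  }
  structure(list(conditions = conditions, validation = validation,
                 intervalMin = intervalMin, durationMin = durationMin,
                 replicates = replicates, concNoiseSd = concNoiseSd,
                 d50NoiseSd = d50NoiseSd),
            class = "protocolSpec")
}

#' @export
print.protocolSpec <- function(x, ...) {
  cat(sprintf("Protocol: c0 = {%s} (validation {%s}) kg m^-3\n",
              paste(x$conditions, collapse = ", "),
              paste(x$validation, collapse = ", ")))
  cat(sprintf("  sample every %g min over %g min, %d replicates, noise %g%%/%g%% (conc/D50)\n",
              x$intervalMin, x$durationMin, x$replicates,
              100 * x$concNoiseSd, 100 * x$d50NoiseSd))
  invisible(x)
}

#' Generate a synthetic measurement set from known kinetics
#'
#' Simulates each protocol condition once at the ground-truth kinetics,
#' draws replicate observations with independent relative Gaussian noise
#' at every sample time, and forms replicate means and pooled (floored)
#' variances; the endpoint D50 is drawn the same way from the truth
#' distribution's volume-weighted median. The returned set carries a
#' sealed truth record (generating parameters and noise-free
#' trajectories) in attribute `"truth"`, kept out of the measurement
#' table proper so fitting code cannot consume it by accident.
#'
#' @param thetaTrue generating [kineticParams()].
#' @param protocol a [protocolSpec()].
#' @param config a [simConfig()] (constants, grid, solver options).
#' @param which `"estimation"` or `"validation"` conditions.
#' @param seed RNG seed; the same seed reproduces the set exactly.
#' @param varianceFloor relative variance floor for [pooledVariance()].
#' @return A [measurementSet()] with attribute `truth`.
#' @export
generateMeasurements <- function(thetaTrue, protocol, config,
                                 which = c("estimation", "validation"),
                                 seed = NULL, varianceFloor = 1e-4) {
  stopifnot(inherits(thetaTrue, "kineticParams"),
            inherits(protocol, "protocolSpec"),
            inherits(config, "simConfig"))
  which <- match.arg(which)
  if (!is.null(seed)) set.seed(seed)
  c0s <- if (which == "estimation") protocol$conditions else
    protocol$validation
  duration <- protocol$durationMin * 60
  sampleTimes <- seq(protocol$intervalMin, protocol$durationMin,
                     by = protocol$intervalMin) * 60
  denseTimes <- sort(unique(c(seq(0, duration, length.out = 121),
                              sampleTimes)))
  experiments <- list()
  truth <- list(theta = thetaTrue, conditions = list())
  for (c0 in c0s) {
    res <- tryCatch(
      simulateBatch(batchConditions(c0, duration, config$constants),
                    thetaTrue, config$grid, reportTimes = denseTimes,
                    solverOpts = config$solverOpts),
      error = function(e) {
        stop("truth simulation failed for condition c0 = ", c0, ": ",
             conditionMessage(e))
      })
    idx <- match(sampleTimes, denseTimes)
    cTruth <- res$c[idx]
    d50Truth <- unname(res$quantiles[length(denseTimes), "D50"])
    if (is.na(d50Truth)) {
      stop("condition c0 = ", c0, " produced no crystal mass at batch ",
           "end; the generating kinetics cannot emulate an endpoint ",
           "size measurement")
    }
    nr <- protocol$replicates
    nm <- length(sampleTimes)
    concReps <- matrix(cTruth, nr, nm, byrow = TRUE) *
      (1 + matrix(rnorm(nr * nm, sd = protocol$concNoiseSd), nr, nm))
    d50Reps <- d50Truth * (1 + rnorm(nr, sd = protocol$d50NoiseSd))
    experiments[[length(experiments) + 1]] <- list(
      id = sprintf("%s_c0_%g", substr(which, 1, 3), c0),
      c0 = c0,
      concTimes = sampleTimes,
      concMean = colMeans(concReps),
      concVar = pooledVariance(concReps, floorRel = varianceFloor),
      d50Time = duration,
      d50Mean = mean(d50Reps),
      d50Var = pooledVariance(d50Reps, floorRel = varianceFloor))
    truth$conditions[[as.character(c0)]] <- list(
      c0 = c0, times = denseTimes, c = res$c,
      d50 = res$quantiles[, "D50"], d50End = d50Truth,
      cAtSamples = cTruth)
  }
  set <- measurementSet(experiments)
  attr(set, "truth") <- truth
  set
}

#' Write / read measurement sets
#'
#' The on-disk schema is one tab-separated row per measurement:
#' `experiment_id`, `c0` (kg m^-3), `type` (`conc` or `d50`),
#' `time_min`, `value` (kg m^-3 for `conc`, um for `d50`), `variance`
#' (same squared units). The reader validates the schema and the
#' measurement-set invariants and reports offending line numbers. The
#' sealed truth record is never written to the measurement file; pass
#' `truthPath` to store it separately.
#'
#' @param set a [measurementSet()].
#' @param path measurement file path.
#' @param truthPath optional separate path for the sealed truth record
#'   (written only when the set carries one).
#' @return Invisibly, `set`.
#' @export
writeMeasurements <- function(set, path, truthPath = NULL) {
  stopifnot(inherits(set, "measurementSet"))
  rows <- list()
  for (e in set$experiments) {
    rows[[length(rows) + 1]] <- data.frame(
      experiment_id = e$id, c0 = e$c0, type = "conc",
      time_min = e$concTimes / 60, value = e$concMean,
      variance = e$concVar)
    rows[[length(rows) + 1]] <- data.frame(
      experiment_id = e$id, c0 = e$c0, type = "d50",
      time_min = e$d50Time / 60, value = e$d50Mean * 1e6,
      variance = e$d50Var * 1e12)
  }
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- attr(set, "truth")
  if (!is.null(truthPath) && !is.null(truth)) {
    con <- file(truthPath, "w")
    on.exit(close(con))
    th <- truth$theta
    writeLines(sprintf("# sealed truth record: theta = %.10g %.10g %.10g %.10g",
                       th$Aj, th$gamma, th$Ag, th$g), con)
    for (cc in truth$conditions) {
      write.table(data.frame(c0 = cc$c0, time_s = cc$times, c = cc$c,
                             d50_m = cc$d50),
                  con, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(set)
}

#' @rdname writeMeasurements
#' @export
readMeasurements <- function(path) {
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse measurement file: ",
                             conditionMessage(e)))
  need <- c("experiment_id", "c0", "type", "time_min", "value", "variance")
  if (!all(need %in% names(tab))) {
    stop("measurement file is missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  lineNo <- seq_len(nrow(tab)) + 1L  # header is line 1
  bad <- !(tab$type %in% c("conc", "d50"))
  if (any(bad)) {
    stop("unknown measurement type at line(s) ",
         paste(lineNo[bad], collapse = ", "))
  }
  bad <- !is.finite(tab$variance) | tab$variance <= 0
  if (any(bad)) {
    stop("non-positive variance at line(s) ",
         paste(lineNo[bad], collapse = ", "))
  }
  bad <- !is.finite(tab$value) | !is.finite(tab$time_min) | tab$time_min < 0
  if (any(bad)) {
    stop("malformed value/time at line(s) ",
         paste(lineNo[bad], collapse = ", "))
  }
  experiments <- lapply(split(tab, tab$experiment_id), function(d) {
    conc <- d[d$type == "conc", , drop = FALSE]
    d50 <- d[d$type == "d50", , drop = FALSE]
    if (nrow(d50) != 1) {
      stop("experiment ", d$experiment_id[1], ": expected exactly one ",
           "d50 row, found ", nrow(d50))
    }
    if (length(unique(d$c0)) != 1) {
      stop("experiment ", d$experiment_id[1], ": inconsistent c0")
    }
    conc <- conc[order(conc$time_min), , drop = FALSE]
    list(id = d$experiment_id[1], c0 = d$c0[1],
         concTimes = conc$time_min * 60, concMean = conc$value,
         concVar = conc$variance,
         d50Time = d50$time_min * 60, d50Mean = d50$value * 1e-6,
         d50Var = d50$variance * 1e-12)
  })
  names(experiments) <- NULL
  measurementSet(experiments)
}
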