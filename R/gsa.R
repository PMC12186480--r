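# Variance-based global sensitivity analysis: Sobol quasi-random design,
# Saltelli/Jansen Monte Carlo index estimators, identifiability ranking.

# Joe-Kuo direction-number table (primitive polynomial degree s, coefficient
# word a, initial direction integers m) for Sobol dimensions 2..10;
# dimension 1 is the van der Corput sequence in base 2.
.sobolDirs <- list(
  list(s = 1, a = 0, m = 1),
  list(s = 2, a = 1, m = c(1, 3)),
  list(s = 3, a = 1, m = c(1, 3, 1)),
  list(s = 3, a = 2, m = c(1, 1, 1)),
  list(s = 4, a = 1, m = c(1, 1, 3, 3)),
  list(s = 4, a = 4, m = c(1, 3, 5, 13)),
  list(s = 5, a = 2, m = c(1, 1, 5, 5, 17)),
  list(s = 5, a = 4, m = c(1, 1, 5, 5, 5)),
  list(s = 5, a = 7, m = c(1, 1, 7, 11, 19))
)

#' Unscrambled Sobol quasi-random sequence
#'
#' Gray-code implementation with Joe-Kuo direction numbers, supporting up
#' to 10 dimensions (a four-parameter crossed design needs 8). The
#' sequence is deterministic; `skip = 1` (default) drops the initial
#' all-zeros point.
#'
#' @param n number of points.
#' @param d dimension (1..10).
#' @param skip number of initial points to discard.
#' @return An `n` x `d` matrix of points in \[0, 1)^d.
#' @export
sobolSequence <- function(n, d, skip = 1) {
  if (d < 1 || d > 10) stop("sobolSequence supports 1 <= d <= 10")
  if (skip == 0) {
    if (n == 1) return(matrix(0, 1, d))
    return(rbind(numeric(d), sobolSequence(n - 1, d, skip = 1)))
  }
  B <- 30L
  nb <- as.integer(ceiling(log2(max(n + skip, 2))) + 1)
  V <- matrix(0L, nb, d)
  V[, 1] <- bitwShiftL(1L, B - seq_len(nb))
  for (j in seq_len(d - 1)) {
    dir <- .sobolDirs[[j]]
    s <- dir$s
    aBits <- as.integer(intToBits(dir$a))[seq_len(max(s - 1, 1))]
    for (k in seq_len(min(s, nb))) {
      V[k, j + 1] <- bitwShiftL(as.integer(dir$m[k]), B - k)
    }
    if (nb > s) {
      for (k in (s + 1):nb) {
        vk <- bitwXor(V[k - s, j + 1], bitwShiftR(V[k - s, j + 1], s))
        if (s > 1) {
          for (i in seq_len(s - 1)) {
            if (aBits[s - i] == 1L) vk <- bitwXor(vk, V[k - i, j + 1])
          }
        }
        V[k, j + 1] <- vk
      }
    }
  }
  out <- matrix(0, n, d)
  x <- integer(d)
  total <- n + skip - 1L
  for (i in seq_len(total)) {
    # lowest zero bit of (i - 1)
    cbit <- 1L
    ii <- i - 1L
    while (bitwAnd(ii, 1L) == 1L) {
      ii <- bitwShiftR(ii, 1L)
      cbit <- cbit + 1L
    }
    x <- bitwXor(x, V[cbit, ])
    if (i >= skip) out[i - skip + 1L, ] <- x / 2^B
  }
  out
}

#' Saltelli cross-sampling design
#'
#' Builds the radial design used by the Monte Carlo Sobol estimators: two
#' independent base matrices A and B of `N` points each, the `AB_i`
#' matrices (A with column i taken from B) for first/total-order indices,
#' and optionally the `BA_i` matrices for closed second-order indices.
#' Total model evaluations: `N * (p + 2)` or `N * (2p + 2)`.
#'
#' @param bounds a bounds data.frame as returned by [defaultBounds()].
#' @param N base sample count, ideally a power of two (default 8192).
#' @param secondOrder include the `BA_i` blocks for pair indices.
#' @param skip initial Sobol points to discard (see [sobolSequence()]).
#' @return An object of class `sobolDesign` with the stacked evaluation
#'   matrix `X` (rows grouped A, B, AB_1..AB_p, BA_1..BA_p) and block
#'   bookkeeping.
#' @export
sobolDesign <- function(bounds, N = 8192, secondOrder = TRUE, skip = 1) {
  bounds <- checkBounds(bounds)
  p <- nrow(bounds)
  if (2 * p > 10) stop("at most 5 parameters supported by the Sobol table")
  U <- sobolSequence(N, 2 * p, skip = skip)
  A <- U[, seq_len(p), drop = FALSE]
  B <- U[, p + seq_len(p), drop = FALSE]
  blocks <- vector("list", 2 + p + if (secondOrder) p else 0)
  blocks[[1]] <- A
  blocks[[2]] <- B
  for (i in seq_len(p)) {
    AB <- A; AB[, i] <- B[, i]
    blocks[[2 + i]] <- AB
  }
  if (secondOrder) {
    for (i in seq_len(p)) {
      BA <- B; BA[, i] <- A[, i]
      blocks[[2 + p + i]] <- BA
    }
  }
  X01 <- do.call(rbind, blocks)
  X <- sweep(sweep(X01, 2, bounds$upper - bounds$lower, "*"),
             2, bounds$lower, "+")
  colnames(X) <- bounds$parameter
  structure(list(X = X, N = N, p = p, secondOrder = secondOrder,
                 bounds = bounds), class = "sobolDesign")
}

#' @export
print.sobolDesign <- function(x, ...) {
  cat(sprintf("Sobol/Saltelli design: N = %d base points, p = %d, %d model evaluations%s\n",
              x$N, x$p, nrow(x$X),
              if (x$secondOrder) " (with second-order blocks)" else ""))
  invisible(x)
}

#' Run the crystallization model over a design matrix
#'
#' Simulates one batch per design row and tabulates the concentration and
#' (volume-weighted) D50 trajectories at the report times. Rows whose
#' simulation fails are flagged, never silently dropped. With `cores > 1`
#' rows are distributed over forked workers; results are identical to the
#' serial run.
#'
#' @param X a numeric matrix with columns Aj, gamma, Ag, g (e.g.
#'   `design$X`), or a `sobolDesign`.
#' @param conditions a [batchConditions()] object.
#' @param grid a [sizeGrid()] object.
#' @param reportTimes output times, s.
#' @param solverOpts passed to [simulateBatch()].
#' @param cores forked worker count (POSIX only).
#' @return A list with matrices `c` and `d50` (rows = design rows), a
#'   logical `ok` flag per row and a character vector `errors`.
#' @export
evaluateEnsemble <- function(X, conditions, grid, reportTimes,
                             solverOpts = list(), cores = 1) {
  if (inherits(X, "sobolDesign")) X <- X$X
  stopifnot(is.matrix(X), ncol(X) == 4)
  runRow <- function(i) {
    tryCatch({
      res <- simulateBatch(conditions, vecToParams(X[i, ]), grid,
                           reportTimes = reportTimes,
                           solverOpts = solverOpts)
      list(c = res$c, d50 = res$quantiles[, "D50"], ok = TRUE, err = "")
    }, error = function(e) {
      list(c = rep(NA_real_, length(reportTimes)),
           d50 = rep(NA_real_, length(reportTimes)),
           ok = FALSE, err = conditionMessage(e))
    })
  }
  rows <- if (cores > 1) {
    parallel::mclapply(seq_len(nrow(X)), runRow, mc.cores = cores)
  } else {
    lapply(seq_len(nrow(X)), runRow)
  }
  list(c = do.call(rbind, lapply(rows, `[[`, "c")),
       d50 = do.call(rbind, lapply(rows, `[[`, "d50")),
       ok = vapply(rows, `[[`, logical(1), "ok"),
       errors = vapply(rows, `[[`, character(1), "err"))
}

#' Monte Carlo Sobol sensitivity indices
#'
#' First-order indices by the Saltelli (2010) estimator, total-order by
#' the Jansen estimator, and (when the design carries `BA` blocks) closed
#' second-order pair effects by the Saltelli (2002) estimator, reported
#' as the closed effect minus the two first-order terms.
#'
#' @param Y model outputs: a vector of length `nrow(design$X)` or a
#'   matrix with one column per output (e.g. per report time).
#' @param design the [sobolDesign()] the outputs were computed on.
#' @return An object of class `sobolResult`: matrices `S1`, `ST`
#'   (parameters x outputs), array `S2` (parameter pairs x outputs), the
#'   output variance `V`, and `N`. Outputs with (numerically) zero
#'   variance yield `NA` indices and are flagged in `degenerate`.
#' @export
sobolIndices <- function(Y, design) {
  stopifnot(inherits(design, "sobolDesign"))
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  N <- design$N; p <- design$p
  nBlocks <- 2 + p + if (design$secondOrder) p else 0
  if (nrow(Y) != N * nBlocks) {
    stop("output table does not match the design: expected ",
         N * nBlocks, " rows, got ", nrow(Y))
  }
  nOut <- ncol(Y)
  outNames <- colnames(Y)
  pn <- design$bounds$parameter
  S1 <- matrix(NA_real_, p, nOut, dimnames = list(pn, outNames))
  ST <- S1
  pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
  S2 <- matrix(NA_real_, nrow(pairs), nOut,
               dimnames = list(paste(pn[pairs[, 1]], pn[pairs[, 2]],
                                     sep = ":"), outNames))
  Vout <- numeric(nOut)
  degenerate <- logical(nOut)
  block <- function(k) Y[(k - 1) * N + seq_len(N), , drop = FALSE]
  fA <- block(1); fB <- block(2)
  for (o in seq_len(nOut)) {
    a <- fA[, o]; b <- fB[, o]
    V <- var(c(a, b))
    Vout[o] <- V
    scale2 <- mean(c(a, b)^2)
    if (!is.finite(V) || V <= 1e-12 * max(scale2, 1e-300)) {
      degenerate[o] <- TRUE
      next
    }
    for (i in seq_len(p)) {
      abi <- block(2 + i)[, o]
      S1[i, o] <- mean(b * (abi - a)) / V
      ST[i, o] <- mean((a - abi)^2) / (2 * V)
    }
    if (design$secondOrder) {
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        bai <- block(2 + p + i)[, o]
        abj <- block(2 + j)[, o]
        closed <- mean(bai * abj - a * b) / V
        S2[k, o] <- closed - S1[i, o] - S1[j, o]
      }
    }
  }
  structure(list(S1 = S1, ST = ST,
                 S2 = if (design$secondOrder) S2 else NULL,
                 V = Vout, N = N, parameters = pn,
                 degenerate = degenerate),
            class = "sobolResult")
}

#' @export
print.sobolResult <- function(x, ...) {
  cat(sprintf("Sobol indices (N = %d):\n", x$N))
  cat("First-order (S1):\n"); print(round(x$S1, 3))
  cat("Total-order (ST):\n"); print(round(x$ST, 3))
  invisible(x)
}

#' Rank parameters by identifiability
#'
#' Orders parameters by total-order index at each output/time and flags
#' those whose ST falls below the experimental-error cutoff as
#' inestimable: their effect on that output could not be discerned from
#' measurements with that relative error.
#'
#' @param result a [sobolIndices()] result.
#' @param cutoff total-order index below which a parameter is flagged
#'   (default 0.05, a 5 percent experimental-error floor).
#' @return A data.frame with columns `output`, `parameter`, `rank`,
#'   `ST`, `inestimable`.
#' @export
rankIdentifiability <- function(result, cutoff = 0.05) {
  stopifnot(inherits(result, "sobolResult"))
  outs <- colnames(result$ST)
  if (is.null(outs)) outs <- as.character(seq_len(ncol(result$ST)))
  do.call(rbind, lapply(seq_along(outs), function(o) {
    st <- result$ST[, o]
    ord <- order(st, decreasing = TRUE)
    data.frame(output = outs[o],
               parameter = result$parameters[ord],
               rank = seq_along(ord),
               ST = st[ord],
               inestimable = st[ord] < cutoff,
               row.names = NULL)
  }))
}

#' Long-format export of Sobol indices
#'
#' Flattens a [sobolIndices()] result into the long table used for
#' heatmap plotting: one row per (output, parameter or pair, order).
#'
#' @param result a `sobolResult`.
#' @param path optional file; when given, written tab-separated.
#' @return The long-format data.frame, invisibly when `path` is given.
#' @export
sobolLongTable <- function(result, path = NULL) {
  stopifnot(inherits(result, "sobolResult"))
  outs <- colnames(result$S1)
  if (is.null(outs)) outs <- as.character(seq_len(ncol(result$S1)))
  rows <- list(
    data.frame(output = rep(outs, each = nrow(result$S1)),
               parameter = rep(rownames(result$S1), length(outs)),
               order = "S1", index = as.vector(result$S1)),
    data.frame(output = rep(outs, each = nrow(result$ST)),
               parameter = rep(rownames(result$ST), length(outs)),
               order = "ST", index = as.vector(result$ST)))
  if (!is.null(result$S2)) {
    rows <- c(rows, list(
      data.frame(output = rep(outs, each = nrow(result$S2)),
                 parameter = rep(rownames(result$S2), length(outs)),
                 order = "S2", index = as.vector(result$S2))))
  }
  tab <- do.call(rbind, rows)
  if (!is.null(path)) {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
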