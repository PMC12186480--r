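# Sobol sequence, Saltelli design and index estimators, checked against
# closed forms and an independently generated reference sequence.

ishigami <- function(X, a = 7, b = 0.1) {
  sin(X[, 1]) + a * sin(X[, 2])^2 + b * X[, 3]^4 * sin(X[, 1])
}

ishigamiS1 <- function(a = 7, b = 0.1) {
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- 8 * b^2 * pi^8 / 225
  V <- V1 + V2 + V13
  c(V1 / V, V2 / V, 0)
}

ishigamiBounds <- function() {
  data.frame(parameter = c("x1", "x2", "x3"),
             lower = rep(-pi, 3), upper = rep(pi, 3))
}

test_that("the Sobol sequence reproduces the reference low-discrepancy points", {
  # first points of the unscrambled Joe-Kuo sequence in 8 dimensions,
  # generated independently with scipy.stats.qmc.Sobol and frozen
  ref <- rbind(
    c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    c(0.75, 0.25, 0.25, 0.25, 0.75, 0.75, 0.25, 0.75),
    c(0.25, 0.75, 0.75, 0.75, 0.25, 0.25, 0.75, 0.25),
    c(0.375, 0.375, 0.625, 0.875, 0.375, 0.125, 0.375, 0.875),
    c(0.875, 0.875, 0.125, 0.375, 0.875, 0.625, 0.875, 0.375),
    c(0.625, 0.125, 0.875, 0.625, 0.625, 0.875, 0.125, 0.125),
    c(0.125, 0.625, 0.375, 0.125, 0.125, 0.375, 0.625, 0.625),
    c(0.1875, 0.3125, 0.9375, 0.4375, 0.5625, 0.3125, 0.4375, 0.9375))
  expect_equal(sobolSequence(8, 8, skip = 1), ref)
  # the zero point leads the sequence when skip = 0
  expect_equal(sobolSequence(3, 8, skip = 0)[1, ], rep(0, 8))
  expect_equal(sobolSequence(3, 8, skip = 0)[-1, ], ref[1:2, ])
  # 1-d case: the Gray-code van der Corput points (first column of the
  # multi-dimensional table)
  s1 <- sobolSequence(8, 1)
  expect_equal(s1[, 1], ref[, 1])
})

test_that("the Saltelli design has the stated block algebra and bounds", {
  b <- defaultBounds("gsa")
  d <- sobolDesign(b, N = 16, secondOrder = TRUE)
  expect_equal(nrow(d$X), 16 * (2 * 4 + 2))
  d1 <- sobolDesign(b, N = 16, secondOrder = FALSE)
  expect_equal(nrow(d1$X), 16 * (4 + 2))
  for (j in 1:4) {
    expect_true(all(d$X[, j] >= b$lower[j] & d$X[, j] <= b$upper[j]))
  }
  # AB_i blocks take column i from B and the rest from A
  A <- d$X[1:16, ]
  B <- d$X[16 + 1:16, ]
  AB1 <- d$X[2 * 16 + 1:16, ]
  expect_equal(AB1[, -1], A[, -1])
  expect_equal(AB1[, 1], B[, 1])
  expect_error(sobolDesign(data.frame(parameter = "a", lower = 1, upper = 1)),
               "degenerate")
})

test_that("Ishigami indices match their closed forms at N = 2^13", {
  d <- sobolDesign(ishigamiBounds(), N = 2^13)
  Y <- ishigami(d$X)
  res <- sobolIndices(Y, d)
  expect_equal(unname(res$S1[, 1]), ishigamiS1(), tolerance = 0.02)
  # x3 acts only through its interaction with x1: ST3 > S13 > 0, S23 ~ 0
  expect_gt(res$ST[3, 1], 0.2)
  expect_equal(unname(res$S2["x2:x3", 1]), 0, tolerance = 0.02)
  expect_gt(res$S2["x1:x3", 1], 0.2)
})

test_that("an additive linear model has S1 = ST summing to one", {
  b <- data.frame(parameter = c("x1", "x2", "x3", "x4"),
                  lower = rep(0, 4), upper = rep(1, 4))
  d <- sobolDesign(b, N = 2^12)
  a <- c(4, 3, 2, 0)   # x4 absent from the model
  Y <- d$X %*% a
  res <- sobolIndices(Y, d)
  expect_equal(sum(res$S1[, 1]), 1, tolerance = 0.05)
  Vi <- a^2 / 12
  expect_equal(unname(res$S1[, 1]), Vi / sum(Vi), tolerance = 0.02)
  expect_equal(unname(res$ST[, 1]), Vi / sum(Vi), tolerance = 0.02)
  # the absent parameter is flagged inestimable
  rk <- rankIdentifiability(res, cutoff = 0.05)
  expect_true(rk$inestimable[rk$parameter == "x4"])
  expect_false(any(rk$inestimable[rk$parameter != "x4"]))
})

test_that("index estimates converge as the base sample doubles", {
  r10 <- sobolIndices(ishigami(sobolDesign(ishigamiBounds(), N = 2^10)$X),
                      sobolDesign(ishigamiBounds(), N = 2^10))
  r11 <- sobolIndices(ishigami(sobolDesign(ishigamiBounds(), N = 2^11)$X),
                      sobolDesign(ishigamiBounds(), N = 2^11))
  expect_lt(max(abs(r10$S1[, 1] - r11$S1[, 1])), 0.02)
})

test_that("zero-variance outputs yield flagged sentinels, not zeros", {
  b <- ishigamiBounds()
  d <- sobolDesign(b, N = 64)
  Y <- cbind(const = rep(2.5, nrow(d$X)), live = ishigami(d$X))
  res <- sobolIndices(Y, d)
  expect_true(res$degenerate[1])
  expect_false(res$degenerate[2])
  expect_true(all(is.na(res$S1[, 1])))
  expect_false(any(is.na(res$S1[, 2])))
})

test_that("identifiability ranking orders by total index with cutoff flags", {
  res <- structure(list(
    S1 = matrix(c(0.5, 0.25, 0.03, 0.01), 4, 1,
                dimnames = list(c("Aj", "gamma", "Ag", "g"), "c@60")),
    ST = matrix(c(0.6, 0.3, 0.04, 0.02), 4, 1,
                dimnames = list(c("Aj", "gamma", "Ag", "g"), "c@60")),
    S2 = NULL, V = 1, N = 64,
    parameters = c("Aj", "gamma", "Ag", "g"),
    degenerate = FALSE), class = "sobolResult")
  rk <- rankIdentifiability(res, cutoff = 0.05)
  expect_equal(rk$parameter, c("Aj", "gamma", "Ag", "g"))
  expect_equal(rk$ST, c(0.6, 0.3, 0.04, 0.02))
  expect_equal(rk$inestimable, c(FALSE, FALSE, TRUE, TRUE))
  # ordering equals a brute-force sort of the ST table
  expect_equal(rk$parameter, res$parameters[order(res$ST[, 1],
                                                  decreasing = TRUE)])
})

test_that("ensemble evaluation equals row-by-row simulation and flags failures", {
  g <- fastGrid(32)
  cond <- batchConditions(15, 3600, fixConstants)
  times <- seq(600, 3600, by = 600)
  set.seed(21)
  b <- defaultBounds("gsa")
  X <- t(replicate(6, b$lower + runif(4) * (b$upper - b$lower)))
  colnames(X) <- b$parameter
  X[3, ] <- X[1, ]             # duplicate row: identical outputs
  ens <- evaluateEnsemble(X, cond, g, times,
                          solverOpts = list(maxSteps = 4e4))
  expect_true(all(ens$ok))
  expect_equal(ens$c[3, ], ens$c[1, ])
  for (i in c(2, 5)) {
    ref <- simulateBatch(cond, vecToParams(X[i, ]), g, reportTimes = times,
                         solverOpts = list(maxSteps = 4e4))
    expect_equal(ens$c[i, ], ref$c)
    expect_equal(ens$d50[i, ], unname(ref$quantiles[, "D50"]))
  }
  # a zero-growth row keeps concentration constant
  X2 <- X[1:2, ]; X2[2, "Ag"] <- 0
  ens2 <- evaluateEnsemble(X2, cond, g, times)
  expect_equal(ens2$c[2, ], rep(15, length(times)))
  # worker count does not change results (forked workers on POSIX)
  if (.Platform$OS.type == "unix") {
    ensP <- evaluateEnsemble(X, cond, g, times,
                             solverOpts = list(maxSteps = 4e4), cores = 2)
    expect_identical(ensP$c, ens$c)
    expect_identical(ensP$d50, ens$d50)
  }
  # an impossible row is flagged, not dropped
  X3 <- X[1:2, ]; X3[2, "Ag"] <- 2.5; X3[2, "g"] <- 4
  ens3 <- evaluateEnsemble(X3, cond, g, times,
                           solverOpts = list(maxSteps = 50))
  expect_false(ens3$ok[2])
  expect_match(ens3$errors[2], "step")
  expect_equal(nrow(ens3$c), 2)
})

test_that("total-order indices dominate first-order on the crystallization model", {
  # moderately sized check on the real model: ST >= S1 within estimator noise
  g <- fastGrid(48)
  cond <- batchConditions(15, 7200, fixConstants)
  times <- c(1800, 3600, 7200)
  d <- sobolDesign(defaultBounds("gsa"), N = 2^10, secondOrder = FALSE)
  ens <- evaluateEnsemble(d$X, cond, g, times,
                          solverOpts = list(maxSteps = 4e4))
  expect_true(all(ens$ok))
  colnames(ens$c) <- paste0("c@", times)
  res <- sobolIndices(ens$c, d)
  expect_true(all(res$ST - res$S1 >= -0.02))
  expect_true(all(res$S1 >= -0.02 & res$S1 <= 1.02, na.rm = TRUE))
  # late-batch concentration is dominated by the nucleation pair
  rk <- rankIdentifiability(res)
  last <- rk[rk$output == colnames(res$ST)[3], ]
  expect_true(all(c("gamma", "Aj") %in% last$parameter[1:2]))
})
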