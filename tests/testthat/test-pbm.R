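# Solver-level checks: right-hand-side structure, conservation,
# convergence order, positivity, and qualitative kinetic response.

test_that("the semi-discrete operator is quiescent without supersaturation", {
  g <- fastGrid(32)
  n0 <- rep(0, 32)
  r <- fvmRHS(n0, 1.0, fixTheta, g, fixConstants)  # c < csat
  expect_equal(r$dn, rep(0, 32))
  expect_equal(r$dc, 0)
  expect_equal(r$G, 0)
  expect_equal(r$B0, 0)
  expect_error(fvmRHS(c(NaN, rep(0, 31)), 1, fixTheta, g, fixConstants),
               "integration failure")
})

test_that("zero growth freezes the solute balance but not nucleation", {
  g <- fastGrid(32)
  pNoG <- kineticParams(fixTheta$Aj, fixTheta$gamma, 0, fixTheta$g)
  r <- fvmRHS(runif(32), 10, pNoG, g, fixConstants)
  expect_equal(r$dc, 0)        # dc/dt is proportional to G
  expect_gt(r$B0, 0)
  expect_equal(r$dn[-1], rep(0, 31))
  expect_equal(r$dn[1], r$B0 / g$widths[1])
})

test_that("one RHS application conserves crystal number when B0 = 0", {
  # single-bin pulse, constant growth: total number flux telescopes to the
  # two boundary fluxes, which are both zero
  g <- sizeGrid(nBins = 40, Lmin = 0, Lmax = 1e-4, spacing = "uniform")
  pAdv <- kineticParams(-100, 0.5, 1000, 0)   # G constant, B0 ~ e^-100
  n <- rep(0, 40); n[17] <- 1e8
  r <- fvmRHS(n, 10, pAdv, g, fixConstants)
  expect_equal(sum(r$dn * g$widths), 0, tolerance = 1e-10)
})

test_that("a quiescent or growth-free batch keeps its concentration", {
  g <- fastGrid(48)
  cond <- batchConditions(15, 3600, fixConstants)
  pNoG <- kineticParams(fixTheta$Aj, fixTheta$gamma, 0, fixTheta$g)
  res <- simulateBatch(cond, pNoG, g, reportTimes = seq(0, 3600, 600))
  expect_equal(res$c, rep(15, 7))
  # subsaturated batch: zero state is a fixed point
  condSub <- batchConditions(1.5, 3600, fixConstants)
  res2 <- simulateBatch(condSub, fixTheta, g, reportTimes = seq(0, 3600, 600))
  expect_equal(res2$c, rep(1.5, 7))
  expect_equal(max(abs(res2$finalCSD$n)), 0)
  expect_true(all(is.na(res2$quantiles)))
})

test_that("mass closure holds through a default-tolerance simulation", {
  g <- sizeGrid()   # default 300-bin, 1 nm - 50 um geometric grid
  for (c0 in c(15, 18)) {
    cond <- batchConditions(c0, 240 * 60, fixConstants)
    res <- simulateBatch(cond, fixTheta, g,
                         reportTimes = seq(0, 240 * 60, length.out = 17))
    mu3 <- apply(res$density, 2, csdMoment, grid = g, k = 3)
    closure <- abs(res$c + fixConstants$rhoc * fixConstants$kv * mu3 - c0) / c0
    expect_lt(max(closure), 0.005)
    # no dissolution: concentration trajectory is non-increasing
    expect_true(all(diff(res$c) <= 1e-12))
    expect_equal(res$S, res$c / fixConstants$csat)
    # positivity after clipping
    expect_true(min(res$density) >= 0)
  }
})

test_that("positivity holds across randomized parameter draws", {
  g <- fastGrid(48)
  set.seed(11)
  b <- defaultBounds("gsa")
  for (k in 1:5) {
    th <- vecToParamsDraw(b)
    cond <- batchConditions(15, 7200, fixConstants)
    res <- simulateBatch(cond, th, g,
                         reportTimes = seq(0, 7200, length.out = 9),
                         solverOpts = list(maxSteps = 2e5))
    expect_true(min(res$density) >= 0)
    expect_true(all(diff(res$c) <= 1e-12))
    q <- res$quantiles[, "D50"]
    q <- q[!is.na(q)]
    expect_true(all(q >= g$Lmin & q <= g$Lmax))
  }
})

test_that("advection of a smooth pulse converges at high-resolution order", {
  # B0 = 0 (Aj = -100), constant G (g = 0), uniform grid; exact solution
  # is the translated initial profile
  G_nm_min <- 6000                       # 1e-7 m/s
  G <- G_nm_min * 1e-9 / 60
  tEnd <- 1500                           # pulse travels 1.5e-4 m
  pAdv <- kineticParams(-100, 0.5, G_nm_min, 0)
  cstBig <- physicalConstants(csat = 2, kv = 1e-9)  # negligible consumption
  # the pulse must be resolved at the coarsest grid (sigma = 10 cells at
  # 100 bins); narrower pulses sit outside the asymptotic range
  pulse <- function(x) 1e6 * exp(-((x - 3e-4) / 1e-4)^2)
  err <- vapply(c(100, 400), function(nb) {
    g <- sizeGrid(nBins = nb, Lmin = 0, Lmax = 1.2e-3, spacing = "uniform")
    cond <- batchConditions(15, tEnd, cstBig)
    res <- simulateBatch(cond, pAdv, g, reportTimes = c(0, tEnd),
                         initialCSD = pulse(g$centers),
                         solverOpts = list(maxSteps = 2e6))
    exact <- pulse(g$centers - G * tEnd)
    sum(abs(res$finalCSD$n - exact) * g$widths)
  }, numeric(1))
  order <- log(err[1] / err[2]) / log(4)
  expect_gte(order, 1.5)
})

test_that("raising the nucleation pre-exponential shrinks crystals and solute alike", {
  g <- fastGrid(48)
  cond <- batchConditions(15, 240 * 60, fixConstants)
  ajs <- seq(36.5, 38.5, length.out = 5)
  out <- t(vapply(ajs, function(aj) {
    th <- kineticParams(aj, fixTheta$gamma, fixTheta$Ag, fixTheta$g)
    res <- simulateBatch(cond, th, g,
                         reportTimes = seq(0, 240 * 60, length.out = 9))
    c(cEnd = tail(res$c, 1), d50 = tail(res$quantiles[, "D50"], 1))
  }, numeric(2)))
  expect_true(all(diff(out[, "cEnd"]) <= 0))
  expect_true(all(diff(out[, "d50"]) <= 0))
})

test_that("simulation results export as delimited tables", {
  g <- fastGrid(32)
  cond <- batchConditions(15, 3600, fixConstants)
  res <- simulateBatch(cond, fixTheta, g, reportTimes = seq(0, 3600, 900))
  tf <- tempfile(); cf <- tempfile()
  writeSimulationResult(res, tf, cf)
  tab <- read.table(tf, header = TRUE, sep = "\t", check.names = FALSE)
  expect_equal(tab$c, res$c)
  expect_equal(nrow(tab), length(res$times))
  csd <- read.table(cf, header = TRUE, sep = "\t")
  expect_equal(csd$n, res$finalCSD$n)
  expect_equal(csd$center_m, g$centers)
  unlink(c(tf, cf))
})
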