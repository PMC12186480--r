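# Synthetic measurement generator and the measurement-file round trip.

test_that("noise-free generation reproduces the truth trajectory exactly", {
  cfg <- fastConfig()
  ms <- generateMeasurements(fixTheta, twoBatchProtocol(0, 0), cfg, seed = 1)
  truth <- attr(ms, "truth")
  expect_identical(unlist(truth$theta), unlist(fixTheta))
  for (e in ms$experiments) {
    tc <- truth$conditions[[as.character(e$c0)]]
    expect_equal(e$concMean, tc$cAtSamples)
    expect_equal(e$d50Mean, tc$d50End)
    # zero sample variance floors at the relative minimum
    expect_equal(e$concVar, 1e-4 * e$concMean^2)
  }
  # the truth record is an attribute, never part of the table rows
  expect_false("truth" %in% names(ms$experiments[[1]]))
})

test_that("generation is seed-deterministic and heteroscedastic", {
  cfg <- fastConfig()
  a <- generateMeasurements(fixTheta, twoBatchProtocol(), cfg, seed = 9)
  b <- generateMeasurements(fixTheta, twoBatchProtocol(), cfg, seed = 9)
  expect_identical(a$experiments, b$experiments)
  d <- generateMeasurements(fixTheta, twoBatchProtocol(), cfg, seed = 10)
  expect_false(identical(a$experiments, d$experiments))
  # relative noise implies nonconstant variances along the batch
  for (e in a$experiments) expect_gt(max(e$concVar) / min(e$concVar), 1.5)
})

test_that("replicate variances converge to the configured noise level", {
  cfg <- fastConfig()
  proto <- protocolSpec(conditions = 15, replicates = 10000,
                        concNoiseSd = 0.02, d50NoiseSd = 0.05)
  ms <- generateMeasurements(fixTheta, proto, cfg, seed = 3)
  e <- ms$experiments[[1]]
  truthC <- attr(ms, "truth")$conditions[["15"]]$cAtSamples
  expected <- (0.02 * truthC)^2
  expect_true(all(abs(e$concVar / expected - 1) < 0.05))
})

test_that("validation conditions are generated separately and disjointly", {
  expect_error(protocolSpec(conditions = c(15, 16), validation = c(16, 20)),
               "disjoint")
  cfg <- fastConfig()
  proto <- protocolSpec(conditions = 15, validation = 16)
  msv <- generateMeasurements(fixTheta, proto, cfg, which = "validation",
                              seed = 2)
  expect_equal(msv$experiments[[1]]$c0, 16)
  expect_match(msv$experiments[[1]]$id, "^val")
})

test_that("a non-crystallizing truth fails loudly with the condition named", {
  cfg <- fastConfig()
  # a surface energy this high drives the CNT barrier beyond double range:
  # the nucleation rate underflows to exactly zero
  noNuc <- kineticParams(37.7, 5, 0.682, 2.4)
  expect_error(
    generateMeasurements(noNuc, protocolSpec(conditions = 15), cfg, seed = 1),
    "c0 = 15")
})

test_that("measurement files round-trip field for field", {
  cfg <- fastConfig()
  ms <- generateMeasurements(fixTheta, twoBatchProtocol(), cfg, seed = 5)
  tf <- tempfile(); tr <- tempfile()
  writeMeasurements(ms, tf, truthPath = tr)
  back <- readMeasurements(tf)
  expect_equal(length(back$experiments), length(ms$experiments))
  for (k in seq_along(ms$experiments)) {
    a <- ms$experiments[[k]]
    idx <- which(vapply(back$experiments, `[[`, character(1), "id") == a$id)
    b <- back$experiments[[idx]]
    expect_equal(b$c0, a$c0)
    expect_equal(b$concTimes, a$concTimes)
    expect_equal(b$concMean, a$concMean, tolerance = 1e-10)
    expect_equal(b$concVar, a$concVar, tolerance = 1e-10)
    expect_equal(b$d50Mean, a$d50Mean, tolerance = 1e-10)
    expect_equal(b$d50Var, a$d50Var, tolerance = 1e-10)
  }
  # nu computed from the file equals sum over experiments of N_conc + 1
  expect_equal(measurementCount(back), measurementCount(ms))
  # the sealed truth lives in its own file, not the measurement table
  expect_false(any(grepl("truth", readLines(tf))))
  expect_true(any(grepl("sealed truth", readLines(tr))))
  unlink(c(tf, tr))
})

test_that("malformed measurement files are rejected with line numbers", {
  cfg <- fastConfig()
  ms <- generateMeasurements(fixTheta, protocolSpec(conditions = 15), cfg,
                             seed = 6)
  tf <- tempfile()
  writeMeasurements(ms, tf)
  lines <- readLines(tf)
  # negative variance
  bad <- sub("(\t[0-9.e+-]+)$", "\t-1", lines[3])
  f2 <- tempfile(); writeLines(c(lines[1:2], bad, lines[4:length(lines)]), f2)
  expect_error(readMeasurements(f2), "line")
  # unknown measurement type
  badT <- sub("\tconc\t", "\tfoo\t", lines[3])
  f3 <- tempfile(); writeLines(c(lines[1:2], badT, lines[4:length(lines)]), f3)
  expect_error(readMeasurements(f3), "type")
  # missing column
  f4 <- tempfile()
  writeLines(sub("^experiment_id\tc0", "experiment_id", lines[1]), f4)
  expect_error(readMeasurements(f4), "column|parse")
  unlink(c(tf, f2, f3, f4))
})

test_that("configuration files parse sections, arrays and defaults", {
  tf <- tempfile()
  writeLines(c(
    "# crystallizer configuration",
    "[constants]",
    "csat = 2.0",
    "T = 293.15",
    "[grid]",
    "nBins = 64",
    "Lmin = 2e-8",
    "spacing = \"geometric\"",
    "[solver]",
    "rtol = 1e-4",
    "[batch]",
    "c0 = 15",
    "duration_min = 240",
    "conditions = [15, 18, 19]"), tf)
  cfg <- readConfig(tf)
  expect_equal(cfg$constants$csat, 2.0)
  expect_equal(cfg$grid$nBins, 64)
  expect_equal(cfg$grid$spacing, "geometric")
  expect_equal(cfg$batch$conditions, c(15, 18, 19))
  obj <- configToObjects(cfg)
  expect_s3_class(obj$grid, "sizeGrid")
  expect_equal(obj$grid$nBins, 64)
  expect_equal(obj$conditions$c0, 15)
  expect_equal(obj$conditions$duration, 240 * 60)
  # malformed lines carry their line number
  f2 <- tempfile(); writeLines(c("[a]", "oops"), f2)
  expect_error(readConfig(f2), "line 2")
  f3 <- tempfile(); writeLines(c("[constants]", "kv = what"), f3)
  expect_error(readConfig(f3), "cannot parse")
  # csat is required
  f4 <- tempfile(); writeLines(c("[constants]", "kv = 0.81"), f4)
  expect_error(configToObjects(readConfig(f4)), "csat")
  unlink(c(tf, f2, f3, f4))
})
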