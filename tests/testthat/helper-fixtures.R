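# Shared fixtures for the suite. Everything is built in code; the
# synthetic world (truth kinetics + csat) is the package's documented one.

fixTruth <- syntheticTruth()
fixConstants <- fixTruth$constants
fixTheta <- fixTruth$theta

# paper-world optimum used for closed-form kinetic checks
fixThetaOpt <- kineticParams(Aj = 37.7, gamma = 0.881, Ag = 0.682, g = 2.40)

# scaled-down grid used by estimation-path tests: keeps the 5-15 um
# product well resolved while raising the first-bin width that sets the
# advective CFL step
fastGrid <- function(nBins = 64) sizeGrid(nBins = nBins, Lmin = 4e-8)

fastConfig <- function(...) {
  simConfig(fixConstants, fastGrid(), solverOpts = list(maxSteps = 4e4), ...)
}

# uniform draw of kinetic parameters inside a bounds box
vecToParamsDraw <- function(bounds) {
  v <- bounds$lower + runif(nrow(bounds)) * (bounds$upper - bounds$lower)
  kineticParams(v[1], v[2], v[3], v[4])
}

twoBatchProtocol <- function(concNoiseSd = 0.02, d50NoiseSd = 0.10) {
  protocolSpec(conditions = c(15, 18), concNoiseSd = concNoiseSd,
               d50NoiseSd = d50NoiseSd)
}
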