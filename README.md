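# crystalUQ

Parameter estimation and uncertainty quantification for batch
antisolvent protein crystallization, built around a one-dimensional
population-balance model (PBM) and designed for the *sparse offline
measurement* regime: solute concentration sampled every half hour with
a few replicate batches, and a single end-of-batch crystal size
distribution from laser diffraction.

It is aimed at process modellers in biopharmaceutical development who
need more than a single fitted parameter vector: it quantifies which
kinetic parameters are identifiable from which measurements, recovers
the full (non-Gaussian, non-elliptical) parameter uncertainty inside a
finite-sample confidence region without linearization, and propagates
that uncertainty to prediction bands on concentration and crystal-size
trajectories.

## The model and method

State: crystal number density $n(L,t)$ over size $L$ and solute
concentration $c(t)$, with supersaturation $S = c/c_{sat}$:

$$\frac{\partial n}{\partial t} + \frac{\partial (G n)}{\partial L}
 = B_0\,\delta(L - L_{min}), \qquad
 \frac{dc}{dt} = -3\rho_c k_v \int G\,n\,L^2\,dL$$

$$B_0 = e^{A_j} S \exp\!\left(-\frac{16\pi\gamma^3 v_0^2}
 {3k_B^3T^3\ln^2 S}\right) \quad\text{(CNT nucleation)}, \qquad
 G = A_g (S-1)^g \quad\text{(power-law growth)}$$

The four kinetic parameters $\theta = (A_j, \gamma, A_g, g)$ are
estimated from data. The pipeline:

1. **Simulate** (`simulateBatch`): high-resolution finite-volume
   discretization (Superbee flux limiter, geometric 300-bin grid over
   1 nm–50 µm) integrated by an adaptive SSP Runge–Kutta scheme under
   an advective CFL constraint (compiled core).
2. **Identifiability** (`sobolDesign`, `evaluateEnsemble`,
   `sobolIndices`, `rankIdentifiability`): time-indexed first-,
   second- and total-order Sobol indices of $c(t)$ and $D_{50}(t)$,
   with a 5% experimental-error cutoff below which a parameter is
   flagged inestimable.
3. **Fit** (`fitDE`, `mleLoss`): variance-weighted maximum-likelihood
   loss (each squared misprediction scaled by its replicate-derived
   measurement variance) minimized by differential evolution.
4. **Confidence region** (`fisherBound`): the loss sub-level set
   $\mathrm{MLE}(\theta) \le \mathrm{MLE}(\theta_{opt})\,
   (1 + \tfrac{p}{\nu-p} F^{\alpha}_{p,\nu-p})$, with $\nu$ the total
   measurement count.
5. **Posterior** (`abcdeSample`, `posteriorQuantiles`,
   `spearmanMatrix`, `exportCorner`): likelihood-free ABC with
   differential-evolution moves fills the region with a uniform
   population; summaries are 16/50/84% quantiles, rank correlations
   and corner-plot data.
6. **Propagate** (`propagatePosterior`, `asymmetryReport`): Monte
   Carlo simulation of every accepted parameter vector collapsed into
   centered 25/50/75% bands, the full envelope, and endpoint
   D50 mean ± sd.

A synthetic-data module (`protocolSpec`, `generateMeasurements`)
emulates the measurement protocol — 30-minute sampling, 3 replicates,
one endpoint D50, heteroscedastic relative Gaussian noise — from known
ground-truth kinetics, so the whole pipeline is testable end to end
without laboratory data.

## Worked example

Simulate a batch at the package's documented synthetic-world truth
(`syntheticTruth()`: $A_j = 37.7$, $\gamma = 0.70$ mJ m$^{-2}$,
$A_g = 0.682$ nm min$^{-1}$, $g = 2.40$, $c_{sat} = 2$ kg m$^{-3}$ —
a placeholder world, not measured values), generate noisy
measurements, refit, and summarize:

```r
library(crystalUQ)
tw   <- syntheticTruth()
grid <- sizeGrid(nBins = 64, Lmin = 4e-8)       # scaled-down grid
cfg  <- simConfig(tw$constants, grid, solverOpts = list(maxSteps = 4e4))

res <- simulateBatch(batchConditions(c0 = 15, duration = 240 * 60,
                                     constants = tw$constants),
                     tw$theta, grid)
res
#> Batch PBM simulation: c0 = 15 kg m^-3, 14400 s, 64 bins
#>   final c = 10.23 kg m^-3 (S = 5.12), final D50 = 9.86 um
#>   3182 steps (207 rejected)
```

A batch starting at 15 mg/mL consumes about a third of its protein in
four hours and leaves ~10 µm crystals (volume-weighted median).

```r
ms <- generateMeasurements(tw$theta,
                           protocolSpec(conditions = c(15, 18)),
                           cfg, seed = 42)
ms
#> Measurement set: 2 experiment(s), nu = 18 measurements
#>   est_c0_15: c0 = 15, 8 concentration points, D50 = 10.3 um at 240 min
#>   est_c0_18: c0 = 18, 8 concentration points, D50 = 6.88 um at 240 min

fit <- fitDE(ms, cfg, nPop = 64, nGen = 96, CR = 0.9, seed = 1)
fit
#> Variance-weighted MLE fit (differential evolution)
#> Kinetic parameters:
#>   A_j   = 37.21  [log # m^-3 s^-1]
#>   gamma = 0.6951  [mJ m^-2]
#>   A_g   = 0.7285  [nm min^-1]
#>   g     = 2.39  [-]
#>   MLE_min = 8.385, 95% region bound = 15.84 (p = 4, nu = 18)
```

With 2% concentration noise and 10% D50 noise, the refit lands close
to the generating kinetics (37.7, 0.70, 0.682, 2.40); the fitted loss
(8.4) is commensurate with nu = 18 noisy measurements, and
`fisherBound` scales it to the 95% confidence-region threshold (15.8).
Sampling the region:

```r
post <- abcdeSample(function(v) mleLoss(v, ms, cfg), fit$mleBound,
                    defaultBounds("fit"), popSize = 128, nGen = 32,
                    seed = 2)
posteriorQuantiles(post)
#>              q16        q50        q84
#> Aj    36.5057735 37.2700032 37.8440086
#> gamma  0.6859344  0.6949291  0.7038415
#> Ag     0.6601313  0.7291524  0.8080398
#> g      2.3585762  2.3900974  2.4269002
```

Each 16–84% interval brackets the generating value; the growth
pre-exponential is the least constrained (a single endpoint size
measurement per batch carries all the growth information). At this
reduced population a few members can remain marginally outside the
region, which the sampler reports as a warning.

## Command line

A thin CLI over the same functions ships in `inst/scripts/crystaluq`
(subcommands `simulate`, `synth`, `fit`, `gsa`, `abc`, `propagate`),
driven by a small `[section] key = value` configuration file; see
`?readConfig`.
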