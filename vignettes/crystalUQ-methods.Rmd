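---
title: "Population-balance parameter estimation and uncertainty quantification: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-balance parameter estimation and uncertainty quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

crystalUQ simulates an unseeded, isothermal, well-mixed batch
crystallizer in which a protein is driven out of solution by a
precipitant. The state is the crystal number density $n(L, t)$
(# m$^{-3}$ m$^{-1}$) over crystal size $L$ together with the solute
concentration $c(t)$ (kg m$^{-3}$, numerically equal to mg/mL). The
governing equations are the one-dimensional population balance with a
nucleation boundary source, and a solute mass balance:

$$\frac{\partial n}{\partial t} + \frac{\partial (G\,n)}{\partial L}
  = B_0\,\delta(L - L_{min}), \qquad n(L, 0) = 0,$$

$$\frac{dc}{dt} = -3 \rho_c k_v \int_0^\infty G\, n\, L^2\, dL .$$

The driving force is the supersaturation ratio $S = c / c_{sat}$.
Kinetics follow classical nucleation theory and an empirical power law:

$$B_0 = e^{A_j}\, S\, \exp\!\left(-\frac{16 \pi \gamma^3 v_0^2}
 {3 k_B^3 T^3 \ln^2 S}\right), \qquad G = A_g (S - 1)^g .$$

Modeling assumptions, stated once and relied on throughout: no
aggregation, breakage, or dissolution (both rates clamp to zero for
$S \le 1$); size-independent growth; isothermal operation (no energy
balance); a clear-liquor start. These are the standard assumptions for
stirred lysozyme-type batches; they also mean the model cannot
represent secondary nucleation bursts or attrition-dominated systems.

The four regressed parameters, their units, and the literature-derived
boxes used by the package (`defaultBounds()`):

| parameter | meaning | units | GSA box | search box |
|---|---|---|---|---|
| $A_j$ | log nucleation pre-exponential | log(# m$^{-3}$ s$^{-1}$) | 22.7–32.9 | 10–60 |
| $\gamma$ | surface energy | mJ m$^{-2}$ | 0.32–1.0 | 0.15–1.2 |
| $A_g$ | growth pre-exponential | nm min$^{-1}$ | 0.394–0.876 | 0.15–2.5 |
| $g$ | growth exponent | – | 2–3 | 1–4 |

The log transform on the nucleation pre-exponential keeps its scale
comparable to the other parameters during optimization; the package
reads the CNT prefactor as $e^{A_j} \cdot S$ (the transform applies to
the pre-exponential constant alone). Physical constants default to
$k_v = 0.81$, $\rho_c = 1240$ kg m$^{-3}$, $v_0 = 2.97\times10^{-26}$
m$^3$ (a molecular volume; the exponent of the CNT barrier is
dimensionless only with $v_0$ in m$^3$), $T = 293.15$ K.

**The saturation concentration has no default.** $c_{sat}$ depends on
buffer, pH, precipitant load and temperature, and must be supplied by
the user (`physicalConstants(csat = ...)`). The package's synthetic
world (`syntheticTruth()`) uses a placeholder of 2.0 kg m$^{-3}$,
documented as synthetic-world truth and nothing more.

Unit conventions: SI internally (m, s, kg m$^{-3}$, J m$^{-2}$);
$A_g$ in nm min$^{-1}$ and $\gamma$ in mJ m$^{-2}$ are converted at
the type boundary (`paramsSI()`), never inside the numerics.

# Numerics

## Discretization

The size domain (default 1 nm – 50 µm) spans 4.5 decades, so the
default 300-bin grid is geometric (constant edge ratio); a uniform
grid would spend nearly all bins on the top decade. Uniform spacing is
available by flag for convergence studies.

The advective term uses a high-resolution finite-volume scheme: upwind
face fluxes plus a Superbee-limited MUSCL correction built from
one-sided slopes, written division-free so it stays well-defined on
geometric grids and reduces to the classical flux-limiter form on
uniform ones. The nucleation source enters the first cell as
$B_0 / w_1$ — the conservative finite-volume reading of the boundary
delta source, consistent with both the $\delta(L - L_{min})$ source
and the inflow-boundary formulations. The outflow face at $L_{max}$
carries zero flux; the domain is chosen large enough that no
appreciable mass reaches it.

## Time stepping

The method-of-lines system is integrated with an explicit three-stage
strong-stability-preserving Runge–Kutta scheme (Shu–Osher form) with
an embedded second-order (SSP-RK2) error estimate. A step is accepted
when the weighted RMS error passes `rtol` = 1e-4, `atol` = 1e-6
(defaults), and the step size additionally satisfies the advective CFL
restriction $\Delta t \le 0.9\, \min_i w_i / G$. Two numerical choices
deserve a note:

* the absolute tolerance for the density block is scaled by the
  current maximum density. Number densities legitimately reach
  $10^{18}$ # m$^{-3}$ m$^{-1}$ while starting at zero; a fixed
  absolute tolerance of $10^{-6}$ would be meaningless across that
  range.
* negative densities produced at the tolerance level by the limited
  scheme (the limiter's positivity guarantee is CFL-conditional) are
  clipped to zero after each accepted step; the clipped number is
  accumulated in `stats$clippedNumber` so a pathological run is
  visible rather than silent.

Quality gates, exercised in the test suite: solute mass closure
$|c + \rho_c k_v \mu_3 - c_0| / c_0 \le 0.5\%$ throughout
default-grid simulations, and an observed L1 convergence order
$\ge 1.5$ for a translated smooth pulse between 100 and 400 uniform
bins. Two caveats discovered while validating: TVD limiters are
formally first-order at nondegenerate solution extrema (the classical
$4/3$ L1-order result), so the convergence test uses a pulse resolved
by $\approx 10$ cells at the coarsest grid, where the observed order
is 1.6; and mass closure degrades on very coarse geometric grids
(about 1–4% at 64 bins) purely from the quadrature mismatch between
edge fluxes and the cell-centered consumption integral — the 0.5%
gate applies to the default 300-bin grid.

## Size quantiles

`csdQuantile()` reports D10/D50/D90 with volume weighting by default —
the convention of laser-diffraction analyzers, which measure a
volume-based distribution; number weighting is available. The
cumulative weight is assigned to bin centers with the half-bin (Hazen)
convention and inverted by linear interpolation between occupied
centers, so a distribution concentrated in one bin returns that bin's
center for any quantile. Quantiles of an empty distribution are an
error, and trajectory quantiles before any crystal mass exists are
`NA` — downstream code treats the induction period explicitly rather
than inventing a size.

# Global sensitivity analysis

Identifiability is quantified with variance-based Sobol indices of
$c(t)$ and $D_{50}(t)$ with respect to the four kinetic parameters,
over the literature GSA box. The package estimates indices directly
with Monte Carlo estimators on a Saltelli cross-sampling design built
from an unscrambled Joe–Kuo Sobol sequence (first-order:
Saltelli 2010; total-order: Jansen; closed second-order:
Saltelli 2002, reported as the closed pair effect minus the two
first-order terms). A surrogate-based route (RS-HDMR) exists in GUI
tools for the same quantities; direct estimation was chosen to keep
the pipeline scriptable and dependency-free, at the cost of more model
evaluations — with $N = 8192$ base points and second-order blocks the
design needs $N(2p+2) = 81{,}920$ simulations.

Design notes: outputs with numerically zero variance return flagged
`NA` sentinels, never a fake zero index; report times for GSA start
after the induction period ($D_{50}$ is undefined before the first
crystals), and the report-time grid is user configuration, since
useful measurement times depend on the batch; parameters whose
total-order index falls below the 5% cutoff — the expected relative
experimental error — are flagged inestimable by
`rankIdentifiability()`.

On the synthetic world the indices reproduce the qualitative
identifiability structure that motivates measuring both outputs: the
surface energy dominates the concentration output with the nucleation
pre-exponential second, while the growth parameters are nearly
invisible in $c(t)$ and must be identified from the size quantile,
where the growth exponent dominates early in the batch.

# Estimation: loss, optimizer, confidence region

The measurement container mirrors the sparse offline regime: per
experiment, replicate-averaged concentrations at the sample times with
replicate-derived variances, plus exactly one endpoint D50 with its
variance. The variance-weighted loss is

$$\mathrm{MLE}(\theta) = \sum_e \left[ \sum_m
  \frac{(c^{avg}_{e,m} - c^{mod}(t_m | \theta))^2}{\sigma^2_{c,e,m}}
  + \frac{(D_{50,e}^{avg} - D_{50}^{mod}(t_{end} | \theta))^2}
         {\sigma^2_{D50,e}} \right],$$

the Gaussian negative log-likelihood up to constants. Concentration
terms are **summed, not averaged**: each measurement keeps its own
variance weight, which is what lets low-variance points dominate the
fit. Model values at measurement times come from monotone
piecewise-linear interpolation of a report grid forced at least 4
times denser than the sampling schedule. Replicate variances are
floored at $10^{-4}$ of the squared mean (configurable): replicates
that agree exactly happen with three samples, and a zero variance
would give one point infinite weight. A failed simulation returns
`+Inf` with the reason attached, keeping the loss total so
population-based optimizers simply avoid that region.

Minimization uses classic differential evolution (rand/1/bin,
$F = 0.7$, $CR = 0.5$, 512 particles and 512 generations by default,
fixed generation budget, no early stopping). Out-of-bounds mutants are
reflected back into the box, which preserves search-space volume near
bounds — relevant because early fits tend to sit on bound faces.
Determinism is per-seed. One practical note from validating at reduced
budgets: the loss surface has strongly correlated pairs ($A_j$ with
$\gamma$, $A_g$ with $g$ — each pair shares a kinetic law), and with
$CR = 0.5$ the coordinate-wise crossover stalls on those curved valley
floors when the evaluation budget is thousands rather than hundreds of
thousands. Raising the crossover to $CR = 0.9$ makes DE close to
rotation invariant and reliably drives the noise-free refit loss to
$\sim 10^{-4}$ at a 64×128 budget; the scaled tests therefore run with
$CR = 0.9$ while the package default remains the classic 0.5.

The confidence region is the loss sub-level set

$$\mathrm{MLE}(\theta) \le \mathrm{MLE}(\theta_{opt})
  \left(1 + \frac{p}{\nu - p} F^{\alpha}_{p,\,\nu-p}\right),$$

with $p = 4$ parameters and $\nu = \sum_e (N^{conc}_e + 1)$ total
measurements — each experiment contributes its concentration samples
plus one endpoint D50. The Fisher distribution (not $\chi^2$) is used
because the variances are themselves estimated from a handful of
replicates. `fisherBound()` implements the scalar formula and refuses
$\nu \le p$.

# Posterior recovery inside the region (ABCDE)

Likelihood-free recovery of the parameter distribution treats the
fitted loss as an ABC distance: every $\theta$ whose loss is below the
Fisher bound is "inside", and the target is the uniform distribution
over that region. The sampler is a population MCMC with
differential-evolution proposals:

* **in-region members** move by the symmetric DE-MC kernel
  $\theta^* = \theta_i + \gamma_{DE}(\theta_m - \theta_n) +
  \varepsilon$, with $\gamma_{DE} = 2.38/\sqrt{2p}$ jittered by
  ±10% and a small uniform $\varepsilon$ (the standard adaptive-DE
  heuristic). The difference-vector proposal is symmetric given the
  rest of the population, so acceptance "inside the region" is exactly
  a Metropolis step for the uniform target: the stationary law on the
  region is uniform, and the proposal scale adapts itself to the
  region's shape — which is what lets the sampler trace curved,
  non-elliptical regions that a Gaussian approximation would miss.
* **members above the current threshold** move by a current-to-best
  descent step, $\theta^* = \theta_i + 0.8(\theta_{best} - \theta_i) +
  0.3\gamma_{DE}(\theta_m - \theta_n) + \varepsilon$, accepted when it
  enters the threshold or strictly improves their own loss. This is
  the migration idea of DE-based ABC samplers, and it is what makes
  small generation budgets work: with a plain symmetric kernel and 32
  generations, an entire 128-member population can remain stranded in
  the prior box (we measured exactly that — 0 of 128 members inside
  after 32 generations), because a handful of full-vector DE moves
  cannot descend four orders of magnitude of loss. With the descent
  move the same budget brings every member inside by mid-run, leaving
  the remaining generations for in-region mixing.

The acceptance threshold anneals geometrically from the initial
population's worst finite loss down to the Fisher bound by 75% of the
generation budget, then holds — consistent with population samplers
that converge into the credible region in roughly the first
three-quarters of their run. The population is initialized from the
uniform prior over the search box (no assumptions on parameter
distributions), reflection keeps proposals inside the prior support,
and a population that still has members outside the region at
termination triggers a warning, not an error: an under-converged table
is visible and diagnosable. One documented consequence of threshold
acceptance: a member already inside the region may accept a move to a
*higher* loss (anywhere under the threshold) — that is what makes the
stationary law uniform rather than concentrating at the optimum, so
per-member loss trajectories are not monotone by design.

Summaries: per-parameter 16/50/84% empirical quantiles
(type-7 linear interpolation), the Spearman rank-correlation matrix
(average ranks on ties; zero-variance columns yield `NA` sentinels),
and a corner-plot export with histogram densities, a scatter
subsample, and 1σ/2σ kernel-density contour levels (levels enclosing
39.35% and 86.47% of mass, the bivariate normal conventions) on
standardized coordinates.

# Uncertainty propagation

`propagatePosterior()` simulates every accepted parameter vector
(optionally an evenly-spaced subsample, so results stay deterministic)
and collapses the trajectories into **centered bands**: the X% band
spans the $(50 - X/2)$ to $(50 + X/2)$ percentiles at each report
time — this definition is stated here prominently because "centered
region" admits several readings. The full envelope is the pointwise
min–max. The endpoint D50 is summarized as mean ± one sample standard
deviation (configurable reading; a quantile half-width is equally
defensible). Failed rows are excluded and counted, never silently
dropped. `asymmetryReport()` quantifies the non-Gaussian character of
the propagated uncertainty as the signed width imbalance of the
envelope about the optimal trajectory,
$(w_{up} - w_{down})/(w_{up} + w_{down})$ — propagating a skewed,
bounded parameter posterior through nonlinear kinetics produces
uncertainty that extends asymmetrically (typically upward in
concentration), and this is the one-number-per-time record of that.

# The synthetic world

`generateMeasurements()` emulates the statistical structure of sparse
offline batch measurements: concentration sampled every 30 minutes
over a 4-hour batch, 3 replicate experiments per condition, one
endpoint D50, independent relative Gaussian noise (2% on
concentration, 10% on D50 by default), replicate means and pooled
floored variances. Relative noise makes the variances heteroscedastic
along the batch, which is the premise of variance weighting in the
loss. The generating kinetics (`syntheticTruth()`:
$A_j = 37.7$, $\gamma = 0.70$ mJ m$^{-2}$, $A_g = 0.682$ nm min$^{-1}$,
$g = 2.40$, with $c_{sat} = 2$ kg m$^{-3}$) were chosen once, inside
the literature boxes, so that the default conditions
($c_0 = 15, 18, 19$ estimation; $16, 20$ validation) nucleate, consume
a substantial fraction of the supersaturation within the batch, and
finish with crystals in the 5–15 µm range — qualitatively the behavior
of stirred antisolvent lysozyme batches. The noise-free truth record
(parameters and trajectories) is attached as a sealed attribute and
written, on request, to a separate file so fitting code cannot consume
it by accident.

What the generator does **not** emulate: instrument physics (UV–vis
absorbance nonlinearity, diffraction optics), filtration losses,
sampling-volume depletion, non-Gaussian or correlated noise, drifting
baselines. Passing the recovery tests therefore demonstrates that the
estimation machinery is self-consistent under the stated noise model —
not that the model or the noise model is correct for any particular
real protein system.

# Problem sizes used by the test suite

The full-scale defaults (300 bins, 8192-point GSA designs, 512×512 DE,
4096×128 ABCDE) are the production configuration. The test suite
exercises the complete pipeline end-to-end at deliberately reduced
sizes, chosen as the smallest configurations at which each property is
meaningfully tested: a 64-bin grid on 40 nm – 50 µm for
estimation-path tests (the first geometric bin sets the advective CFL
step, and nothing in a 5–15 µm product depends on sub-40-nm
resolution), two estimation conditions, 64×128 DE for the noise-free
refit, 24×40 DE plus 128×32 ABCDE per noisy replicate, and
evenly-subsampled 64-trajectory propagation. The solver step-budget
cap (`maxSteps`) converts pathological corner-of-the-box kinetics
(growth rates hundreds of times the fitted scale) into clean `+Inf`
losses instead of minute-long simulations.

# Known limitations

* The explicit CFL-bound integrator is the right tool for the
  advection-dominated regime modeled here, but it makes extreme
  growth-rate corners of the search box expensive; they are handled by
  the step budget rather than an implicit scheme.
* Mass closure on coarse geometric grids (≤ 64 bins) is a few percent;
  use the default grid when closure matters.
* The ABCDE table is a single terminal generation; its quantiles carry
  the Monte Carlo error of the population size (about $0.01$–$0.02$
  on a unit-width region at 4096 members).
* One-dimensional size coordinate: needle-like crystals with two
  growth axes, aggregation and breakage are out of scope.
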