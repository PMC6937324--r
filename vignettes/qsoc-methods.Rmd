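---
title: "Methods: the continuous-quality SOC decay model and its calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the continuous-quality SOC decay model and its calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsoc)
```

## The model

`qsoc` models the decay of soil organic carbon (SOC) in long-term bare
fallow — field plots kept free of vegetation so that carbon inputs are
effectively zero and pure decay is observed. The model is first-order in
the stock, but instead of discrete pools it carries a *continuous quality*
distribution: every unit of carbon has a dimensionless quality `q`
inversely related to its persistence, and microbial reprocessing pushes
the stock-average quality $\bar q$ down over time.

Under zero input, with the stock at steady state $C_{ss}$ when the fallow
starts, both the average quality and the stock have closed forms:

$$\bar q(t) = \frac{q_0}{\left(1 + \beta\,\eta_{11}\,u_0\,r_e\,q_0^{\beta}\,t\right)^{1/\beta}},
\qquad
C(t) = C_{ss}\left(\frac{\bar q(t)}{q_0}\right)^{\frac{1-e_0}{\eta_{11} e_0}-\beta}.$$

The plant-derived pool (material still at the input quality $q_0$) obeys a
linear mass balance whose zero-input solution is exponential,
$C_p(t)/C_p(0) = e^{-k t}$ with $k = u_0\,r_e\,q_0^{\beta}/e_0$. The
measured observable is the *fraction* of plant-derived carbon remaining,
normalized to its value at the start of the fallow, so the unknown
historical input rate cancels. Stocks and plant fractions are calibrated
simultaneously.

Two structural properties matter downstream:

* **No inert pool.** $C(t)$ decreases strictly at every finite time and
  tends to zero; there is no recalcitrant floor. Projections therefore
  keep declining at 300, 1000, 3000 and 10 000 years.
* **Quality convergence.** For large $t$, $\bar q(t)$ becomes independent
  of $q_0$: sites that start with different input qualities converge to a
  common trajectory, which is why generic kinetics can describe old SOC.

### Parameters

| Parameter | Meaning | Scope | Prior (default) |
|---|---|---|---|
| $u_0$ | decomposer metabolic rate (yr⁻¹ on the quality scale; the decomposer carbon concentration is absorbed into it) | generic | Uniform(0, 0.98) |
| $\eta_{11}$ | rate of decrease in quality (–) | generic | Uniform(0, 0.72) |
| $q_0$ | initial litter quality (–) | local | Normal(1.08, 0.108) on [0.5, 1.5] |
| $e_0$ | decomposer (carbon-use) efficiency (–) | local | Normal(0.3, 0.03) on [0, 0.6] |
| $\beta_0$ | edaphic shape offset (–) | local | Normal(0.7, 0.07) on [0.469, 0.931] |

The effective shape parameter is $\beta = \beta_0 + 0.01\,\chi$ with
$\chi$ the measured clay percentage. The generic parameters get wide
uniform priors (±100 % of literature values) because they are latent and
hard to measure; the locals get truncated normals with a 10 % coefficient
of variation around literature values, the $\beta_0$ truncation at ±33 %.

A parameter set is *structurally valid* only if all positivity constraints
hold, the stock exponent $(1-e_0)/(\eta_{11} e_0) - \beta$ is positive,
and the equilibrium-quality numerator $1 - e_0 - \eta_{11} e_0 \beta$ is
positive. `validate_parameters()` reports the violated rules; the sampler
treats invalid proposals as zero-probability rather than raising.

### Numerical choices

* As $\beta \to 0$ the quality solution degenerates; below
  $\beta = 10^{-8}$ the code switches to the exponential limit
  $q_0\exp(-\eta_{11} u_0 r_e q_0^{\beta} t)$. The crossover is tested
  against the limit at $\beta = 10^{-6}$ (relative error $< 10^{-4}$).
* $(1+\beta a t)^{-1/\beta}$ is evaluated as
  $\exp(-\mathrm{log1p}(\beta a t)/\beta)$ for accuracy at small
  $\beta a t$.
* Time is continuous, in years since the start of the experiment
  ($t = 0$ at first sampling).

### The plant-fraction rate convention

Two renderings of the plant-pool decay exponent circulate in the
published formulations and are reciprocals of each other. The mass
balance of the pool implies the rate $k = u_0 r_e q_0^{\beta}/e_0$
(dimensionally a decomposition rate, and consistent with the steady-state
pool $e_0 I/(u_0 q_0^{\beta})$); one printed rendering instead shows
$e_0/(u_0 r_e q_0^{\beta})$. `plant_fraction()` defaults to the
mass-balance-consistent rate (`"decay_rate"`) and exposes the printed
reciprocal behind `rate_convention = "reciprocal"` for comparison. The
climate scalar $r_e$ rescales decomposer metabolism, so it accompanies
$u_0$ everywhere $u_0$ appears, including in this rate.

## Climate reduction scalars

Weather enters as annual averages. Temperature uses an Arrhenius-type
response with activation energy 59.46 kJ mol⁻¹ (the average measured on
decades-old bare-fallow SOC), normalized to 1 at 35.14 °C and clamped
above it; the classic empirical soil-respiration parameterization is
available behind `form = "lloyd_taylor"`. Moisture uses the soil water
saturation fraction from a single-bucket annual water balance
(precipitation in, actual evapotranspiration bounded by potential ET,
overflow drains; water conserved at every step), with water-holding
capacity from a linear texture pedotransfer rule. The moisture response
itself is a pluggable curve; the default is a documented piecewise
polynomial — zero at dryness, rising to 1 at an optimum saturation of
0.65, declining quadratically to 0.6 at full saturation — because the
coefficients of the cited external curve are not reproducible from the
source and a config-stated default keeps calibrations reproducible.
Potential ET uses the FAO-56 Penman-Monteith reference form on annual
means (×0.9, an empirical bare-soil scaling); with radiation, humidity or
wind missing it falls back to the Hamon temperature-based approximation
with a warning.

The interaction is multiplicative, $r_e = r_{temp} \times r_{moist}$ per
site-year. To compare sites across climatic zones the per-site mean
$r_e$ is divided by the grand mean over sites, so the normalized scalar
averages exactly 1 across the network and $u_0$ refers to the network's
average climate. Averaging is per site over years first, then across
sites; future projections use each site's constant mean normalized
scalar. (Whether normalization should happen per year or per period is
genuinely open; per-site-over-years was chosen and is stated here.)

## Calibration

The hierarchical structure is: generic $(u_0, \eta_{11})$ shared by all
sites; local $(q_0, e_0, \beta_0)$ per site. Observation series are
linearly interpolated to annual resolution before fitting (endpoints
preserved; `annualize = FALSE` fits raw times only). Errors are
independent Gaussians whose standard deviation is the average replicate
SD of each series — applied to the annualized series, mirroring the
interpolate-then-fit protocol; the plant-fraction error SD defaults to
the series' replicate SD when present, else 10 % of the initial fraction.
Interpolation does inflate the effective number of observations; that is
a property of the protocol being mirrored, not an accident, and the flag
above opts out.

`run_mcmc()` is a blocked adaptive random-walk Metropolis-Hastings
sampler (compiled, seeded, fully reproducible):

* the generic pair is proposed jointly and accepted against the pooled
  likelihood over all sites;
* each site's locals are proposed jointly against that site's own
  likelihood;
* one additional joint proposal over the full parameter vector per
  iteration traverses correlations that cross blocks (notably
  $\eta_{11}$ with the site efficiencies), which component blocks alone
  mix through very slowly;
* proposal covariances are adapted from the running sample covariance of
  each block (adaptive-Metropolis style) and a global scale is tuned
  towards ~30 % acceptance, both **during burn-in only** — the
  post-burn-in kernel is a fixed Metropolis kernel, so the usual ergodic
  guarantees apply. The covariance estimate restarts halfway through
  burn-in to drop the initial transient.

Chains start at independent prior draws, rejection-resampled to
structural validity. Four chains of 100 000 iterations with 10 000
burn-in are the defaults (one published account of the protocol states
300 000 elements, another 100 000 iterations for the same runs; the
count is config-controlled with 100 000 as default). Every kept element
records the full parameter set, log prior, log likelihood, log posterior
and per-site SOC RMSE. Convergence is summarised by the classic
Gelman-Rubin potential scale reduction factor
($\sqrt{((n-1)/n\,W + B/n)/W}$), with values below 1.1 read as adequate
mixing. Setting `flat_likelihood = TRUE` replaces the likelihood by a
constant, which turns the sampler into a prior sampler and is used to
verify that every prior marginal is recovered (validity truncation
removes only ~10⁻⁷ of prior mass, far below detectability).

Under `parameterization = "generic"` the locals are shared by all sites
too — the configuration used for first-stage sensitivity screening, and
the baseline against which the local parameterization's RMSE improvement
is judged.

## Sensitivity analysis

The HSY (regionalized) scheme splits the chain's parameter sets into
*behavioral* and *non-behavioral* at the 5 % quantile of the RMSE
distribution (per site). The threshold is the empirical
lower-interpolation (type 1) order statistic; ties at the threshold are
resolved by including equal-RMSE elements in chain order up to the exact
count $\lceil 0.05 n\rceil$, so the behavioral bin size is deterministic.
The Kolmogorov-Smirnov distance between the two bins' marginals of a
parameter measures how strongly that parameter controls performance;
distances are averaged across sites and ranked. An inert parameter's KS
distance tends to zero with chain length, but note the sampling floor of
a 5 %/95 % split: at $n = 10^4$ the null expectation is ~0.04, so small
distances should be read against that floor. The module accepts any
chain; the two-stage protocol (generic calibration → HSY → local
calibration) is reproduced by running `run_mcmc()` twice with the two
parameterizations.

## Projections and fit reports

`project_stocks()` evaluates the closed-form stock at each horizon for
every (thinned, default every 10th) post-burn-in draw using the site's
constant mean normalized climate scalar, and reports the median and
empirical 2.5/97.5 percentiles. `report_fit()` gives the best-RMSE
trajectory, the pointwise envelope of draws within the 95 % RMSE
quantile, and RMSE summaries (mean, kernel-density mode, percent of the
final observed stock).

## The synthetic-data generator

`simulate_network()` draws site profiles within the spans of the European
bare-fallow network: initial stocks 40–100 Mg C ha⁻¹, clay 7–36 %, mean
annual temperature 5.4–10.7 °C, annual precipitation 533–862 mm,
durations 30–80 years. Its structural assumption mirrors the model's:
true $u_0$ (0.05) and $\eta_{11}$ (0.36) are shared across sites, true
$q_0$ is heterogeneous (0.9–1.3), $e_0 = 0.3$ and $\beta_0 = 0.7$ at
their literature centres. Weather is Gaussian interannual fluctuation
around the site normals (sd 0.8 °C; precipitation CV 12 %, truncated at
zero). Observations are the closed-form model plus homoscedastic Gaussian
noise — SOC sd 1.5 Mg C ha⁻¹ (within the range of the real archives'
replicate SDs, 0.6–5.9), plant fractions sd 0.05 truncated to [0, 1] —
sampled on an irregular schedule (first and last year always included) or
annually. Everything is deterministic from the seed.

What the generator does **not** emulate: non-Gaussian or heteroscedastic
measurement error, bulk-density drift and equivalent-soil-mass
corrections, residual inputs (weeds, deposition), priming, erosion, or
within-year climate structure. Passing tests therefore show that the
pipeline recovers what it assumes — correct code, identifiable
parameters, calibrated uncertainty under the stated error model — not
that the error model is right for any particular field archive. Note
also that the generator's true kinetics decay considerably faster on
centennial scales than field-calibrated values; this makes recovery
tests sharper but means projected magnitudes should not be compared to
field expectations.

## Problem sizes used by the test suite

The suite calibrates scaled-down chains chosen as the smallest runs whose
diagnostics are stable: prior recovery uses 4 chains × 55 000 iterations
thinned by 20 (10⁴ near-independent post-burn-in draws; raw MH draws are
autocorrelated and would inflate the KS statistic); parameter recovery
uses ten independent 4-site networks (40 annual observations per site)
each calibrated with 4 chains × 20 000 iterations and 5 000 burn-in,
checking 95 % CI coverage of the true generic values and every $q_0$,
and the Spearman correlation between true and recovered $q_0$;
convergence is judged by the maximum Gelman-Rubin factor over
$u_0, \eta_{11}$ and the $q_0$s on the same configuration.

## Known limitations

* The Gaussian error model with a single SD per series ignores the
  correlation that annual interpolation introduces between neighbouring
  pseudo-observations; credible intervals on real irregular archives are
  accordingly somewhat optimistic (the `annualize = FALSE` flag avoids
  this at the cost of fewer points).
* $q_0$, $e_0$ and $\beta_0$ trade off along a likelihood ridge; with a
  single site or short series, $q_0$ is informed as much by its prior as
  by the data. Multi-site networks with plant-fraction series are what
  make the generic/local split identifiable.
* The moisture default is a stand-in curve with documented shape, not a
  fitted response; users with site measurements should plug in their own.
* Activation energy is constant; temperature sensitivity of old versus
  young SOC is outside the model's structure.
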