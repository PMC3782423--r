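---
title: "Statistical and dynamic prediction of occluded trajectories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical and dynamic prediction of occluded trajectories: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajcomb)
```

This vignette is the package's account of its science: the generative task,
the two observer models, the response-combination models and their fitting,
the derived neuroimaging regressors, and the numerical and design choices
behind each. Everything quantitative claimed here is computed by the test
suite or by `scripts/acceptance.R`; nothing is asserted from memory.

## 1. The generative task

A session is `n_trials` (default 220) trials. On trial $i$ a landing point
$x_i$ is drawn from $\mathcal N(\mu_{\text{gen}}(i), \sigma_{\text{gen}}(i)^2)$,
truncated to the screen by resampling (not clipping, so the Gaussian shape is
approximately preserved). The generative mean and SD are piecewise constant:
each holds for a gap drawn uniformly on the integers 20–40 (trials), then
jumps — independently of the other parameter — to a fresh value. All
positions are in fractions of the horizontal screen width, so the screen is
$[0, 1]$.

Given the endpoint, the trajectory is a parabola
$x(t) = x_0 + v_0 t + \tfrac12 a t^2$ sampled at 40 equally spaced times over
6 s. The acceleration is drawn uniformly on $[-a_{\max}, a_{\max}]$ and the
start point uniformly on the screen; $v_0$ is then solved so the parabola
passes through $x_i$ at $t_{\text{end}} = 6$ s. Candidate $(x_0, a)$ pairs
producing any off-screen position are rejected and redrawn (error after
1000 attempts, naming the offending parameters). Because start point and
curvature are drawn jointly subject only to the endpoint constraint, neither
alone predicts the endpoint — a property the test suite checks as a near-zero
correlation between $x_0$ and $x_i$.

The first 30 of the 40 samples (`observed_fraction = 0.75`) are shown, with
i.i.d. Gaussian noise of per-trial SD $\sigma_{\text{noise}}(i)$ added to the
horizontal coordinate only; the rest are occluded. The first 20 trials of a
session are noise-free and excluded from all analyses (warmup); the remaining
200 are the analysis trials.

**Noise calibration.** Per-trial noise SDs are drawn log-uniformly on
`noise_sd_range` and then rescaled by one session-wide factor so that the
mean noise SD over analysis trials is exactly 0.67 times the mean generative
endpoint SD over analysis trials. The package applies the calibration to the
generative SDs (which it knows); the empirical SD of points about the fitted
curve is an unbiased estimate of the same quantity and is exercised
separately in the tests.

**Declared choices the task description leaves open.** These are package
decisions, made once:

* Post-jump redraws: means uniform on $[0.2, 0.8]$, SDs log-uniform on
  $[0.02, 0.12]$ screen widths. Uniform/log-uniform are maximally
  noncommittal for a location and a scale parameter respectively, and the
  log-uniform SD exercises the observer across scales.
* $a_{\max}$ is set so that a maximal-curvature trajectory sweeps half the
  screen over its duration, $\tfrac12 a_{\max} T^2 = 0.5$, giving
  $a_{\max} = 1/36$ sw/s².
* The occluded fraction (0.25) and the pre-calibration noise range
  ($[0.015, 0.09]$) are not pinned by the task description; both are
  configurable, and the noise range only sets relative spread (the
  calibration fixes its mean).
* Solving $v_0$ from $(x_0, a, x_i)$ rather than drawing $v_0$ is an
  arbitrary but recorded convention; either way the endpoint constrains only
  the joint draw.
* Vertical motion carries no information and is not modelled; time is the
  ordinate.

## 2. The statistical model: a grid-based ideal observer

The observer knows the structure of the environment (Gaussian endpoints;
mean and SD may independently jump) but not its parameters. It maintains a
joint posterior over $\{\mu, \sigma, \alpha_\mu, \alpha_\sigma\}$ on a fixed
lattice: 60 means uniform over the screen, 20 SDs log-spaced on
$[0.005, 0.3]$, and 8 log-spaced values on $[0.001, 0.3]$ for each jump
probability. The prior is uniform over all cells.

Each trial applies two steps:

1. **Bayes update** on the observed endpoint: cell mass is multiplied by
   $\mathcal N(x_i;\ \mu_{\text{cell}}, \sigma_{\text{cell}}^2)$ and
   renormalized. This is computed in log space with max-subtraction before
   exponentiation, so sessions of outliers cannot underflow.
2. **Leaky propagation**: within each $(\alpha_\mu, \alpha_\sigma)$ slice,
   the $(\mu, \sigma)$ distribution $p$ becomes
   $(1-\alpha_\mu)(1-\alpha_\sigma)\,p
   + \alpha_\mu(1-\alpha_\sigma)\,U(\mu)\,p(\sigma)
   + (1-\alpha_\mu)\alpha_\sigma\,p(\mu)\,U(\sigma)
   + \alpha_\mu\alpha_\sigma\,U(\mu)\,U(\sigma)$,
   where $p(\mu), p(\sigma)$ are the slice marginals and $U$ is uniform over
   the axis. The $\alpha$ marginals are untouched. Mass drift beyond
   $10^{-10}$ is an error, not silently renormalized away.

The per-trial statistical prediction $(\mu_s(i), \sigma_s(i))$ is the
**moment-matched Gaussian of the posterior-predictive mixture**, taken
*before* observing $x_i$: $\mu_s = \sum m\,\mu$,
$\sigma_s^2 = \sum m\,(\sigma^2 + \mu^2) - \mu_s^2$. Moment matching is
chosen over reporting the modal cell's parameters because every downstream
use (precision weighting, the KL regressors) treats the statistical
prediction as a single Gaussian, and moment matching is the unique Gaussian
preserving the predictive mean and variance. Warmup trials are observed like
any others (feedback is always shown). The grid resolution is a
fidelity/cost balance; with the jump-rate axes pinned at zero the filter
agrees with an independently coded stationary grid-Bayes oracle to $10^{-8}$
(see `test-ideal-observer.R`), so resolution, not implementation, is the
only approximation.

## 3. The dynamic model: OLS extrapolation

The dynamic prediction fits $x(t) = c_0 + c_1 t + c_2 t^2$ to the observed
noisy samples by least squares (QR, not normal equations) and extrapolates
to $t_{\text{end}}$. Its uncertainty is the standard error of the fitted
value, $\sigma_d = \sqrt{v\, h^\top (X^\top X)^{-1} h}$ with
$h = (1, t_{\text{end}}, t_{\text{end}}^2)$ — not a prediction interval,
because the true landing point lies on the smooth curve. By default
$v = s^2 = \text{RSS}/(n-3)$, the residual variance a participant could
actually estimate; a known-variance mode ($v = \sigma_{\text{noise}}^2$) is
exposed for the analyses that need exactness. Noise-free trials have zero
residuals and are pinned at $\sigma_d = 0$ exactly (they are excluded from
analysis regardless).

**Sequential variant.** The statistical prior can instead enter the
trajectory-estimation process itself: `sequential_estimate_with_prior()`
runs weighted least squares on the first $k$ samples plus one
pseudo-observation $(t_{\text{end}}, \mu_s)$ of SD $\sigma_s$. With all
samples included, the fitted value and SE at $t_{\text{end}}$ are
algebraically identical to the $M{=}1$ precision-weighted combination of the
known-variance dynamic estimate with the prior; `run_equivalence_check()`
verifies the identity at $<10^{-8}$ on generated sessions. The WLS system is
solved via the QR of the square-root-weighted design so that near-degenerate
priors (SDs of $10^{-9}$ or $10^{9}$) remain stable.

## 4. Combination models, fitting, comparison

The three response models are parameterized with
$P_s = M/\sigma_s^2$, $P_d = (2-M)/\sigma_d^2$ (see `?combine_prediction`).
This parameterization satisfies all the constraints the models must carry:
$M \in [0,2]$ for the weighted and selection rules with $M{=}1$ giving exact
Bayesian weighting, $M \in [0,1]$ for the fixed-ratio rule, and an additive
bias $b$ applied after mixing. Ties in the selection rule
($P_s = P_d$) deterministically choose the statistical source. Responses are
$r \sim \mathcal N(\mu_{sd}, k^2)$.

Fitting maximizes the response log likelihood over the free parameters
within bounds ($k \in (0, 0.5]$, $b \in [-0.25, 0.25]$) by a deterministic
21-point-per-dimension grid followed by `L-BFGS-B` refinement from the best
cell; fits at a bound are flagged. Fixing subsets of $(M, k, b)$ produces the
nested versions used for BIC comparison ($\text{BIC} = p\ln n - 2\log L$);
models with equal parameter counts are compared directly by log likelihood
ratio. The fitter is validated by parameter recovery (bias and RMSE shrink
from $n{=}100$ to $n{=}1000$), by a dense-grid oracle for one-parameter
profiles, and by a generator-identification check across all three rules.

**Attraction slopes.** `attraction_slopes()` bins analysis trials by
$\sigma_d$ terciles and regresses $x_i - r_i$ on $x_i - \mu_s(i)$ within
each bin (OLS with intercept): slope 0 is pure dynamic responding, slope 1
pure statistical responding. The reference slopes of a noiseless optimal
observer are computed by regenerating responses with $M{=}1$, $b{=}0$,
$k \to 0$; in a bin they converge to the mean Bayes weight
$\sigma_d^2/(\sigma_d^2+\sigma_s^2)$, which the tests verify on a controlled
Monte-Carlo sample. Note that on realistic sessions the realized reference
slope is a *variance-weighted* mean of per-trial weights (trials with large
$|x - \mu_s|$ count more) and so sits below the unweighted mean when high
$\sigma_s$ accompanies large displacements — the group-level claim tested is
therefore the monotone rise across bins, via a per-participant linear
contrast and one-sample t test (`attraction_trend_test()`), the standard
linear-trend equivalent of a repeated-measures ANOVA.

## 5. Regressors for model-based imaging

`build_regressors()` emits, per analysis trial: the log precisions
$\ln(1/\sigma_s^2)$ and $\ln(1/\sigma_d^2)$ (natural log throughout —
precision is a scale parameter, so equal information gains are equal log
steps); $\mathrm{KL}(\text{stat}_i \,\|\, \text{comb}_i)$, how far the
statistical prediction must move to absorb the dynamic evidence;
$\mathrm{KL}(\text{stat}_i \,\|\, \text{stat}_{i+1})$ and
$|\mu_s(i{+}1) - \mu_s(i)|$, the between-trial update of the statistical
model (undefined, and flagged `NA` rather than zero-filled, on the final
trial); and accuracy $100\,|r_i - x_i|$ in % screen width, both raw and
orthogonalized against the two log precisions (OLS residual; constant
precision columns are dropped from the basis rather than crashing the
degenerate case). The combined prediction inside the KL term uses the
optimal weighting ($M{=}1$, $b{=}0$), since these regressors are
model-derived rather than subject-fitted; a fitted $M$ can be passed
instead. Gaussian KL uses the closed form
$\ln(\sigma_2/\sigma_1) + (\sigma_1^2 + (\mu_1-\mu_2)^2)/(2\sigma_2^2) -
\tfrac12$, checked against quadrature to $10^{-6}$.

Event onsets mark occluder entry: 6 s trajectory + 1 s modeled response +
0.5 s feedback + a jittered ITI. The ITI is exponential rejected outside
$[2, 12]$ s, with the rate solved (by `uniroot`) so the truncated mean is
exactly 6 s. Events export as a BIDS-style `events.tsv` with one modulation
column per regressor and 0.1 s durations.

## 6. The synthetic cohort and problem sizes

`cohort_spec()` declares the synthetic participant population used by the
recovery experiments and the acceptance script: 22 participants, one
220-trial session each (200 analysed), responses generated from the weighted
rule with per-participant parameters drawn once from
$M \sim U[0.7, 1.3]$, $k \sim U[0.02, 0.05]$ sw, $b \sim U[-0.02, 0.02]$ sw.
The $M$ and $b$ spreads express modest individual departures from optimal
weighting and small lateral biases; $k$ spans response noise from roughly
two to five percent of the screen, commensurate with the task's endpoint
SDs. Every participant is a deterministic function of the master seed.

Problem sizes used throughout the package's own experiments: single sessions
of 220 trials; 10 sessions for calibration and regressor-correlation
summaries; 22 × 200 trials for model recovery; $n$ up to a few thousand
synthetic trials for parameter-recovery properties. These are the study's
native scales; the grid filter processes a session in about a second.

## 7. What the generator does and does not emulate

The simulator reproduces the task's generative structure: the jump
schedule, endpoint-conditioned trajectory sampling, the 0.67 noise
calibration, the warmup block, and feedback on every trial. It does not
emulate: perceptual encoding noise or display rendering; response times or
motor cost; learning of the task's meta-parameters (the observer's grid
covers the jump rates, but no model of how a person acquires the "rules of
the game" is attempted — the training phase that precedes the analysed
session is assumed, not modelled); sequential effects in human responses
beyond what the statistical model carries; and lapses or heavy-tailed
response noise. Passing tests therefore demonstrate the internal consistency
and recoverability of the modelling pipeline on data that obey its
assumptions — they do not show that human responses obey them.

## 8. Known limitations

* The grid filter's fidelity is bounded by its lattice; extremely tight
  generative SDs (below the 0.005 grid floor) or endpoints outside the
  screen are not representable.
* $\sigma_d$ from estimated residual variance is noisy at 30 samples per
  trial; standardized dynamic errors are calibrated under the known-variance
  mode and slightly heavier-tailed under estimation, which is the realistic
  condition and the one used for fitting.
* The MLE surface for the selection rule is piecewise constant in $M$
  wherever no trial's winner flips; the grid stage guarantees a global
  search at its resolution, and refinement is local thereafter.
* BIC comparisons use the standard large-$n$ penalty; with 200 trials per
  participant this is conventional, not asymptotically exact.
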