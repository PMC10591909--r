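---
title: "Methods: eGR-based synergy assessment for four-group in vivo studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eGR-based synergy assessment for four-group in vivo studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egrsyn)
```

## The estimation problem

A single-dose four-group mouse combination study measures tumor volume (TV,
mm³) longitudinally in four arms: vehicle control (C), drug A, drug B and the
combination (AB). The question is whether the combination does better than
the two drugs' effects combined under a null model of no interaction. Two
features make this awkward for off-the-shelf synergy tools: there is exactly
one dose per drug, so dose–response models are unavailable; and the data are
ragged — mice differ in starting volume, measurement days and follow-up
(dropout, euthanasia when the tumor reaches a size limit, extended dosing).

## The eGR metric

Every growth curve is reduced to one number on the rate scale. On the
natural-log volume scale, the trapezoidal area under the curve minus the
rectangle spanned by the starting volume is the *net log-scale AUC*; dividing
by $d^2/2$, where $d$ is the curve's own duration, gives the exponential
growth rate

$$\mathrm{eGR} = \frac{2}{d^2}\left[\sum_i \frac{(t_{i+1}-t_i)(\ln TV_i + \ln TV_{i+1})}{2} - d\,\ln TV_1\right].$$

The normalization is the unique one with the defining property that an
exactly exponential curve $TV_0 e^{kt}$ returns $k$ on *any* schedule of two
or more days, because the net log-AUC of an exponential is $k d^2/2$. Three
consequences shape everything downstream:

* **no curve fitting and no growth-law assumption** — the metric is a linear
  functional of the observed log-curve;
* **scale invariance** — multiplying all volumes by a constant leaves eGR
  unchanged, so heterogeneous starting volumes are harmless;
* **each mouse uses its own window** — curves of different lengths
  contribute on the same per-day scale, so uneven designs need no
  interpolation.

One symmetry caveat, documented because it is easy to over-assume: reversing
a curve in time negates eGR for two-point curves and for exact exponentials
on a day-symmetric schedule, but *not* for arbitrary curves — a symmetric
rise-and-fall curve reverses onto itself yet has positive eGR, since the
baseline rectangle is anchored at the *first* volume. This is inherent to
anchoring at treatment start, which is what the survival interpretation
below requires.

Curves with fewer than two usable measurements carry no rate information;
they are kept in the dataset, excluded from eGR with a recorded warning.
Duplicate (mouse, day) rows are a hard error rather than silently averaged.
An optional `max_day` truncates all curves before analysis (for protocols
that cap analysis at a fixed day); the default uses all data.

## Relative survival, CI and SS

Treating TV as a proxy for viable cell count and each group's mean eGR as the
rate constant of an equivalent exponential, the surviving fraction under
treatment $g$ relative to control after $t$ days is
$S_g = e^{-(\mathrm{eGR}_C - \mathrm{eGR}_g)t}$. Values above 1 (growth
acceleration) are legal. The combination index and synergy score under the
two supported null models are

| model | expected combo survival | CI | SS |
|---|---|---|---|
| Bliss independence | $S_A S_B$ | $S_{AB}/(S_A S_B)$ | $100(S_A S_B - S_{AB})$ |
| highest single agent | $\min(S_A,S_B)$ | $S_{AB}/\min(S_A,S_B)$ | $100(\min(S_A,S_B) - S_{AB})$ |

CI < 1 and SS > 0 mean synergy, with $\mathrm{sign}(CI-1) =
\mathrm{sign}(-SS)$ always. When both single agents are effective
($S_A, S_B \le 1$), HSA CI ≤ Bliss CI: Bliss is the stricter standard. The
default evaluation time is $t = 21$ days (a conventional three-week
treatment course); it is configurable, and because the Bliss log-CI is
$t \cdot (\mathrm{eGR}_C + \mathrm{eGR}_{AB} - \mathrm{eGR}_A -
\mathrm{eGR}_B)$ — $t$ times a $t$-free rate contrast — the choice rescales
CI/SS magnitudes without ever flipping the verdict.

## Bootstrap inference

Sampling noise enters through mice, so the resampling unit is the whole
growth curve, drawn with replacement *within* each arm (the arm is the
stratum), keeping group sizes fixed and within-mouse correlation intact. The
default is 1000 replicates. Since a mouse's eGR is a fixed function of its
curve, resampling curves is equivalent to resampling per-mouse eGR values
within arms; the implementation uses this identity (a property test pins the
equivalence), which makes each replicate a handful of means.

Both statistics tend to be skewed — the combination indices behave
log-normally — so intervals are bias-corrected accelerated (BCa): the bias
term $z_0$ comes from the fraction of bootstrap values below the observed
estimate (ties half-weighted, clamped to the achievable range $[1/(B+1),
B/(B+1)]$ when all values fall on one side), the acceleration $a$ from
leave-one-mouse-out jackknife skewness within strata, and the endpoints are
interpolated order statistics (R's default type-7 convention) at the
adjusted levels. The CI is processed on the log scale, where its additivity
null sits at 0; the SS on its natural percentage scale, null 0. A point-mass
bootstrap distribution (e.g. identical curves within every arm) yields the
degenerate interval $(v, v)$ and a flagged, non-estimable P value.

The P value is the smallest $\alpha$ at which the null value leaves the
$(1-\alpha)$ BCa interval, found by bisection (tolerance $10^{-8}$ on
$\alpha$, floor $1/B$). This construction was chosen over counting bootstrap
tail mass because it makes the reported interval and P value consistent by
definition: the null is inside the 95% interval exactly when P > 0.05.
BCa is equivariant under monotone transforms and the log-CI scales linearly
in $t$, so the CI's P value is *exactly* invariant to the evaluation time —
with the same seed, $t \in \{7, 21, 42\}$ give different CI/SS but the same
P. The SS P value is not exactly $t$-invariant (the SS is not a monotone
transform of a single contrast across replicates), though its sign and
near-value are stable; the tests assert exact invariance only for the CI.

## The single-day baseline

For comparison, `local_bliss_ci()`/`global_ci()` implement a day-wise Bliss
index: per group the mean relative TV $\mu_g$ (each mouse's TV over its own
first measurement, averaged within arm — per-mouse-first for robustness to
baseline spread), the local index $\ln\mu_A + \ln\mu_B - \ln\mu_C -
\ln\mu_{AB}$ (note the opposite orientation: > 0 is synergy), and gCI as the
mean over days where *all four* arms have measured mice. No interpolation is
done — a mouse contributes to a day only if measured on exactly that day —
so the baseline visibly loses the late part of a study once the control arm
is euthanized, which is precisely the failure mode the eGR approach avoids.
Treatment effects $\delta_g = (\mu_C - \mu_g)/\mu_C$ are reported alongside
for bookkeeping. The baseline carries point values only, no inference.

## The simulator

`simulate_study()` generates studies from a two-population exponential
model. Per mouse: initial volume $TV_0$ log-normal with mean 200 mm³
(treatment typically starts at 100–300 mm³) and CV `cv0`; base rate $k$
normal with mean $\ln 2 / DT$ and CV `cvk`, redrawn if non-positive
(positivity, with negligible distortion at the default CV); measurement
error multiplicative log-normal with log-SD `sigma`. Log-normal/truncated
choices keep volumes positive and match the log-scale analysis; each is a
documented policy of this generator, not a claim about any particular
laboratory's error structure. Treatment effect per arm is parameterized by
day-21 tumor growth inhibition: $k_{tr} = k + \ln(1-\mathrm{TGI}^{21})/21$,
so the noise-free relative-volume ratio at day 21 is exactly
$1-\mathrm{TGI}^{21}$. Delayed kick-in holds the arm at the control rate
until `t_ki`; intrinsic resistance grows a fraction `p_rt` at the control
rate from day 0; induced resistance reverts a fraction `p_rt` of the
population at day `t_ir`. Measurements follow the twice-weekly alternating
3/4-day pattern (0, 4, 7, 10, 14, 18, 21, …) up to `t_obs`; the first
measurement at or above `tv_max` (default 3000 mm³, the euthanasia
threshold) is kept as the terminal point and later days are dropped —
analysis needs the crossing measurement, and a flag-free alternative would
bias eGR low.

Default noise levels are `cv0 = 0.2`, `cvk = 0.2`, `sigma = 0.1` — 20%
animal-to-animal variation in starting volume and growth rate, 10%
measurement error, values a practitioner would call realistic for xenograft
studies. They are deliberately not small: the rate CV is the binding
constraint on what any test can detect (see below). The packaged example
dataset is the exception: it is generated at `cvk = 0.05, sigma = 0.05` and
documented as a low-noise illustration whose built-in synergy is visible in
a single study.

What the simulator does *not* emulate: non-exponential growth laws
(Gompertz/logistic plateaus), pharmacokinetics, correlated measurement
errors, body-weight or toxicity dropout. Passing tests therefore show the
pipeline is correct *under exponential kinetics with independent noise*;
on real data the eGR metric itself remains well-defined without those
assumptions, but simulated operating characteristics (power, type-I error)
transfer only as far as the model does.

## Power analysis and what the defaults imply

`estimate_power()` simulates `n_sim` studies (default 100), analyzes each
with the full bootstrap pipeline, and reports the fraction with P < 0.05 —
empirical power, or type-I error when the scenario is additive (combo
TGI²¹ = 0.7 against single-agent 0.5/0.4 is *exact* Bliss additivity, since
$0.5 \times 0.6 = 0.3$). `power_grid()` crosses mice-per-group, doubling
time, euthanasia cutoff and study duration. Seeds form a hierarchy (master →
grid point → replicate, with regeneration substreams for degenerate draws),
so every number is exactly reproducible and grid points are independent.

Two consequences of the default noise levels, both computed by the test
suite and the acceptance script rather than asserted from theory: (i) the
type-I error at 6 mice per group sits at its nominal 5% within binomial
tolerance; (ii) at 2 mice per group the bootstrap is coarse (three distinct
resamples per arm) and noticeably liberal, and the between-animal rate SD
($0.2 \times \ln 2/7 \approx 0.02$/day) is of the same order as the strong
synergy rate contrast ($\ln 1.5 / 21 \approx 0.019$/day), so power against
strong synergy at that size is modest — tens of percent, not near-complete.
Detecting synergy at very small group sizes requires substantially more
homogeneous animals (rate CV well under 0.1) than these defaults grant.
Power rises with sample size and with doubling time (slower growth means
proportionally smaller rate SD at fixed CV), and is only weakly affected by
the euthanasia cutoff over 500–2500 mm³.

Problem sizes used by the test suite, chosen to exercise each claim at the
smallest informative scale: type-I calibration at 200 simulated studies with
200 bootstrap replicates; power points at 50–100 studies with 200–1000
replicates; property loops at 20–100 random cases. The acceptance script
runs the two headline designs at 100 simulations × 1000 replicates.

## Degenerate and edge inputs

* All-identical curves across arms: CI = 1, SS = 0, point-mass bootstrap,
  flagged degenerate, P not estimable.
* A group whose curves all have a single usable day: structure error naming
  the group.
* Adjusted BCa levels outside the achievable range: clamped to the extreme
  order statistic with a diagnostic flag.
* Simulated studies where an arm has no analyzable curve (possible only in
  extreme truncation regimes): regenerated from the next seed substream and
  counted in the power output.
* Non-zero first measurement days: shifted per mouse to a common day-0
  origin at read time (the survival formulas presume a shared treatment
  start); disable with `align_days = FALSE`, in which case validation notes
  the offset.

## Known limitations

* The eGR-based CI/SS magnitudes depend on the evaluation time and the
  tumor's growth rate; they are comparable across studies only with caution.
  The CI P value, being $t$-invariant, is the safer cross-study quantity.
* The gCI baseline reports no uncertainty; it exists to show, not to
  compete.
* Bootstrap inference needs at least a few mice per arm to be trustworthy;
  below ~4 the intervals narrow artificially and P values run liberal. The
  power functions make this visible rather than hiding it.
* TGI²¹ parameterization cannot represent complete kill (TGI = 1 would need
  an infinite negative rate).
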