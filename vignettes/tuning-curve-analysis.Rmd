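---
title: "Models, features and statistics for direction tuning curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, features and statistics for direction tuning curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models and
their parameterizations, the fitting and goodness-of-fit machinery, the
model-free feature extraction rules with every tie-break spelled out, the
statistical tests, and what the synthetic-data generator does and — just
as important — does not emulate.

## The data model

The unit of data is a *trial table*: one row per trial with a cell
identifier, recording paradigm (`spatially_separate` or `transparent`),
experimental condition (`uni`-type single-stimulus conditions and the
bimodal `afix`/`ain` two-stimulus conditions), stimulus direction (a
multiple of 30° in [0°, 330°], K = 12 directions), trial index and firing
rate in s⁻¹.  Cells enter the analysis only if every recorded
(condition, direction) has at least two trials; `build_curves()` collapses
trials to per-direction means `y`, standard deviations `σ` (denominator
n − 1) and counts.

All curves of a cell are *aligned* by a single circular relabelling of
directions so that the maximum trial-mean rate of the unidirectional
condition sits at 240°; cells lacking a `uni`-type condition are aligned
on the right peak (directions in [180°, 360°)) of their `afix` condition.
Alignment is a pure relabelling — the multiset of rates is untouched — and
idempotent; offsets are retained so it can be undone.  When both `uni1`
and `uni2` were recorded, `uni2` is the analysed unidirectional condition.
Argmax ties during alignment resolve to the smallest original angle,
which makes the operation deterministic and order-independent.

## Model families

Angles are degrees throughout; Ω = 2π/360 converts to radians internally.
The five peaked families (unimodal forms, all rates in s⁻¹):

| family | form | parameters |
|---|---|---|
| `wG` | `a Σᵢ exp(−½((θ−c+360i)/b)²) + d` | amplitude a, width b, peak c, baseline d |
| `wC` | `a sinh(b)/(cosh(b) − cos Ω(θ−c)) + d` | a, b, c, d |
| `vM` | `a (e^{k cos Ω(θ−c)} − e^{−k})/(e^k − e^{−k}) + d` | a, concentration k, c, d |
| `sbeta` | `a (4x(1−x))^b + d`, `x = (Ω(θ−c)+π)/2π mod 1` | a, shape b, c, d |
| `wB` | `a (Σᵢ 1/(1+|(θ−c+360i)/b|^{2s}) − β)/(α − β) + d` | a, b, c, d, steepness s |

Wrapped sums run i = −4..4.  The offset θ − c is first wrapped into
[−180°, 180°); for the Gaussian this changes nothing at numerical
precision (the i = ±5 terms are < 10⁻³⁸ for b ≤ 120), but for the
polynomially-tailed bell function it is what makes the evaluation exactly
360°-periodic, which downstream feature extraction assumes.  The
normalizers α and β (the wrap sums evaluated at the peak and at the
antipode) pin wB's range to [d, a + d].  The von Mises concentration is
floored at k = 0.001, where the function is numerically flat and the
normalizing denominator would otherwise vanish.

Responses to two stimuli are modelled as a sum of two copies of the same
family, `f(θ) = g(θ, p₁) + g(θ, p₂)`, each carrying half the shared
baseline (`d/2`): parameter layout `(a₁, b₁, c₁, a₂, b₂, c₂, d)` and, for
wB, two extra steepnesses `(…, s₁, s₂)` — 7 or 9 free parameters.
Fourier series `Fn(θ) = a₀ + Σᵢ aᵢ cos(iΩθ) + bᵢ sin(iΩθ)` of order
2, 3, 4 (5, 7, 9 coefficients) share one functional form across
modalities.

## Fitting

`tunefit()` minimises the weighted residual
`χ² = Σᵢ ((yᵢ − f(θᵢ))/σᵢ)²` with σ the per-direction *trial* standard
deviation, floored at 10⁻⁶ s⁻¹ so that directions with identical trials
act as near-interpolation constraints instead of producing infinite
weights.

**Fourier (linear) families** are solved exactly: with design
`A[i,m] = X_m(θᵢ)/σᵢ` and target `bᵢ = yᵢ/σᵢ`, the coefficients are
`Σ_m (u_m·b / w_m) v_m` over the singular triplets of A; singular values
below `max(w)·10⁻¹²` are dropped (standard truncation; the count is kept
on the fit object).  The test suite verifies agreement with an
independent normal-equations solve to 10⁻⁸.

**Peaked families** are fitted by bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) from a small multistart grid, then polished with a
short bounded quasi-Newton pass — LM converges fast on least-squares
structure but can stall on the plateau-prone width/steepness parameters,
and the polish recovers those cases.  Starts and bounds:

* amplitudes and baseline start at the observed peak-to-peak range and
  minimum, bounded in [0, u] with `u = min(y) + 1.2·(max(y) − min(y))`;
* widths multistart over values corresponding to half-widths at
  half-maximum of 15°, 45° and 90° (for `sbeta` b ∈ {100, 10.74, 2.41},
  for `vM` k ∈ {20.34, 2.3, 0.001}; for `wG`/`wC`/`wB` the HWHM is
  converted through each family's closed form), inside wide physical
  bounds (e.g. wG b ∈ [3, 200]);
* peak positions start at the grid argmax (unimodal) or the argmax of
  each half-grid, defaulting to 120°/240° (bimodal), and move within
  ±90° of the start.

A fit that fails every start is returned with `converged = FALSE` rather
than dropped; model selection excludes such fits with a warning.

## Goodness of fit

`Q` is the null probability — assuming the model correct and the errors
independent zero-mean Gaussians with the observed σᵢ — of a residual χ²
at least as large as observed.  For the linear Fourier families this is
the regularized upper incomplete gamma function at shape `(K − M)/2` and
argument `χ²/2`, i.e. the upper tail of χ²_{K−M}.  For the non-linear
families the residual does not follow that distribution, so `Q` is
estimated by Monte-Carlo: draw replicas from the fitted profile plus
Gaussian noise with the curve's σᵢ, refit the same family to each replica
(starting from the observed solution, with a reduced iteration budget —
the start is the truth, so few steps are needed), and report the fraction
of replica χ² at or above the observed one.  The default is 10000
replicas; desk-scale analyses can lower it (minimum 100).  Replicas are
resampled parametrically (Gaussian) rather than by trial bootstrap, which
matches the Gaussian error assumption underlying the analytic tail.
Fits with `Q ≤ 0.1` are termed *bad*.

Two properties are worth knowing.  First, the Monte-Carlo estimator is
validated against the analytic tail on the linear families (agreement
within ±0.02 at 10000 replicas).  Second — and easy to overlook — when a
family is *correctly specified*, Q is uniform on [0, 1] by construction,
so the expected fraction of cells with Q > 0.1 is exactly 90%; claims of
the form "more than 90% of cells fit well" therefore sit at a statistical
ceiling that even the true model only reaches through estimator bias.
The package's own surrogate experiments (see `scripts/acceptance.R`)
show the stiff or mis-tailed families (`F2`, `wC`) a few percent below
that ceiling on wrapped-Gaussian surrogates at empirical noise, and the
flexible families at or just above it.

## Model selection

`AIC = K·log(SSE/K) + 2M` uses the *unweighted* sum of squared errors, and
`AICc = AIC + 2M(M+1)/(K−M−1)` (correction 10, 28 and 90 for M = 5, 7, 9
at K = 12; undefined for K − M − 1 ≤ 0).  ΔAIC is taken per cell against
the minimum across families; ΔAIC ≤ 1 defines the contender set (the
inclusive reading of "≈ 1"; the threshold is an argument).  Ties for best
resolve by fewest parameters, then by the fixed order
F2, F3, F4, sbeta, vM, wC, wG, wB.  A perfect fit (SSE = 0) returns a
large negative sentinel with a warning rather than −∞.

One interaction deserves emphasis: fitting minimises the *weighted* χ²
while the criterion ranks the *unweighted* SSE, exactly as the formulas
prescribe.  Under strongly heteroscedastic σ these two objectives
diverge, and the exactly-solved Fourier fits (which optimise the weighted
objective perfectly) can be handicapped in SSE terms against the
iteratively fitted peaked families.  With homoscedastic noise the effect
vanishes; analyses that intend SSE-based ranking on heteroscedastic data
should be aware of it.

## The direct method: algorithmic feature extraction

`extract_features()` maps a sampled curve — either the 12 trial-mean
points (*direct*) or a fitted profile sampled at a uniform resolution
(default 1°) — to named scalar features, with identical rules for both
sources.  The rules, including every tie-break:

* **Global extrema.**  `GlobalMaximum`/`GlobalMinimum` over all samples;
  argmin/argmax ties take the smallest angle.  `GlobalMinimumAngle` is
  reported in (−120°, 240°] (angles above 240° wrap down by 360°), which
  keeps the population distribution connected around the aligned peak.
* **Peak partition (bimodal).**  The left peak is the maximum over angles
  in [0°, 180°), the right peak over [180°, 360°).  Peak-angle ties
  resolve toward 120° (left) and 240° (right) — the expected component
  positions under the alignment convention — then to the smallest angle.
* **Inner/outer minima.**  `InnerMinimum(Angle)` is the minimum strictly
  between the two peak angles; `OuterMinimumAngle` the minimum on the
  complementary wrapped arc.  `InnerWidth^{left,right}` are the angular
  distances from each peak to the inner minimum,
  `OuterWidth^{left,right}` the wrapped distances to the outer minimum;
  Δ-features are right minus left.
* **Bandwidths.**  From the peak sample, walk outward in both directions
  while the baseline-subtracted value stays at or above X% of that peak's
  elevation (X ∈ {25, 50, 75}; baseline = `GlobalMinimum`, elevation =
  `PeakToPeak` of that peak); the bandwidth is the angular span between
  the outermost surviving samples, capped at 360°.  There is *no
  interpolation*: on the 12-point grid all angular features are multiples
  of 30°, which is visible as quantization in population scatter plots
  and is intentional.
* **Skewness.**  The right peak's support is the arc from the inner
  minimum through the peak to the outer minimum; its skewness is the
  weighted third standardized moment of angle over that arc (angles
  unwrapped to increase monotonically, weights = baseline-subtracted
  rates).  `minusSkewnessLeft` is the negated mirror quantity, so that a
  mirror-symmetric curve has `ΔSkewness = 0`.  This algorithm is a
  reconstruction — reasonable, mirror-consistent, and isolated in a
  single helper (`weighted_skewness`) so it can be swapped.
* **Circular variance** (unimodal only):
  `1 − |Σ v e^{iΩθ}| / Σ v` on the rate-weighted angles.
* **Normalization.**  Every rate-valued feature gains a `normalized`
  variant divided by the cell's maximum unidirectional rate; cells
  without a `uni` condition get `NA`.

Unimodal curves report the global peak as the "right" peak (the aligned
preferred direction) and leave two-peak features `NA`; bimodal curves
leave `CircularVariance` `NA`.  Feature extraction is invariant to adding
a constant for all angular features, shifts rate features by that
constant, and swaps left/right (negating Δ-features) under mirror
reflection — all property-tested.

`feature_zscores()` quantifies model-vs-direct agreement per feature as
`z = (mean(model) − mean(direct)) / sd(direct)` across cells.

## Statistical comparisons

* **Feature pairs** (`compare_feature_pair`): two-group Kruskal–Wallis
  rank test with tie correction.  Because angle features are 30°-quantized
  and groups can be small, the p-value is computed *exactly* by
  enumerating the permutation null of the rank statistic whenever
  `choose(n₁+n₂, n₁) ≤ 10⁵`, and by the χ²₁ tail otherwise (the regime of
  ~100-cell populations).  Significance is p < α (default 0.05); the
  direction of an effect is read from the medians, falling back to means
  on an exact median tie.
* **Specific effects** (`specific_effects`): per (cell, direction), a
  two-sample Kolmogorov–Smirnov test between the trial ensembles of two
  conditions, exact for combined trial counts ≤ 25 (the experimental
  regime of 2–15 trials), asymptotic beyond.  A direction is enhanced or
  suppressed by the sign of the median difference.  Note the exactness
  has a discreteness cost: with equal trial counts n = m = 10 the
  attainable p-values jump from ~0.012 to ~0.052, so the realized
  false-positive rate at α = 0.05 is well below nominal; with the
  heterogeneous trial counts of real recordings it is ≈ 0.042.
* No multiple-testing correction is applied by default; pass the p-value
  vectors through `p.adjust(..., "BH")` where control of the false
  discovery rate is wanted.

## The synthetic-data generator

`generate_tuning_trials()` emulates the *structure* of the experiments:
12 directions at 30°, a unimodal `uni` condition with a random preferred
direction (so that alignment is exercised), bimodal `afix`/`ain`
conditions with components 120° apart, an attentional gain (default 1.2)
on the component at the preferred direction in `ain`, 2–15 trials per
stimulus (default 10), and heteroscedastic Gaussian trial noise with
σ = cv·mean (default cv = 0.38, the spatially separate paradigm's median
trial coefficient of variation; 0.72 mimics the transparent paradigm),
floored at 0.5 s⁻¹ and clipped at zero rate.  Default response
parameters — 25 s⁻¹ peak amplitude over a 5 s⁻¹ baseline, wrapped-Gaussian
width b = 40° (HWHM ≈ 47°) — sit in the range of the population medians
of the recordings this machinery targets.  A fixed seed yields a
bit-identical dataset, and the generating parameters ride along as an
attribute so tests can use them as ground truth.

What it does **not** emulate, and what that means for the tests:

* **Inter-cell heterogeneity.**  All cells share the same generating
  parameters; real populations vary widely in amplitude, width and
  baseline.  This compresses the across-cell spread of direct-method
  features, which *deflates* the z-score agreement between direct and
  model-based features relative to real data (the denominator is the
  direct-method SD) — the acceptance script's `zscore_within_1sd_fraction`
  should be read with that in mind.
* **Model identity.**  Responses are exactly wrapped-Gaussian; real
  tuning curves are not any of the eight families.  At empirical noise
  this hardly matters (model selection is ambiguous either way — several
  families sit within one AIC unit), but at very low noise it makes the
  generating family cleanly identifiable, which real data would not be.
  Conversely, the symmetric Beta family approximates a wrapped Gaussian
  of these widths to ~0.2 s⁻¹ rms on the 12-point grid, so model
  *identification* tests must push the standard error of the trial means
  below that floor (the suite uses cv = 0.02 with 10 trials and a
  reduced noise floor).
* **Spiking statistics.**  Noise is Gaussian per trial, not point-process
  derived; no across-cell or across-direction noise correlations.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale, chosen to give
stable fractions while keeping a full run in minutes: 40–50 cells for
population fractions (binomial SE ≈ 5–7% at p ≈ 0.9), 100 Monte-Carlo
replicas for per-cell Q in ensemble experiments (Q resolution 0.01),
10000 replicas where the Monte-Carlo estimator itself is validated, and
10⁴ simulations for the false-positive-rate check (SE ≈ 0.002).
Remaining numerical guards: trial-SD floor 10⁻⁶ s⁻¹ in weights, vM
k-floor 0.001, SVD truncation at 10⁻¹² relative, AIC sentinel at
SSE = 0, and Monte-Carlo refits that reuse the observed solution as the
start.

## Known limitations

* The bounds/starts table for the non-linear fits is a reconstruction
  from its published fragment; the width bounds in particular are wide
  physical ranges rather than published values.
* The skewness algorithm is a documented reconstruction (see above).
* Monte-Carlo Q inherits a small liberal bias from imperfect replica
  refits (replica χ² slightly above the attainable minimum raises Q);
  with the LM-plus-polish refitter the bias is a few hundredths at
  moderate Q and does not move the bad-fit classification materially.
* Trial ensembles are compared marginally per direction; there is no
  joint (across-direction) test, no paired per-cell design, and no
  modelling of noise correlations.
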