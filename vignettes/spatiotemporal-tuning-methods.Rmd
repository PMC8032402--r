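---
title: "Methods: screening and modelling 3D self-motion tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening and modelling 3D self-motion tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(vestuning)
```

vestuning analyses single-neuron responses to three-dimensional self-motion
stimuli: brief translations or rotations delivered along 26 directions (or
about 26 axes) equally distributed in 3D space, each following a Gaussian
velocity pulse. This vignette documents the statistical procedures, the
model, the tunable parameters, and the design decisions behind them.

## Stimulus geometry and kinematics

The sampling grid crosses azimuths {0, 45, ..., 315} with elevations
{-45, 0, +45} and adds the two poles, giving 26 unit vectors (8 in the
horizontal plane, 13 antipodal pairs). Azimuth 0 is straight ahead and
azimuth 90 leftward; the literature rarely states this convention, so the
package fixes and documents it. The same grid serves as rotation axes under
a right-hand-rule sign convention. *Adjacency*, needed by the temporal
screen, links lattice neighbours — every pair separated by at most 45
degrees of arc. Azimuth-neighbours on the ±45° rings are only ~31.4° apart,
so "pairs at exactly the minimal spacing" would be a different (and oddly
asymmetric) relation; lattice neighbourhood is the natural reading of
"adjacent directions" on this grid.

Each stimulus epoch lasts 1.5 s with a Gaussian velocity profile centred at
0.75 s and its analytic biphasic acceleration, triphasic jerk, and sigmoidal
position traces. The velocity width `sigma_s` is not printed in protocol
descriptions; it is derived from the printed peak pairs via
`sigma_s = peak_speed * exp(-1/2) / peak_acceleration`, giving ~0.182 s for
the translation protocol (0.3 m/s, 1 m/s²) and ~0.202 s for rotation
(20°/s, 60°/s²). This is the unique width consistent with both printed
peaks.

```{r profile}
prof <- translation_profile()
c(peak_speed = max(prof$velocity), peak_accel = max(abs(prof$acceleration)))
```

## The synthetic-data generator

Every downstream stage is exercised on simulated recordings:
inhomogeneous-Poisson spike trains whose rate follows the rectified
spatiotemporal model below, plus homogeneous-Poisson "null" neurons.
Spikes are drawn by thinning against the per-direction maximum rate, which
is exact for bounded rates and easy to audit. Defaults mirror the
experimental protocol: 26 directions, 1.5 s epochs, 0.3 s pre- and
post-stimulus margins, and 5 trials per direction (trial counts are not
printed for the original experiments; 5 per direction is typical for 3D
protocols of this size and is configurable). Replica conditions (the
analogue of a darkness control) re-simulate the same ground truth with a
fresh seed; null conditions (the analogue of a sound control) use the
untuned generator.

The generator reproduces Poisson trial-to-trial variability and the exact
model family of the analysis. It does **not** reproduce refractoriness,
bursting, slow excitability drift, or model mismatch (real neurons are not
exactly PVAJ). Passing tests therefore demonstrate correctness of the
*procedures* and identifiability under ideal noise, not performance
guarantees on arbitrary real data.

## PSTHs and sliding windows

PSTHs use 25 ms bins over the stimulus epoch, trial-averaged to spikes/s,
and are smoothed with a "300 ms Gaussian filter" — read here as a Gaussian
kernel truncated at ±150 ms (total support 300 ms) with SD 50 ms,
renormalized to unit sum where it overhangs the epoch edge so edge rates
stay unbiased. Only a width is ever printed; making the stated width the
kernel's support is the most conservative reading.

Window statistics use 300 ms windows stepped every 25 ms. Windows are
centred at `step/2, 3*step/2, ...`, the only alignment that yields exactly
`duration/step = 60` windows for a 1.5 s epoch. Edge windows draw on the
recorded pre-/post-stimulus margins rather than truncating, so all windows
average the same amount of data; recordings must therefore carry at least
137.5 ms of margin on each side. Spontaneous rate is computed per trial
over the span from 100 ms before to 300 ms after stimulus onset.

## The tuning screens

**Temporal tuning.** For every (direction, window) cell a two-sided
Wilcoxon rank-sum test (normal approximation, appropriate with tied rates)
compares the per-trial window rates with the *same direction's* per-trial
spontaneous rates. A neuron is temporally tuned only when at least five
consecutive windows are significant at p < 0.01 in at least two adjacent
directions. The reference sample is kept per direction deliberately: it
makes the 26 direction-level decisions independent under the null, which is
what lets the adjacency conjunction suppress false positives. (A reference
pooled across directions correlates all decisions through shared baseline
noise; in a null-neuron calibration that design inflated the family-wise
false-positive rate several-fold above the screen's target, versus
essentially zero for the per-direction design at equal power on strongly
modulated cells.) A practical floor follows from rank-sum
discreteness: with fewer than 5 trials per direction a 2-sided comparison of
n-vs-n samples cannot reach p < 0.01, so the temporal screen needs at least
the default 5 trials to have any power.

**Spatial tuning.** Each window gets a classical one-way fixed-effects
ANOVA of trial rates across the 26 directions; windows with zero variance
get p = 1 by convention. Among significant windows (p < 0.01), local peaks
of the across-direction maximum response are merged when the Pearson
correlation of their 26-direction response vectors is positive and split
when negative; at most two peaks are reported, keeping the two largest —
higher-order peaks are small and unreliable in practice.

**DDI.** The direction discrimination index is

$$DDI = \frac{R_{max}-R_{min}}{R_{max}-R_{min}+2\sqrt{SSE/(N-M)}}$$

with the best direction chosen on the full-epoch mean rate, `R_max` that
direction's best window, and `R_min` the minimum across the other 25
directions *at that same window* — the package follows the reading that
"using this time bin" fixes the window for `R_min`. `SSE` pools
within-direction squared deviations of trial rates at that window; `M = 26`.
Significance comes from a permutation test (default 1000 permutations,
seeded) that shuffles whole trials across direction labels and re-runs the
full selection procedure, with an add-one correction.

**Preferred direction** is the vector sum of the 26 grid vectors weighted
by mean rate at the (first) peak window, reported in spherical coordinates;
a zero resultant is flagged undefined rather than fabricated. Population
uniformity uses a Monte-Carlo resultant-length (Rayleigh-type) test with
10,000 resamples of uniform directions: the original analysis names a
"Uniform test" without defining it, so the package implements this standard
stand-in and labels it in its output metadata.

## The spatiotemporal model

The firing rate along direction $(\theta,\phi)$ at time $t$ is

$$R(\theta,\phi,t)=\left[A\sum_m w_m\, f_m(t-\tau)\,
  y_m\!\big(g_m(\theta,\phi)\big)+FR_0\right]_+$$

with temporal kernels (shared width $\sigma$, delay $\tau$, each rescaled
to unit peak so weights are comparable)

* velocity $f_v = e^{-(t-\tau)^2/2\sigma^2}$,
* acceleration $f_a = \frac{t-\tau}{\sigma^2} e^{-(t-\tau)^2/2\sigma^2}$,
* jerk $f_j = -\frac{(t-\tau)^2-\sigma^2}{\sigma^4}
  e^{-(t-\tau)^2/2\sigma^2}$,
* position $f_p = \int_{-\infty}^{t} f_v$,

and spatial kernel $y(x) = o + (1-|o|)\,x$ applied to the cosine of the
angle from the component's preferred direction, $o \in [-1,1]$. The VA
model uses components {V, A}; the full PVAJ model {P, V, A, J}. Note the
kernel set is implemented exactly in this printed form, in which $f_a$ is
the *negative* of the calculus derivative of $f_v$ (and $f_j$ the
derivative of $f_a$); a sign flip is equivalent to an antipodal flip of
that component's preferred direction, so the convention does not change the
model class. Kernels are centred on the stimulus velocity peak
(`duration/2`), with $\tau$ the residual delay.

Design choices where the source leaves the procedure open:

* **Each component carries its own preferred direction and offset**, since
  per-component spatial kernels demonstrably disagree across cells.
* **Weights live on the simplex** ($w_m \ge 0$, $\sum w_m = 1$) with
  unit-peak kernels; reported example weights only make sense under this
  normalization.
* **The fit targets the smoothed PSTH** (the quantity that is displayed and
  correlated elsewhere in the pipeline), not raw counts.
* **Free-parameter counts for BIC**: VA = 11 (A, FR0, tau, sigma, 1 free
  simplex weight, 2 × (azimuth, elevation, offset)); PVAJ = 19 (3 free
  weights, 4 component triples).

**Optimization.** Bounded Levenberg–Marquardt trust-region least squares
(`minpack.lm::nls.lm`) over a smooth reparameterization: softmax logits for
the weights, unnormalized 3-vectors for preferred directions (normalized
inside the model, removing coordinate singularities at the poles), offsets
boxed to [-1, 1], `tau` to [-0.3, 0.3] s, and `sigma` to [0.5, 2] × the
stimulus velocity width. Twenty seeded restarts: the first uses an analytic
warm start — with `tau = 0` and `sigma` at the stimulus width the model is
linear in per-direction kernel coefficients, and a least-squares regression
of each direction's trace on the kernel basis yields initial weights,
preferred directions (vector sums corrected for the grid's anisotropic
second-moment matrix, diag(8, 8, 10)), and offsets — the remainder spread
component directions over the strongest-responding grid vectors and then
uniformly. Lowest RSS wins; ties break to the earliest restart. On
noise-free model-generated PSTHs this recovers R² > 0.99 and weights to
within a few 10⁻³.

At realistic noise (5 trials, baseline 10 spikes/s, amplitude 40) the
delay estimate scatters by several tens of milliseconds even though weights
and directions are recovered well. This is intrinsic, not an optimizer
artefact: to first order a small time shift of a Gaussian kernel equals
adding its derivative, so $\tau$ trades against the acceleration weight;
the residual surface genuinely prefers nonzero $\tau$ on some noisy draws.
The median over tens of neurons remains near zero (the acceptance script
reports it, typically 10-20 ms at these settings).

## Model comparison

Fits are scored by $BIC = n\ln(RSS/n) + p\ln n$ over the pooled
direction × bin points, and compared by the BIC difference index
$BDI = (BIC_{VA} - BIC_{PVAJ}) / |BIC_{PVAJ}|$ — positive when the full
model is worth its extra parameters. Component attribution uses the
partial correlation between the pooled observed PSTH and each component's
fitted contribution, controlling for the other components (computed from
the precision matrix; validated in tests against explicit
residual-on-residual regression). The effective sample size counts every
direction × bin point with no autocorrelation correction — no correction is
specified for this analysis in the literature the package follows — so the
p-values are anti-conservative for smoothed PSTHs and should be read as a
ranking device; the weights carry the effect sizes. The conditioning set
and df convention are flagged in the function documentation.

## Cross-condition analyses

Controls are compared at the metric level: Pearson correlation between the
two conditions' smoothed PSTHs pooled over directions and bins, per-
condition DDI, and per-condition maximal firing rate (the max trial-mean
windowed rate), plus population-level paired t-tests and correlations. In
simulation, replica conditions (same ground truth, new seed) keep tuning
status and DDI within ±0.1 for ≳90% of tuned cells with strongly
correlated PSTHs, while null conditions produce near-zero correlations and
no temporally tuned cells — mirroring the qualitative darkness/sound
control outcomes.

## Numerical and statistical conventions

* p-value thresholds follow the analysis being reproduced: p < 0.01 for the
  tuning screens, p < 0.05 for partial correlations, with **no
  multiple-testing correction**; raw p-values are stored so users can
  re-threshold.
* Degenerate inputs are flagged, never silently patched: zero-variance
  ANOVA windows give p = 1, zero vector-sum resultants give an undefined
  preferred direction, zero observed variance gives undefined R² and PSTH
  correlations, `RSS = 0` gives `BIC = -Inf` with a warning, zero weights
  give infinite log weight ratios.
* All stochastic steps (simulation, restarts, permutation and Monte-Carlo
  tests) are seeded; population runs derive per-neuron seeds from one
  master seed, so entire pipelines are bit-reproducible.

## Problem sizes used in the shipped checks

The package's own verification suite simulates at desk scale, chosen to
make binomial/Monte-Carlo error small relative to the tested margins:
50-neuron populations for parameter recovery and control mirrors, 200 null
neurons for screen calibration, 30 seeds per model-selection scenario, 20
random draws for equation-level oracles, and 50 random instances for the
DDI oracle. The acceptance script scales some of these down (20 recovery
neurons, 100 nulls, 15 selection seeds, 25 control pairs) while keeping
every quantity a genuine end-to-end recomputation.

## Known limitations

* The Poisson generator understates real spike-count dispersion and omits
  history dependence; calibration results transfer to real data only to the
  extent that windowed rate statistics are approximately exchangeable.
* The delay parameter is weakly identified at low trial counts (see above).
* Partial-correlation p-values inherit the uncorrected effective-n
  convention.
* The "Uniform test" is a Monte-Carlo resultant-length stand-in for an
  unspecified original; it is sensitive to unimodal concentration but not
  to antipodally symmetric departures from uniformity.
* Loading the original deposited recordings is out of scope; spike-event
  CSV + protocol JSON is the documented extension point.
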