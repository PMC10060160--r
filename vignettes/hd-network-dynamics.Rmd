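---
title: "Methods: population dynamics of the head-direction network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population dynamics of the head-direction network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, the
numerical conventions, and what the synthetic tests do and do not
establish about real recordings.

## The problem

Head-direction (HD) cells in the anterodorsal thalamus fire when the
animal faces a cell-specific allocentric direction; collectively their
preferred firing directions (PFDs) tile the circle, and the population
activity forms a single localized "bump" whose position is the internal
head direction. The network has no absolute reference: it anchors to
visual landmarks, drifts without them, and re-anchors ("resets") when a
landmark moves. The analyses here quantify that behaviour in two latent
dimensions: the **angle** of the bump (decoded internal HD) and a global
multiplicative **network gain** scaling the whole population's activity
relative to baseline tuning.

Angles are degrees throughout, wrapped to the half-open interval
`[-180, 180)`, counter-clockwise positive. The offset is
`angdiff(θ_decoded, θ_measured) = measured − decoded` wrapped; the worked
sign case `decoded = measured − 90° ⇒ offset = +90°` is asserted in the
test suite and fixes the convention for every downstream analysis.

## Synthetic sessions (`synthgen`)

Every stage is testable against ground truth because the generator
emulates the statistics of the recordings:

- **Trajectory.** Head angular velocity is a discretized
  Ornstein–Uhlenbeck process (default stationary s.d. 60 °/s, time
  constant 0.5 s); heading is its wrapped integral. These values give
  full 360° coverage within a few minutes of simulated exploration, as
  real mice produce on a small elevated platform. Sessions of ≥ 3 min
  are re-drawn (bounded attempts) if any 1° bin goes unvisited.
- **Tuning.** HD cells get von Mises tuning curves,
  `f(θ) = peak · exp(κ(cos(θ − PFD) − 1))`, PFDs evenly tiling the
  circle with jitter, `κ ~ U(3, 8)` (half-width at half-maximum roughly
  25–40°) and `peak ~ U(0.5, 2)` a.u. No published parametric
  distributions exist for these widths and amplitudes; the ranges are
  the generator's assumption, chosen to look like thalamic tuning, and
  are config-exposed.
- **Emission.** Deconvolved-calcium-like activity is zero-inflated
  gamma: an exact zero with probability `p_zero` (default 0.5), else a
  gamma draw with fixed shape (default 2) and scale set so the mixture
  mean equals `gain(t) · f_i(internal HD at t)`. `p_zero` is constant
  per neuron; only the scale carries the tuning, the simplest model
  consistent with a ZIG noise description.
- **Protocols.** `two_min_shift` (3-min baseline, then 4 × [2-min
  darkness, 2-min cue at previous + 90°]), `twenty_s_shift` (alternating
  ±90° 20-s flashes between 2-min darkness epochs, D1–D7),
  `cue_rotation` (baseline, darkness, 7-min rotation at 1.5 or 3.0 °/s,
  darkness). Schedules are pure functions of the config. The cue
  channel carries the `CUE_OFF` (`NaN`) sentinel during darkness; epoch
  labels are authoritative.
- **Ground-truth drift.** The injected internal-minus-measured offset is
  zero at baseline, an OU walk mean-reverting toward 0 during darkness
  (controllable drift plus a weak baseline attraction, default s.d. 25°,
  τ = 60 s), and an exponential relaxation toward the cue-implied offset
  (τ = 5 s) while a cue is displayed.

What the generator does **not** emulate: behavioural correlates of gain
(angular-velocity dependence arises in real data, not in the generator
unless injected), anticipatory firing, non-HD spatial correlates, slow
nonstationarities (photobleaching, z-drift), and cross-neuron noise
correlations (emission noise is conditionally independent, matching the
decoder's assumption — real data violate it mildly). Passing recovery
tests therefore demonstrates correctness of the estimators under the
stated model, not robustness to every failure mode of miniscope data.

## HD-cell identification (`tuning`)

Tuning curves are occupancy-normalized at 1°/bin (activity summed per
bin over occupancy seconds), unvisited bins linearly interpolated around
the circle, then circularly smoothed with a 50° boxcar. Circular boxcar
smoothing conserves the curve mean exactly (asserted). The PFD is the
arg-max bin centre; because a boxcar can produce exact plateaus, ties
resolve to the circular centre of the maximal run (lower bin on even
runs), and a fully flat curve degenerates to the first bin.

The HD score is the Pearson correlation between the 3-frame-smoothed
activity and a Gaussian stimulus signal
`exp(-angdiff(PFD, θ(t))²/(2·17²))`. The activity is z-scored first;
Pearson r is affine-invariant, so this normalization is cosmetic.

The classification threshold is calibrated by an iterative shuffle
procedure: starting at `start_r = 0.9` (the start value is a convention,
config-exposed, since any sufficiently high start converges to the same
fixed point), neurons above threshold contribute `n_shuffles = 1000`
circularly time-shifted copies of their activity; shifts are drawn
uniformly from `[T/20, 19T/20]` to avoid near-identity shifts; the
threshold decreases by 0.01 until it reaches the null 95th percentile.
Circular shifting preserves both the activity's marginal distribution
and its autocorrelation, which is why it is the right null for
autocorrelated calcium traces. Implementation note: the correlation of
a circularly shifted copy with a fixed stimulus equals the circular
cross-correlation at that lag, so all T shift-correlations are computed
at once by FFT — the procedure is exact, just fast. Nulls pool per
recording group (one animal in the original design).

## Bayesian decoding (`decoder`)

The emission model is a per-neuron, per-1°-bin zero-inflated gamma fit
by method of moments: `p_zero` is the empirical zero fraction (activity
≤ 1e-10 counts as zero on continuous traces), shape `k = m²/v` and scale
`s = v/m` from the nonzero mean and variance. Binned sufficient
statistics are circularly smoothed (21° default) before the parameters
are derived, pooling sparsely occupied neighbouring bins; this biases
shapes slightly low where tuning varies quickly, a deliberate
variance/bias trade. Degenerate bins are clamped: all-zero bins get
`p_zero → 1` with floor gamma parameters; zero-variance bins hit the
shape ceiling (500); `p_zero` is clamped to `[0.001, 0.999]` so
log-likelihoods stay finite. A Poisson-style fallback is unnecessary
here because the ZIG moment fit is defined for every input after
clamping.

Decoding uses **all** recorded cells, not only classified HD cells
(avoiding selection bias), assumes independence across neurons (log
likelihoods add; asserted as an invariant), a uniform prior over bins,
and smooths the log-likelihood matrix with a centred 5-frame moving sum
per bin — log-domain addition, i.e. a product of likelihoods across
neighbouring frames. Whether the original smoothing operates in the
probability or log domain is not specified anywhere we could verify;
the log-domain reading is implemented as the default and the window-1
case is the exact identity. Edges use truncated windows. The decoded HD is
the per-column arg-max bin centre, ties toward the smallest bin.

## Network gain (`popstate`)

Under the model `r_{i,t} = α_t f_i(θ_t) + ε`, `ε ~ N(0, σ²)`, with
`f_i` the *baseline* tuning curve evaluated at the *decoded* head
direction (never the measured one — during drift the two differ and the
population follows the internal angle), the maximum-likelihood gain has
the closed form `α̂_t = Σ r f / Σ f²`; the noise variance cancels and
never needs estimating. The estimator equals the minimizer of
`Σ(r − αf)²` (checked against a refined grid search to 1e-6) and is
exactly equivariant to activity scaling. Gains are smoothed with a
20-frame moving average and normalized so the baseline mean is exactly
1. By default only classified HD cells enter the sum (their tuning
curves are meaningful); a config switch admits all cells. Frames whose
decoding failed propagate `NA`, never 0.

One practical caveat the test suite encodes: tuning curves must come
from epochs whose gain is flat (the baseline). If they are estimated on
frames that already carry a direction-dependent gain landscape, the
landscape is absorbed into the curves and the recovered gain flattens.

## Drift, resets, maps, vector fields

Offsets smooth both angle series circularly (20 frames) before wrapped
subtraction; darkness analyses optionally add a 300-frame low-frequency
version. Drift speed is the slope of a centred sliding 20-frame linear
regression on the unwrapped offset (implemented as an exact convolution
with the regression weights; even windows take one extra sample back,
matching the moving-average convention). Unwrapping is asserted to
produce spike-free speeds across wrap seams.

Reset events are extracted at cue onsets: pre-cue offset is the
circular mean over 50 frames (~1.67 s) before onset; the stabilized
offset is the circular mean over the final 30 s of the cue epoch (the
stabilization window is a package choice, config-exposed); the
trajectory is the onset-referenced offset over the first 1,450 frames,
and events whose cue epoch is too short are flagged and excluded.
Fast/slow classification is k-means (k = 2, 50 restarts, city-block
point-to-centroid distance, component-wise median centroids — written
in-package because no installed library offers L1 k-means). Raw cluster
labels are arbitrary, so "fast" is the cluster whose mean trajectory
covers half the cue shift earlier. Outlier exclusion everywhere is the
mean ± 3 s.d. rule.

Heat maps bin (angular velocity × internal HD) at 1.5 °/s × 1°, average
within overlapping ±3 °/s × ±15° windows, then blur with a 15-pixel
Gaussian — wrap-padded along HD (no seam at ±180°, asserted),
reflect-padded along velocity, and normalized-convolution so unvisited
pixels neither receive nor contribute weight. Pixel comparisons use
rank-sum tests on the raw windowed samples (not blurred values) at
α = 0.001 uncorrected, with the gain-map convention additionally masking
negative differences; no multiple-comparison correction is applied, by
design, and that caveat transfers to any use of the p-matrices. Whether
velocity should be signed or absolute is left to the caller; signed is
the default.

Vector fields bin (drift angle × drift speed) at 18 × 20°-bins over
`[-180, 180]°` and 20 bins over `[-3, 3] °/s`. A nominal y-bin width of
0.03 °/s is inconsistent with that range and count (20 × 0.03 ≠ 6); the
range and bin count are taken as authoritative, giving 0.3 °/s bins.
Drift acceleration is the slope of the drift-speed series over the same
20-frame regression window (the acceleration estimator is otherwise
unspecified; this choice keeps both axes' derivatives consistent).
Symmetrization averages the field with its origin reflection (vectors
negated); the output is exactly centrally symmetric, bins populated on
only one side take the (negated) populated value, and the operation is
idempotent. Streamlines integrate forward-Euler on bilinearly
interpolated vectors (missing bins filled nearest-neighbour, x-axis
circular, y clipped to range); the integrator and interpolation are
package choices not validated against any particular plotting library's
internals, which matters only for cosmetics, not for the convergence
statements the tests make.

## Polar embedding (`polarnet`)

Three parallel fully connected branches map the N-dim activity of one
frame to `(z₁, z₂, g)`; B₁ and B₂ have three hidden layers (64, 32, 16),
the middle branch two (32, 16); the loss is the MSE between
`(g z₁, g z₂)` and `(cos θ, sin θ)` on baseline frames. At convergence
`z₁ ≈ cos θ / g`, so the decoded angle is `atan2(z₂, z₁)` and the latent
radius `R̂ = 1/g` absorbs global activity fluctuations the angle cannot
explain. Hidden widths, activations, optimizer (full-batch Adam,
lr 2e-3, early stopping on a 20% validation tail) and epoch budget are
unpublished details; all are package choices and config-exposed. `g` is
passed through a softplus plus a 1e-3 floor so the radius is always
defined.

Two of those choices are load-bearing and worth the reader's attention:

- **Rectified-linear hidden units** (default, `tanh` available).
  Saturating units squash the effect of a global activity scaling; relu
  networks are approximately positively homogeneous, so a gain change
  never seen during baseline training still moves `g` roughly
  proportionally. In package experiments this roughly tripled the
  radius separation across ground-truth gain steps.
- **Scale-only input normalization** (divide by per-neuron training
  s.d., no centring, `center = TRUE` available). Centring turns a
  multiplicative gain change into an affine one and degrades
  extrapolation.

When the radius is compared against network gain, both are put through
the same 20-frame moving average the gain trace uses; per-frame radii
carry emission noise that the comparison convention should not penalize.
Radius dispersion shrinks with population size; the ring-tightness bound
(coefficient of variation < 0.2) is checked at full study scale
(165 cells), while smaller test populations tolerate proportionally
more.

## Ring-attractor model (`ringmodel`)

The underlying equations of the original model are not public; the
package implements a standard threshold-linear continuous attractor and
commits to reproducing the *qualitative* property suite, not
equation-level fidelity. Dynamics:

    τ dr/dt = −r + g_mod · relu(W_eff r_n + b) + I_cue + I_env (+ noise)

with `r_n` the rates normalized to unit total, `W_eff` a cosine
excitation kernel (`j1 = 2`) plus a global-inhibition offset
(`b = −0.35`) plus a velocity-scaled derivative (sine) kernel, τ = 0.1 s,
72 units. Normalizing the recurrent drive makes the bump *shape* an
attractor while `g_mod` sets its amplitude — total steady-state rate is
exactly linear in gain — and because the cue input is *not* scaled by
gain, a low-gain bump is weaker relative to the cue pull: that single
arrangement yields both the activity-conservation property and the
gain-controls-reset-speed property. The velocity pathway is the
classic asymmetric-kernel mechanism; its coefficient is calibrated
numerically at construction so a commanded 30 °/s moves the bump at
30 °/s, and sign-specific vestibular gains scale it asymmetrically.

The cue reaches the ring through a fixed Gaussian projection from
cue-position channels (von Mises concentration 1.5, broad enough that a
90°-shifted cue overlaps the bump's flank — this is what makes resets
continuous rotations through intermediate angles rather than jump-and-
reform, asserted via a unimodality check on the rate profile's
resultant). A second, weak pathway from **stable environment cues**
(amplitude 0.012 vs 0.05 for the cue) is plastic:
`ΔW = lr·(post ⊗ pre) − decay·W`, clipped non-negative, `lr = 0.6 /s`,
`decay = 0.012 /s`. After baseline training anchors it at offset 0, a
shifted-cue exposure builds a competing association at the reset
orientation at the weight-decay timescale (~80 s): 20-s exposures leave
baseline dominant (strong darkness reversion), 120-s exposures do not —
the experience-dependence result. Recalibration integrates a low-passed
(2 s) cue-minus-internal error into the vestibular gains
(`η = 5e-4 /s/deg`, clamped to `[0.1, 5]`); during cue rotation the
persistent tracking lag builds an asymmetry, and after cue-off the
symmetric head-velocity noise (s.d. 30 °/s) rectifies through it into a
same-direction drift that relaxes as the bump approaches the baseline
attractor. Whether the gain profile during resets is imposed or emergent
is treated as imposed (`gain_profile` argument), with the emergent
variant left to the caller via `g_mod` scheduling.

Model constants were chosen so the three phenomena sit at seconds-to-
minutes timescales with comfortable margins, and are all exposed in
`ring_state()`; the property suite (monotone gain→reset-speed, exposure
ordering, rotation bias with ablation control) is the module's contract.

## Problem sizes and determinism

The test and acceptance suites run at these sizes, chosen to keep the
statistics meaningful on a single CPU: decoder bound and embedding at
full study scale (165 cells, 10 min, 30 Hz); recovery tests at 60–120
cells and 4–10 min; ring-model property tests at dt = 0.02 s with 20
seeded repeats each, 20-s resets, 40-s baselines, 20/120-s exposures and
3-min rotations (the rotation protocol's 7-min version runs identically,
only longer). Every random stage derives a named substream from one
master seed; identical seeds give bit-identical sessions, labels and
pipeline CSVs (asserted).

## Known limitations

- The ZIG moment fit smooths moments across bins; with very sharp
  tuning and long sessions a per-bin maximum-likelihood fit would be
  slightly better calibrated.
- The decoder and gain estimator inherit the independence and
  global-gain assumptions; correlated noise or per-neuron gain
  heterogeneity would bias both in ways the generator does not model.
- Heat-map p-matrices are uncorrected across pixels by design.
- The ring model is a minimal rate model: no spiking, no conjunctive
  velocity cells, no fitted constants; it demonstrates sufficiency of
  the proposed mechanisms, not uniqueness.
- The polar network's extrapolation of the radius beyond the training
  gain range is approximate (relu homogeneity is broken by biases); the
  radius–gain relation is monotone but not exactly linear far from
  baseline.
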