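---
title: "Chaotic analysis of EEG epochs: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chaotic analysis of EEG epochs: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegchaos)
```

## The scientific question

Metabolic encephalopathy is a reversible, global disturbance of brain
function secondary to a systemic metabolic insult (hepatic, uremic). Its
EEG signature is a shift from the irregular, broadband activity of the
awake brain toward slower, more synchronized activity, classically
including triphasic waves: stereotyped complexes with a dominant positive
deflection flanked by negative deflections, above 70 µV, recurring at
1–2 Hz. If the healthy brain behaves like a high-dimensional, weakly
synchronized dynamical system, then increased synchronization should show
up as a *loss of dynamical complexity* in the EEG. This package measures
that loss with two invariants of nonlinear dynamics — the correlation
dimension (CD) and the largest Lyapunov exponent (LLE) — computed per
fixed-length EEG epoch, and then asks two statistical questions: do the
invariants separate encephalopathy-like from normal-like epochs
(nonparametric comparison, ROC), and can an SVM classify single epochs
from the feature pair (CD, LLE)?

Patient EEG from clinical archives cannot be redistributed, so the
package ships a synthetic-data module that emulates the *stated* signal
properties of the two groups, and validates the estimators against
canonical dynamical systems whose invariants are known analytically.

## The analysis pipeline

Each epoch is a 12-second, 500 Hz stretch of signal in microvolts (6000
samples), stored as plain ASCII text (one row per sample, one column per
channel). Preprocessing is a zero-phase Butterworth band pass, 0.5–60 Hz.

**Delay embedding.** A scalar series $x_1,\dots,x_N$ is embedded as
$X(n) = (x_n, x_{n-\lambda}, \dots, x_{n-(m-1)\lambda})$, giving
$N-(m-1)\lambda$ points in $\mathbb{R}^m$. The pipeline fixes $m = 10$
and $\lambda = 1$ for EEG epochs — a fixed operating point that makes
per-epoch indices comparable across a cohort — while the classical estimators for
choosing the parameters from data are available as separate functions:
first zero crossing of the autocorrelation, first minimum of the lagged
histogram mutual information (16 equal-width bins by default), and
Kennel's false-nearest-neighbour criterion (thresholds
$r_{tol} = 15$, $a_{tol} = 2$, acceptance at a false fraction below 1%).

**Correlation dimension.** The correlation sum
$C(r)$ is the fraction of admissible point pairs at distance $\le r$
(Euclidean norm). CD is the least-squares slope of $\log C(r)$ versus
$\log r$ over the linear scaling region. Two details matter in practice:

* *Theiler exclusion.* Successive EEG samples are strongly
  autocorrelated, so temporally adjacent points masquerade as geometric
  neighbours and inflate $C(r)$ at small $r$. Pairs closer in time than
  a Theiler window $w$ (default $m \cdot \lambda$) are excluded from both
  the numerator and the admissible-pair count. Setting `theiler = 0`
  recovers the literal all-pairs correlation sum.
* *Scaling-region selection.* The radii grid is 24 log-spaced values
  between the 1st and 50th percentile of a deterministic subsample of
  admissible pairwise distances. The fitted window is the contiguous run
  of at least 6 radii, among radii with $C(r) \in [10^{-3}, 0.5]$, that
  maximises the linear-fit $R^2$; the chosen bounds, $R^2$ and point
  count are reported in the `cd_fit` object so every estimate is
  auditable. Explicit bounds override the search.

**Largest Lyapunov exponent (Rosenstein method).** Every embedded point
is paired with its nearest neighbour at temporal separation greater than
the signal's mean period (estimated as the reciprocal of the
power-spectrum mean frequency). The pair's distance $d_j(i)$ is tracked
for $i$ steps and $y(i) = \frac{1}{\Delta t}\langle \ln d_j(i)\rangle$ is
averaged over surviving pairs; LLE is the slope of $y(i)$ over the
initial linear region. The default fitted region is anchored at step 0
and ends at the step maximising the fit $R^2$ (minimum five steps): the
divergence curve of a chaotic signal rises linearly and then saturates at
the attractor diameter, and extending the fit into the saturated plateau
would bias the slope toward zero. Pairs are dropped when either
trajectory runs off the data or the distance collapses to zero. With
$\Delta t = 1$ the exponent is per sample step, the dimensionless scale
on which awake-EEG values around 0.2 (normal) versus 0.08
(encephalopathy) are typically quoted.

**Statistics.** CD and LLE are compared between groups with the
Mann–Whitney U test (midranks; z from the tie-corrected normal
approximation with continuity correction; exact two-sided p for small
samples, by the null U distribution without ties or full permutation
enumeration with ties). The ROC analysis uses the orientation
*lower-score-indicates-positive*, because both invariants decrease in
disease: a case is called positive when its feature is strictly below
the cut-off. Under this orientation the trapezoid AUC equals
$U/(n_1 n_2)$, an identity the test suite asserts to $10^{-9}$.

**Classification.** Features are z-scored with training-set statistics
only, and a radial-kernel C-SVM (cost 1, $\gamma = 1/2$) is trained on a
seeded, stratified, disjoint 150/150-per-class split and evaluated on the
held-out half. The kernel and hyperparameters are configurable; the
defaults are the standard ones, exposed for override. Positive class is encephalopathy; accuracy, sensitivity
(`tp/(tp+fn)`) and specificity (`tn/(tn+fp)`) are reported next to the
confusion matrix, with explicit formulas, because reported
sensitivity/specificity labels are easy to swap when only the matrix is
shown.

## The synthetic cohorts: what they emulate, and what they do not

No generative model for the clinical cohorts exists, so the generators
are built strictly from the signal properties stated for each group:

* **Encephalopathy-like epochs** are a periodic train of triphasic
  complexes — three smooth Gaussian lobes of alternating sign, the
  positive lobe twice the negative lobes' amplitude — at 1–2 Hz (default
  1.5 Hz), peak amplitude above 70 µV (default 100 µV), over Gaussian
  background noise (default SD 5 µV). Lobe widths (0.12 s positive,
  0.07 s negative, ±0.18 s offsets) are free morphology parameters chosen
  so the waveform's dominant spectral peak stays within 1–2 Hz.
  Parameters outside the stated triphasic morphology are rejected.
* **Normal-like epochs** are a broadband mixture: five
  incommensurate-frequency rhythms spanning the delta-to-gamma bands
  (2.3, 6.1, 10.7, 19.3, 37.1 Hz at 14, 12, 16, 9, 6 µV), a chaotic
  Lorenz-x component and broadband noise (both band-limited to
  0.5–60 Hz, SD 8 µV each). Amplitudes were chosen once so that no
  single octave band holds more than 60% of the spectral power and at
  least 95% of the power lies inside 0.5–60 Hz.
* **Cohorts** derive per-epoch seeds deterministically from a master
  seed and jitter amplitudes and rates by ±10% (uniform) per epoch, so
  rank tests never see degenerate zero-variance groups. Epochs are
  single-channel by default; a `channels` parameter replicates the
  deterministic structure with independent noise per channel.

Passing tests on these cohorts shows that the *pipeline* recovers a
built-in complexity contrast with the right direction and effect
direction — encephalopathy-like epochs scoring lower CD and LLE — and
that the statistics and classifier behave correctly downstream. It does
*not* show that real encephalopathic EEG is separable at the same
operating points: the generators are not physiological simulations (no
neural mass dynamics, no inter-channel coupling, no artefacts, no
encephalopathy grades), and clinical cut-offs must come from clinical
data. A triphasic-wave-free low-complexity variant was deliberately not
shipped as a named generator: no quantitative description of such
epochs was available to build it from, though the triphasic generator's
morphology parameters span low-complexity variants if needed.

## Numerical choices and degenerate inputs

* **Filter realisation.** The band pass is a high-pass (order 3) /
  low-pass (order 6) Butterworth cascade, each applied forward-backward
  (zero phase, since phase distortion would warp the embedding
  geometry), after per-channel demeaning so the high-pass sees no DC
  step at the epoch edges. The cascade is used instead of a single
  band-pass design because a 0.5 Hz corner at 500 Hz sampling gives a
  numerically ill-conditioned band-pass polynomial. The default order 6
  keeps the transition band narrow enough that re-filtering an already
  filtered epoch changes its RMS by well under 1%.
* **Correlation counts.** Pair counting compares squared distances, so
  the compiled path is exactly reproducible by a plain double-loop
  oracle (no square roots to reorder rounding).
* **Histogram MI on noiseless periodic signals.** A pure sinusoid has an
  arcsine-shaped marginal whose bin occupancy makes the lagged-MI curve
  oscillate; the first-minimum delay rule is meant for noisy,
  band-limited signals (like EEG), where the curve is smooth and bottoms
  out near the quarter period. Similarly, sampling a periodic signal at
  an exactly commensurate rate collapses the orbit onto a few repeated
  points and degenerates every nearest-neighbour computation; the
  generators draw random phases, and validation uses incommensurate
  frequencies.
* **Map generators** enforce their bounded regimes: logistic growth
  rates outside (0, 4] and Hénon orbits that diverge are rejected, as
  are logistic orbits that hit an absorbing fixed point during burn-in
  (at least 100 iterations are always discarded).
* **Lorenz integration** uses a fixed-step RK4 scheme (internal step
  ≤ 0.005 time units) so trajectories are exact deterministic functions
  of their inputs; halving the step changes emitted samples by well
  under 1% RMS, which the tests assert.
* **Degenerate inputs** fail loudly rather than silently: constant
  signals (undefined autocorrelation/MI/normality), series too short to
  embed, radii grids without usable scaling points, single-class label
  vectors, and confusion-matrix metrics with zero denominators (returned
  as `NA` with a warning, never as 0).
* **Determinism.** Every generator is a pure function of (spec, seed);
  RNG state is saved and restored around seeded draws, nearest-neighbour
  searches and window selections are deterministic, and the pipeline's
  persisted artifacts are byte-identical across re-runs at a fixed
  master seed. Stage timings are logged to the console only.

## Problem sizes used in validation

Estimator validation uses the scales at which the invariants stabilise:
5000 samples for the logistic-map LLE (analytic value $\ln 2$), 10000
points for line/square/Hénon dimension recovery, and exact
oracle-equivalence checks for the correlation sum on trajectories up to
500 points. Cohort-level validation uses 150 epochs per group for the
group comparison and ROC, and 300 per group for the 150/150-per-class
held-out SVM; end-to-end byte-level determinism is asserted on a
20-per-group run of the full five-stage pipeline, determinism being
independent of cohort size.

## Known limitations

* CD and LLE at $m = 10$, $\lambda = 1$ on 6000-sample epochs are
  *operational* complexity indices, not converged invariants; absolute
  values depend on the embedding settings, the Theiler window and the
  scaling-region rule, all of which are therefore recorded in the fit
  objects.
* The K-S normality p-value uses estimated mean/SD without a Lilliefors
  correction, making it conservative; it is a screen, not an inferential
  endpoint.
* Multi-channel epochs are reduced by averaging per-channel features
  (configurable), a pragmatic default when no channel-level protocol is
  prescribed.
* The Wolf LLE algorithm is not implemented; Rosenstein's method is the
  primary estimator here.
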