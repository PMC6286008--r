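---
title: "Lagged Poincaré-plot analysis of REG pulse signals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lagged Poincaré-plot analysis of REG pulse signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regpoincare)
```

## The problem

Rheoencephalography (REG) measures electrical impedance through the
scalp; because blood conducts well, pulsatile cerebral blood volume
shows up as a pulsatile impedance signal of roughly 0.1 Ω amplitude at
the heart rate. Breath holding (apnea) raises arterial CO₂ and with it
cerebral blood flow, and the question this package addresses is whether
that physiological change leaves a detectable trace in the *nonlinear
dynamics* of the REG waveform — specifically in descriptors of its
two-dimensional time-delay embedding, the lagged Poincaré plot — when
classical pulse-geometry features see little.

The package implements the full pipeline as testable units: a synthetic
REG generator with an apnea and a baseline regime, band limiting and
artifact screening, pulse-geometry features, the Poincaré descriptors
over a range of lags, embedding-lag selection criteria, group
statistics, and leave-one-out-validated classification.

## Descriptors

For a segment $x(t)$, $t = 1..N$, and a lag $\tau$ (in samples) the
Poincaré plot is the point set $(x(t), x(t+\tau))$, $t = 1..N-\tau$.
Rotating by 45°:

* $SD1 = \mathrm{sd}\left((x - y)/\sqrt{2}\right)$ — spread
  perpendicular to the identity line, short-term variability;
* $SD2 = \mathrm{sd}\left((x + y)/\sqrt{2}\right)$ — spread along it,
  total variability;
* $SDarea = \pi \, SD1 \, SD2$ — the fitted-ellipse area;
* $SDratio = SD1/SD2$ — a dimensionless (ir)regularity index;
* $R$ — the Pearson correlation of $x$ and $y$;
* $CCM$ — the Complex Correlation Measure: the mean unsigned area of
  the triangles formed by consecutive point triplets, normalized by the
  ellipse area. Unlike the variance descriptors it is sensitive to the
  *temporal order* of the points.

Sample statistics use the $n-1$ denominator throughout; the rotation
identity $SD1^2 + SD2^2 = \mathrm{var}(x) + \mathrm{var}(y)$ holds
under either convention and is enforced by tests to 1e-10. Triangle
areas are $|\det|/2$ (the standard shoelace area); some CCM
formulations omit the $1/2$, which would scale every CCM value by a
constant 2 and nothing else. The normalizing count is the number of
triplets, $N_{plot} - 2$. $R$ is plain Pearson on the two windows (each
with its own mean and variance); using a single grand mean instead
changes values by $O(\tau/N)$.

Degenerate plots (zero variance in a coordinate, or $SD2 = 0$ making
the ratio undefined) raise classed errors from the scalar functions;
`feature_sweep()` converts them to `NA` rows with a warning so a sweep
never aborts.

## The synthetic generator

No public REG recordings accompany the analysis, so `generate_record()`
builds pulsatile signals from per-beat templates: a half-cosine
anacrotic rise over `rise_fraction` (default 0.22) of the beat and an
exponential-like decay back to the foot, each beat rescaled so its
max − min equals the drawn pulse range *exactly* (tests check 1e-9).
Defaults emulate the study conditions: 250 Hz sampling, 16-s segments,
mean period 0.99 s with 0.12 s between-segment SD, per-pulse ranges
near 0.092 Ω (apnea) and 0.099 Ω (baseline), plus a slow sinusoidal
drift (0.005 Ω at 0.05 Hz), 0.002 Ω white noise, 0.02 s beat-to-beat
period jitter and 2% beat-to-beat amplitude jitter.

The two regimes must differ in beat-to-beat variability structure so
that SDratio, R and CCM — not the geometry features — discriminate.
The mechanism is deliberately simple: in the apnea regime an AR(1)
path ($\phi = 0.9$), standardized per record and scaled by
`regime_modulation` (default 0.3), multiplies beat amplitudes by
$(1+m)$ and beat periods by $(1-m)$. Compressed-and-taller versus
stretched-and-smaller beats change pulse *slopes*, which is what the
short-term descriptors see at small lags, while total variance changes
much less. The strength was fixed once so that separation is moderate
rather than perfect (single-feature AUC ≈ 0.75–0.85 at small lags),
because a perfectly separable dataset would make every downstream
validation step trivially and uninformatively pass. The standardization
makes `regime_modulation` the *realized* modulation SD of each record,
which keeps the regime effect consistent across records instead of
letting short AR(1) paths average it away.

What the generator does **not** emulate: dicrotic notches and other
secondary waveform features, respiration or motion artifacts beyond an
amplitude-burst screen test, electrode or demodulation physics, and any
calibrated apnea effect size — the study quantifies no effect size, so
`regime_modulation` is a free parameter, not an estimate. Passing tests
therefore show that the *pipeline* behaves correctly and that the
descriptors react to correlated beat-to-beat modulation as expected,
not that real apneas are detectable at any particular accuracy.

## Preprocessing

`bandlimit()` applies, zero-phase, an order-4 Chebyshev type II
high-pass with 0.1 Hz stopband edge and an order-8 Chebyshev type II
low-pass with 20 Hz stopband edge. The second filter is a *low*-pass:
its stated purpose is rejecting electrical (mains) interference, and a
20 Hz high-pass would destroy the ~1 Hz pulse signal. Stopband
attenuation is 40 dB for both — a conventional value that, with order
and edge, fixes the designs uniquely. Zero-phase application preserves
pulse landmark timing.

Numerical care at the edges matters more than usual here because the
0.1 Hz high-pass has poles extremely close to the unit circle (its
impulse response needs ~8 s to decay to 1e-4). Filtering runs
forward-backward over a reflective pad of twice that settling length,
with steady-state initial conditions at the pad ends; the low-pass
(applied first) uses mirror reflection, which is value-continuous and
cannot fold fast oscillations into a level step, while the high-pass
uses point reflection, which continues the local trend that its slow
poles would otherwise ring against. The signal mean is subtracted
before filtering: Chebyshev II has a −40 dB ripple rather than a null
at DC, and REG analysis is offset-invariant. Even so, stopband
rejection *observed inside a 16-s window* is limited by edge
transients (roughly −26 to −35 dB for worst-case tones) rather than by
the −40 dB design; the design response itself is exposed by
`bandlimit_response()` and both are tested at their own scales.

`select_segments()` replaces the study's visual artifact inspection
with a reproducible screen: a window is rejected if any sample deviates
from the record median by more than 5× its MAD, or if a per-second
amplitude range exceeds 3× the record's median per-second range.

## Pulse geometry

`detect_landmarks()` finds pulse feet as local minima at least 0.4 s
apart (max 150 bpm) and places one maximum between each pair of feet,
which enforces strict alternation by construction. The ten features of
`compute_geometry()` are per-pulse values summarized by the median.
Units follow the magnitudes conventional for these descriptors: the
beat area is a trapezoidal integral in Ω·samples (a 0.09 Ω pulse of
~1 s at 250 Hz gives areas near 10), and derivative features are
per-sample forward differences.

## Lag selection

`tau_criteria()` evaluates eight classical criteria: T/4 and T/5 of the
dominant period (the ACF peak within 0.33–2 s, i.e. 30–180 bpm), the
first AMIF minimum, the first ACF zero, the 1/e decay, the first sign
change of the ACF second derivative, and 1/10 and 1/20 of the first ACF
local minimum lag (the lag, not the value — the only dimensionally
sensible reading). The ACF uses the biased estimator (divide by $n$),
which keeps $|\rho| \le 1$ and the sequence positive semidefinite.

The AMIF is estimated from a 16×16 equal-width histogram. That
estimator carries strong binning ripple — on a noiseless sinusoid the
raw $I(\tau)$ curve has spurious strict minima every few samples — so a
5-point moving average is applied before the minimum search, and the
result should be read at roughly that resolution. A consequence worth
stating honestly: on a pure sinusoid the first smoothed minimum falls
near T/8, well before the T/4 decorrelation lag; the same ordering
(AMIF minimum well below first ACF zero) appears in published values
for real pulse signals, so the estimator was kept as is.

`ccm_inflection()` implements the observation that CCM-vs-τ curves fall
steeply and then flatten; the knee is a natural upper bound for useful
lags. The curve is smoothed (5-point moving average) and the knee is
the first lag past the steepest descent where the slope has recovered
to 20% of that steepest rate. The 20% threshold (exposed as
`plateau_frac`) is deliberately loose because empirical CCM curves keep
a long shallow tail after the physiological knee; with it, the knee on
the default synthetic dataset (τ ≈ 18) coincides with the ACF
second-derivative criterion, the agreement that motivates the knee as
a criterion in the first place. The reference slope is the *steepest*
smoothed slope rather than the slope at τ ≤ 3 because the curve is
concave at the origin, which would otherwise make the knee drift with
small changes in the early curve.

## Group statistics and classification

`compare_groups()` gates on normality — Lilliefors-corrected
Kolmogorov–Smirnov at α = 0.05 in both groups (the correction is
required because mean and SD are estimated from the data) — choosing a
Welch t-test or a two-sided Mann–Whitney U. Significance is flagged at
0.05 and at the Bonferroni-corrected 0.025 (two feature families), a
fixed threshold rather than division by the number of lags, matching
the convention of the original analysis. AUC uses the rank
(Mann–Whitney) formulation, oriented to ≥ 0.5 with the direction
recorded; the operating point is Youden-optimal.

`loocv_evaluate()` holds out each segment once and pools the held-out
scores. Classifier choices where the source analysis is silent:
logistic regression is an unpenalized binomial GLM; naïve Bayes uses
Gaussian class-conditionals; the SVM is linear with C = 1, scored by
its decision value; CART uses Gini impurity, minimum leaf size 3 and no
pruning (`cp = 0`). Input combinations never include both SDratio and R
(they are nearly collinear, pooled correlation ≈ −0.97).

One pitfall is documented rather than hidden: **pooled leave-one-out
scores are pessimistically biased under the null.** Removing a segment
from training shifts the fitted model away from that segment's class,
so held-out scores anti-correlate with labels when there is no signal;
with ~50 segments the permuted-label AUC of the unregularized logistic
model sits near 0.31, not 0.5. The regularized SVM and the
coarse-scored CART stay within 0.5 ± 0.1, and the null-calibration
tests use the SVM for that reason. Flagged performance (AUC > 0.8,
accuracy ≥ 80%) on the default synthetic dataset should be read with
this small-sample caveat, as should any LOO result at this n.

## Problem sizes and numerical choices

The test suite and the analysis scripts run the study-scale dataset (53
segments × 70 lags = 3710 descriptor rows) and smaller fixtures chosen
so the full suite completes in about a minute: the CCM oracle runs 100
random series of length 10–50; identity properties run on 1000 random
plots; the type-I calibration uses 1000 replicates at n = 24/29; the
permutation nulls use 25–40 permutations. `scripts/acceptance.R`
regenerates a 50-segment dataset and reports the recovered mean pulse
period. Seeds are fixed at the call sites; the generator draws
everything from one seeded stream per call and holds no global state.

## Known limitations

* The apnea/baseline mechanism is one plausible choice among many; the
  package demonstrates descriptor sensitivity to correlated
  beat-to-beat modulation, not clinical apnea detectability.
* Edge transients bound the in-window stopband rejection of the 0.1 Hz
  high-pass on short records; segments cut from long recordings (the
  intended use) do not suffer this.
* The AMIF estimator localizes minima only to ~5 samples.
* Pooled-LOO AUC is biased under the null for unregularized
  probabilistic classifiers (see above).
* Embedding dimension is fixed at m = 2; higher-dimensional
  reconstruction, recurrence quantification and entropy-family
  descriptors are out of scope.
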