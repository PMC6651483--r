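---
title: "Detecting movement-pattern divergence with an LSTM forecaster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting movement-pattern divergence with an LSTM forecaster}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Wearable accelerometers make it cheap to record how a person moves over a
full day, but *comparing* movement between groups — say, children with a
neurodevelopmental condition against typically developing peers — is harder
than comparing how much they move. Two children can have identical activity
levels yet move in characteristically different ways. `actilstm` implements
a pattern-level comparison: a recurrent forecaster learns what typical
movement looks like from a reference ("control") group, and movement
fragments from new participants that the forecaster cannot predict are
counted as evidence of patterns absent from the reference repertoire.
Per-participant counts of such "non-similar" fragments, stratified by
movement intensity, are then compared between groups with standard
two-sample tests.

The pipeline assumes four tri-axial accelerometers (left/right wrist and
ankle: `lh`, `rh`, `lf`, `rf`), sampled at a nominal 10 Hz — adequate
because the bulk of voluntary limb-movement power sits below about 2 Hz —
and a deliberate synchronization shake recorded while the four sensors are
held together.

## Preprocessing: orientation-invariant vertical acceleration

Raw samples $\vec a_t(i)$ live in each sensor's own, unknown and possibly
drifting, coordinate frame. Comparable signals are obtained by projecting
onto the gravity direction:

1. **Gravity estimate.** $\vec g'(i)$ is the mean of $\vec a_t$ over a
   centered window of $N+1$ samples (default $N = 20$, i.e. 2.1 s at
   10 Hz). The window is truncated, not padded, at the recording edges: no
   invented data. The window passes the DC gravity component and strongly
   attenuates the $\gtrsim 0.5$ Hz movement band.
2. **Movement acceleration.** $\vec a_m(i) = \vec a_t(i) - \vec g'(i)$.
3. **Vertical projection.** The signed component along the unit gravity
   direction, $a_v(i) = \vec a_m(i) \cdot \hat g'(i)$, in g units. The
   parallel/orthogonal decomposition $\vec a_m = \vec a_{mv} + \vec a_{mh}$
   is exactly orthogonal by construction. Two normalizations are defensible
   here (dividing by $\lVert g' \rVert$ or by $\lVert g' \rVert^2$); they
   differ by $\lVert g' \rVert \approx 1$ g. We use the unit-vector form so
   that $a_v$ — and therefore every intensity threshold downstream — is in
   g units.

$a_v$ is invariant to any fixed rotation of the sensor frame, and tracks
slow orientation drift as long as the drift is slow relative to the filter
window.

**Synchronization.** The shake burst is found per channel by scanning
$|a_v|$ for the first sample at or above `th1` (default 2 g), then
returning the first later index where the forward mean of $|a_v|$ over
`n_sync + 1` samples (default 11, i.e. 1.1 s) falls to `th2` (default
0.5 g) or below. We read the burst-exit criterion as a mean of *absolute*
values: the synchronization shake oscillates, so its signed mean is near
zero and a signed criterion would terminate the burst at its first sample
rather than its end. All four channels are trimmed to their own detected
burst end and truncated to the common length. `th1`/`th2` are only
constrained by inequalities (above rest, below burst); the defaults sit
between the synthetic rest amplitude and the 3 g synthetic burst and are
fully configurable.

## Windowing and intensity stratification

Synchronized recordings are divided into non-overlapping 8-second windows
(80 samples; any trailing remainder is discarded); the first 6 s of each
window is the forecaster input and the final 2 s the target. Each window's
movement intensity is the sample standard deviation (denominator $n-1$)
pooled over all $80 \times 4 = 320$ values — the literal "combined"
reading; a per-channel-mean alternative would differ only in how
cross-channel imbalance is weighted. Windows are assigned to half-open
intensity bins, by default $[0, 0.2), [0.2, 0.4), \ldots, [0.8, 1.0),
[1.0, \infty)$ g; the sub-0.2 edges and the treatment of fragments above
1 g are package choices matching the named analysis intervals.

## The forecaster

A two-layer LSTM processes the 60-step, 4-channel input
$x_t = (lf_t, lh_t, rf_t, rh_t)$ from zero initial state:

$$f_t = \sigma(W_f x_t + U_f h_{t-1} + b_f), \quad
  i_t = \sigma(W_i x_t + U_i h_{t-1} + b_i), \quad
  o_t = \sigma(W_o x_t + U_o h_{t-1} + b_o)$$
$$c_t = f_t \odot c_{t-1} + i_t \odot \tanh(W_c x_t + U_c h_{t-1} + b_c),
  \qquad h_t = o_t \odot \tanh(c_t)$$

with 50 memory units in the first layer and 20 in the second, weights
shared across time steps, and the first layer's per-step outputs feeding
the second. A dense affine map takes the second layer's *final* hidden
state to the 80 predicted values (20 steps × 4 channels, channel-major).
Feeding only the final state — rather than the full output sequence — is a
design choice: the final state already summarizes the window, and the
smaller head has fewer parameters to overfit; the alternative is reachable
through the configuration. Deeper variants (e.g. three 50-unit layers) are
supported via `hidden_sizes` but are not the default: on data of this kind
they mostly add training cost and overfitting risk.

Training minimizes the mean squared forecast error over control-group
windows with minibatch Adam (learning rate $10^{-3}$, batch 64),
early-stopped on a 10% validation split with patience 5 and a cap of 20
epochs; initialization, the split and the batch order are all seeded, so
identical inputs reproduce identical parameters. The epoch cap is sized to
the synthetic cohorts used throughout this package's validation, where the
validation MSE has flattened well before it; for richer real recordings it
should be raised. Inputs are not rescaled — vertical acceleration in g is
already $O(1)$ — so similarity thresholds stay comparable across runs. The
forward pass and backpropagation through time are implemented as compiled
(RcppArmadillo) kernels; the scalar gate equations in `lstm_cell_step()`
are the readable reference implementation, and the test suite holds the
two to within $10^{-10}$ of each other and of finite-difference gradients.

## Scoring and inference

Each window's prediction is compared with its observed target by the
Pearson correlation of the two flattened 80-value vectors (channels
concatenated — the literal reading of whole-output "reconstruction
similarity"; a per-channel-mean variant is a one-line change). A window
with $r$ below the similarity threshold `th` (default 0.5) is
**non-similar**. If either vector is essentially constant (variance
$< 10^{-12}$) the similarity is defined as 0: an uninformative forecast
should never count as a match. True rest windows are near-constant and
therefore score non-similar for *every* participant; they land in the
lowest intensity bin and cancel in group comparisons.

Per-participant non-similar counts — overall and per bin — are compared
with a **one-sided pooled-variance two-sample t-test** (case group mean
greater than control), $df = n_a + n_b - 2$. One-sided pooled is the
configuration that reproduces the published group-level p-values from
their printed count summaries (verified in the test suite against
`stats::t.test` and the t-distribution CDF); the Welch variant is
available and differs negligibly at these group sizes. No multiple-testing
correction is applied across bins, matching the original analysis; the
report keeps every comparison visible, and bins where a test is impossible
(no windows, zero variance in both groups) are flagged `undefined` rather
than dropped. Threshold sweeps recompute counts from stored correlations
without re-running the model; counts are provably non-decreasing in `th`.
Group separability is summarized by the pairwise-comparison AUC (ties
count one half, identical to the scaled Mann–Whitney statistic) with the
operating point chosen as the smallest count threshold maximizing
Youden's index.

## The synthetic cohort generator

No recordings ship with the package, so validation rests on a seeded
generator that emulates the statistical structure the analysis relies on,
with full ground truth:

* **Motifs.** Movement templates are random sine series (harmonics 1–4,
  coefficients decaying as $1/k$) on a fundamental period of 21 samples,
  normalized to unit pooled SD, so an amplitude scale maps linearly onto
  fragment intensity. The harmonics span 0.48–1.9 Hz, respecting the
  \<2 Hz band limit of voluntary movement. The period is deliberately
  equal to the default gravity-filter window ($N+1$): every harmonic sums
  to exactly zero over any 21 consecutive samples, so the moving-average
  gravity estimate is *exact* in motif interiors and the projection
  round-trip recovers the planted vertical acceleration to machine
  precision there. An edge taper would break this exactness, which is why
  motifs instead start and end at zero through the sine-only construction.
  Filter transients remain at slot boundaries (half a window on either
  side), as they would at any real signal discontinuity.
* **Scheduling.** Post-shake content is laid out in 8-s slots aligned with
  the analysis windows; a fraction of slots (default 0.3) is rest. Each
  motif slot draws a template and an amplitude scale (uniform on
  0.05–1.1 g). Slot alignment makes the forecasting task well-posed — the
  6-s context identifies the motif and phase, and the 2-s continuation is
  deterministic — which is what lets a scaled-down cohort exercise the
  full detection mechanism.
* **Divergence.** Atypical participants draw a fraction $\delta$ of their
  in-band motifs from a disjoint dictionary; controls never do. The random
  stream is consumed identically in both groups, so $\delta = 0$ collapses
  the groups sample-for-sample.
* **Embedding.** The world-frame signal (gravity $+\,a_v\hat z\,+$
  horizontal band-limited noise at 30% of the vertical amplitude) is
  rotated into a per-sensor frame: a uniformly random fixed rotation
  composed with a rotation-vector random walk (default 0.01 rad/s),
  applied exactly via the Rodrigues formula. White sensor noise (default
  0.02 g) is added in the sensor frame.
* **Shake.** A 3 g, 3 s alternating-sign vertical burst with per-sensor
  lead-ins of 0/5/10/15 samples precedes the content; the first content
  slot is forced to rest so burst-exit detection lands at the content
  start. The burst strictly dominates every motif amplitude (unit-SD
  templates are peak-capped at 1.8, scales at 1.1 g), making `th1`/`th2`
  detection unambiguous.

What the generator does *not* emulate: biomechanically realistic gait or
fidgeting, non-wear and diary-annotated removal periods, sensor
re-positioning, medication pharmacodynamics, or the sheer diversity of
real 24-h behaviour. Passing the synthetic validation therefore
demonstrates that the machinery — projection, synchronization, training,
scoring, inference — works as specified, not that the effect sizes seen on
real cohorts will reproduce.

## Problem sizes used in validation

The test suite and acceptance script run the full design at a scaled-down
size chosen so the whole validation is convenient on a laptop: 9
control-train / 9 control-test / 9 atypical participants, 10 minutes of
10 Hz signal each (75 windows per participant), divergence $\delta = 0.8$
confined to the 0.4–1.0 g band, against $\delta = 0$ null cohorts, across
20 seeds each. The 24-hour windowing arithmetic (10 800 windows per
participant) is checked directly on a full-length recording.

## Known limitations

* The t-test treats per-participant counts as approximately normal; with
  9 participants per group this is a pragmatic choice inherited from the
  original analysis, not an endorsement.
* Exact reproduction of any fitted model from the original study is
  impossible — training duration, optimizer and normalization there are
  unreported — so only the printed summary statistics are reproduced
  numerically; absolute fragment counts require the original recordings.
* One model is trained per run (optionally per intensity bin); no
  hyperparameter search is attempted.
* Sampling jitter, resampling and gyroscope/magnetometer fusion are out of
  scope; timestamps are sample-index based and the nominal rate is
  metadata.
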