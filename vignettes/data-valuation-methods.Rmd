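---
title: "Valuing training windows in wearable-sensor activity recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing training windows in wearable-sensor activity recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Human activity recognition (HAR) from body-worn inertial measurement units
(IMUs) trains classifiers on fixed-length windows of multichannel
time series — typically 3-axis accelerometer plus 3-axis gyroscope channels,
cut into windows of 1–3 seconds with 50% overlap. Labels for such windows
come from manual annotation of video-synchronised recordings and are noisy;
in clinical settings (balance assessments, rehabilitation scoring) the label
budget is small and corrupted labels measurably degrade the classifier.

`harvalue` assigns every training window a *value*: the probability, in
(0, 1), that the window should be selected into the training set of the task
classifier. Windows carrying wrong labels receive low values, so ranking by
value simultaneously (a) discovers corrupted annotations for review and
(b) improves the classifier by down-weighting or removing the worst data.

## The model

Three networks cooperate:

**Data value estimator (DVE), `h(x, y)`.** A raw window `x` (W timesteps x C
channels) is embedded by a 1D convolution (64 filters, kernel 3, GeLU), a
sinusoidal positional encoding, and two identical transformer encoder blocks
(2 self-attention heads, 256-unit feed-forward layer, GeLU, dropout 0.1),
then average-pooled over time. The pooled embedding is concatenated with the
one-hot label and refined by five 100-unit ReLU dense layers. Just before
the output, the *marginal information* vector `m(x, y)` is concatenated, and
a final dense layer with a sigmoid produces the selection probability. The
selection probability *is* the sample's value.

**Marginal information.** `m(x, y) = |onehot(y) - f_v(x)|`, where `f_v` is a
predictor pretrained on the clean validation split and then frozen. Every
component lies in [0, 1]; for a mislabelled window the components at the
true and claimed classes are both near 1, so `m` is a per-class
contamination signal. Feeding it directly into the last layer gives the DVE
a short, easily credited path to the dominant cue while the feature
extractor learns whatever the validation predictor cannot see.

**Task predictor, `f(x)`.** A double-head 1D-CNN stacking ensemble: parallel
convolutions with kernel sizes 1 and 3 (64 filters, ReLU) extract
per-timestep and local-context features, each head is globally max-pooled
over time, and the concatenated features feed a dense softmax classifier.
It is trained by Adam (learning rate 0.01) on the *value-weighted*
cross-entropy `(1/N) * sum_i w_i * CE(f(x_i), y_i)` — normalised by the
count, not by the weight sum, so down-weighting data genuinely shrinks the
gradient instead of renormalising it away.

## Training (REINFORCE with a moving-average baseline)

The sampler that turns probabilities into a binary selection is not
differentiable, so the DVE is trained with a policy gradient. One outer
iteration:

1. draw a selection batch of `Bs` training windows and their probabilities
   `w_j = h(x_j, y_j)`;
2. sample `s_j ~ Bernoulli(w_j)` (if every draw is 0 the draw is repeated up
   to 10 times, then the maximum-probability window is force-selected —
   Eq.-weighted training is undefined on an empty set);
3. restore the predictor to its warm-start snapshot and run `NI`
   selection-masked Adam steps of size `Bp` on the selected windows;
4. measure the mean validation cross-entropy `L`;
5. update the DVE by one Adam step on the surrogate
   `(L - baseline) * log pi(s)`, where
   `log pi(s) = sum_j [s_j log w_j + (1 - s_j) log(1 - w_j)]`;
6. advance the baseline `delta <- ((T-1)/T) delta + L/T`.

Selections whose validation loss beats the baseline are reinforced — their
selected windows gain probability relative to the unselected ones.

Three numerical choices matter at small scale and are deliberate design
decisions of this package:

* **Baseline debiasing.** The moving average starts at 0, so for roughly `T`
  iterations the raw advantage `L - delta` is systematically positive, and a
  short run is spent entirely inside that transient. The advantage therefore
  uses the bias-corrected average `delta / (1 - ((T-1)/T)^k)` after `k`
  updates — the same start-up correction Adam applies to its moments. The
  recursion itself is unchanged; the first iteration, having no history,
  uses advantage 0.
* **Zero-initialised policy head.** The DVE's final dense layer starts at
  zero, so every window starts at value exactly 0.5 and the policy gradient
  alone decides the sign of each feature's influence. With a random final
  layer, the marginal-information weights can start anti-correlated with
  contamination, which a short run cannot reliably undo.
* **Exploration regularisation.** The Bernoulli policy has two absorbing
  regions — select everything, select nothing — where the sigmoid saturates
  and the policy gradient vanishes. A penalty
  `1000 * [relu(mean(w) - 0.9) + relu(0.1 - mean(w))]` keeps the mean
  selection probability inside its responsive band. It is standard practice
  in this family of valuation algorithms and can be disabled with
  `trainerConfig(explorationWeight = 0)`.

* **Common random numbers.** Each outer iteration re-seeds the inner
  predictor loop identically, so the mini-batch sequence is the same in
  every iteration and reward differences are attributable to the selection
  vector rather than to batch noise. Because the Adam update is
  sign-normalised per coordinate, un-paired reward noise would otherwise
  translate into full-size policy jumps.

The predictor is warm-started once on the full training split and restored
to that snapshot at every outer iteration. With a persistent predictor the
validation loss drifts downward with accumulated training regardless of the
selection, so the advantage stops measuring selection quality; restoring the
snapshot makes each reward a controlled experiment on the current selection
only. Both networks use Adam with conventional moments (0.9/0.999, eps
1e-8). Probabilities are clipped to [1e-6, 1 - 1e-6] wherever a logarithm is
taken.

### Defaults and their origins

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.01 | predictor Adam learning rate |
| `beta` | 0.01 | DVE Adam learning rate |
| `Bp` | 64 | predictor mini-batch (small-data profile; 1024 suits large public datasets) |
| `Bs` | `min(N_train, 4*Bp)` | selection batch |
| `NI` | 200 | inner predictor iterations per outer iteration |
| `T` | 20 | moving-average window of the baseline |
| `outerIters` | 30 | outer DVE iterations |
| conv filters / kernel | 64 / 3 | DVE backbone |
| heads / FFN / dropout | 2 / 256 / 0.1 | transformer encoder blocks (2 blocks) |
| MLP | 5 x 100 ReLU | label-conditioned refinement |
| predictor kernels | 1 and 3 | double-head 1D-CNN |

## Evaluation statistics

**CSD (corrupted sample discovery).** Sort training windows ascending by
value; accumulate the lowest `v*r` windows, `v = round(0.05 * N)`,
`r = 0..10`; report the fraction of the injected corruptions contained in
the accumulated set. The ideal curve is `min(v*r/o, 1)` for `o` corruptions:
with a 20% corruption rate it reaches 1 at `r = 4` (20% of the data
removed). Under random values the expected discovery at fraction `f` is `f`.
CSD is a rank statistic — any strictly monotone transformation of the
values leaves it unchanged.

**RHLVS (remove high/low-value samples).** For each `r`, retrain a reference
classifier from scratch on the training split minus the top (resp. bottom)
`v*r` windows by value — remaining windows weighted by their values, as the
weighted objective prescribes (`weighted = FALSE` trains unweighted) — and
record test accuracy. Good valuations keep the remove-low curve flat or
rising while the remove-high curve falls. Three reference variants are
provided: a conv/pool stack with a GRU(8) tail and 50% dropout (clinical
profile), the same with 70% dropout (complex public-data profile), and a
flatten + dense baseline without recurrence; all convolutions use 64
filters, kernel 3, ReLU, max-pooling 2, and a 100-unit dense layer. Ties in
the value ranking are broken by sample index, so both removal directions
are deterministic; each curve shares one initialisation seed across its
retrainings for comparability.

## The synthetic generator

`generateDataset()` emulates windowed IMU HAR data: class `k` carries a
sinusoid of `k + 1` cycles per window, with channel-specific amplitudes
(0.6–1.1), phases and small DC offsets, plus i.i.d. Gaussian noise
(`noiseSd = 0.5` by default against unit-order signatures — separable but
not trivial, so that label corruption measurably hurts training). Windows
are assigned to train/validation/test in a 4:2:3 ratio by seeded shuffling,
with largest-remainder rounding (deterministic, sums to N). Splits are
sample-wise, not subject-wise — there are no subjects. `corruptLabels()`
flips `round(rate * N_train)` uniformly chosen training labels to uniformly
drawn *different* classes and records the ground truth.

What the generator does *not* emulate: sensor drift and orientation error,
subject-level covariance (windows from one recording are correlated in real
data; here they are exchangeable), class imbalance (use
`oversampleAugment()` to rebalance real data), and non-stationary activity
transitions. Tests passing on this generator show the algorithm's machinery
works end to end — they do not certify performance on clinical recordings.

## Problem sizes used by the tests

The end-to-end checks run the full pipeline on 270 windows (3 classes x 90,
64 timesteps x 6 channels) with 20% corruption, a small training profile —
50 inner iterations, 15 outer iterations, 100 pretraining iterations —
and a 40-iteration baseline classifier for RHLVS, across three seeds. These
sizes were chosen so a complete run is a desk-scale computation while the
corrupted/clean value gap, the CSD curve and the RHLVS ordering remain
clearly resolved.

```{r, eval = FALSE}
library(harvalue)
ds <- normalizeDataset(generateDataset(syntheticSpec(seed = 1)))
cor <- corruptLabels(ds, rate = 0.2, seed = 1001)
vt <- trainValuation(
  cor$dataset,
  trainerConfig(NI = 50, outerIters = 15, Bp = 64, seed = 2001),
  predCfg = predictorConfig(iterations = 100)
)
plot(csd(vt, cor$record))
plot(rhlvs(cor$dataset, vt, classifierSpec("public_baseline"), seed = 3001))
```

## Known limitations

* REINFORCE with a single Monte-Carlo selection per iteration is
  high-variance; short runs depend on the stabilisers above, and at 15
  outer iterations occasional seed combinations still fail to separate
  corrupted from clean data. Longer runs (the 30-iteration default and
  beyond) average the noise down. Differentiable relaxations
  (Gumbel-softmax) are out of scope.
* The method needs a clean validation split; if the validation labels are
  themselves corrupted, the marginal information and the reward both
  mislead.
* The reward is the mean validation cross-entropy
  (`rewardType = "accuracy"` switches to 1 - accuracy); losses other than
  cross-entropy are not implemented.
* Windows are valued independently; duplicated windows receive equal values
  rather than sharing credit.
* All networks run on CPU in plain R; the implementation targets datasets of
  hundreds to a few thousand windows, not the millions-of-windows regime.
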