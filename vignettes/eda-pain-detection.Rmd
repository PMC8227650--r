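---
title: "Real-time EDA indices for acute pain detection: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Real-time EDA indices for acute pain detection: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Skin conductance (electrodermal activity, EDA) is driven purely by
sympathetic sudomotor innervation, which makes it an attractive signal for
*objective* pain monitoring: an acute painful stimulus evokes a skin
conductance response (SCR) within a couple of seconds. `edapain` implements a
complete computational chain for near-real-time pain detection from a
wrist-worn EDA stream: preprocessing, two complementary decompositions
(a time-frequency decomposition and a convex tonic/phasic decomposition),
three per-sample indices, a causal streaming scheme, stimulus-locked segment
features, discriminability statistics, and a subject-wise machine-learning
evaluation harness. Because the human datasets this class of methods is
evaluated on are not freely redistributable, the package ships a synthetic
EDA generator with exact ground truth, and every stage is validated against
it.

## Preprocessing

`preprocess_eda()` converts an irregularly sampled conductance trace (tens to
~130 Hz) into the uniform 2 Hz series all indices consume:

1. cubic-spline resampling to 4 Hz (natural spline in batch mode);
2. a centered running median of 5 samples (1.25 s — the narrowest odd,
   centered window spanning at least one second) to remove impulsive
   artifacts;
3. decimation to 2 Hz;
4. a second-order zero-phase Butterworth high-pass at 0.01 Hz.

The high-pass is applied forward–backward with odd-reflection padding and
steady-state initial conditions, so a constant input is rejected to machine
precision and edge transients die inside the padding (the pad spans five
filter time constants, ~80 s at the 0.01 Hz cutoff). In causal mode — used
by the streaming scheme — each stage is replaced by a causal counterpart:
local monotone cubic Hermite interpolation (finite stencil, so future
samples cannot influence past output), a trailing median, and a single
forward filter pass initialised at steady state.

## VFCDM: variable frequency complex demodulation

`vfcdm_decompose()` splits the 2 Hz series into 12 narrow bands centered at
0.04–0.92 Hz in 0.08 Hz steps. Stage 1 shifts each band to baseband
(multiplication by a complex carrier) and isolates it with an *ideal*
low-pass of cutoff 0.04 Hz; stage 2 estimates each band's
instantaneous-frequency track from the stage-1 phase and re-demodulates the
band content along that track, sharpening the amplitude/phase estimates of
non-stationary oscillations. Each band is reconstructed as
`A(t) cos(Phi(t) + phi(t))`.

Three realization choices matter and were settled by measurement:

* **The ideal low-pass is realised exactly in the frequency domain.** Each
  band is a one-sided partition cell of the input's own DFT, so the 12 real
  band signals tile the spectrum up to 0.96 Hz and their sum reproduces any
  input band-limited below that (relative RMSE ~1–2% on 300-s signals,
  limited only by record-edge effects). A realizable FIR at 2 Hz cannot do
  this: with 64 taps its transition band (~0.1 Hz) exceeds the 0.08 Hz band
  spacing, which both blurs band assignment and breaks reconstruction.
* **The lowest band is not refined.** Re-demodulating the 0–0.08 Hz band
  would require a low-pass cutoff below its 0.04 Hz center *and* at least
  half a band wide — impossible — because its spectral mirror image overlaps
  any sufficiently wide filter. Band 1 therefore carries the stage-1 content
  (it holds the DC-side residue; TVSymp never uses it).
* **Stage-2 tracks are confined to a trust region.** Unconstrained tracks in
  weak bands wander, and re-demodulation along a wandering track smears
  content across band boundaries, destroying reconstruction. Tracks are
  gated where the band envelope is below 25% of its maximum, smoothed over
  10 s, and clipped to ±bandwidth/4 around the center. With these defaults
  an in-band chirp is still tracked essentially perfectly (r > 0.999).

The first and last 10 s of a decomposition (`edge_s`) are record-edge
transients and downstream consumers should not trust them.

## The three indices

**TVSymp** (`tvsymp()`): sum VFCDM components 2 and 3 (centers 0.12 and
0.20 Hz — together covering roughly the 0.08–0.24 Hz range where
sympathetically mediated EDA dynamics concentrate), normalize the sum to
unit sample variance (the mean is not subtracted: band-pass components are
already zero-mean), and take the instantaneous amplitude of the analytic
signal. A unit-variance sinusoid has amplitude `sqrt(2)`, which is the
calibration every implementation should reproduce.

**MTVSymp** (`mtvsymp()`): at each sample subtract the mean of the preceding
`k = 5` seconds of TVSymp and floor at zero. This emphasises abrupt
sympathetic surges and suppresses sustained elevation. The definition is
undefined inside the first `k` seconds; there the trailing mean uses all
available history, and the first sample is 0.

**dPhEDA** (`dpheda()`): the five-point-stencil central difference of the
phasic component from the convex decomposition, exact for polynomials up to
degree 4; the series is replicate-padded two samples at each end so lengths
stay aligned for segment extraction.

## Convex tonic/phasic decomposition

`cvxeda_decompose()` models the series as

```
y = M q + B l + C d + residual,   q >= 0
```

where `M q` is the response of a Bateman second-order system (time constants
`tau0 = 2.0 s`, `tau1 = 0.7 s`, peak-normalised kernel) to a sparse
nonnegative sudomotor driver `q`, `B l` is a cubic B-spline tonic curve with
knots every 10 s (ridge weight `gamma = 1e-2`), and `C d` is an offset plus
linear drift. The objective `½||y − Mq − Bl − Cd||² + alpha·1'q + ½gamma||l||²`
with `alpha = 8e-4` is a convex QP; the tonic/drift coefficients are
eliminated in closed form and the remaining nonnegative QP in `q` is solved
exactly by a dual active-set method (`quadprog`), with a relative ridge of
`1e-8` on the reduced Hessian for numerical definiteness. The three parts
always add back to the input exactly; on generator ground truth the
recovered phasic correlates with the true phasic at r > 0.99 with exact peak
timing. The decomposition accepts the high-passed (signed) series — the
spline tonic absorbs residual low-frequency content — so it can run directly
after preprocessing.

## Streaming scheme

`run_stream_simulation()` replays a recording through the causal
preprocessing chain and `stream_update()`: per 0.5-s hop, the trailing 55 s
(TVSymp/MTVSymp) and 25 s (dPhEDA) of 2 Hz samples are taken; windows
younger than nominal are completed by prepending the running mean of all
received samples; the last value is repeated for 5 s on the right to protect
the filters' trailing transients; the indices are computed over the padded
window; and a 2-s average is emitted.

Two defaults deserve justification, both settled by measuring streamed
output against the zero-phase batch reference on synthetic records:

* **Emission latency.** The emitted average is read 4 s
  (`emission_latency_s`) before the window end. A 0.08–0.24 Hz envelope has
  a coherence time of several seconds; at the very edge of a window its
  value is a causal extrapolation, and no filter choice repairs that (the
  measured ceiling was r ≈ 0.72 against batch at any alignment). A few
  seconds inside the window the envelope is well determined (r ≈ 0.94–0.95).
  The stream is therefore an estimate of the state ~5 s ago — the precise
  sense in which a windowed monitor is "near real-time". Setting the latency
  to 0 recovers the literal read-at-the-edge scheme.
* **Normalization.** Streaming TVSymp is normalized by the running RMS of
  the summed band components over everything received so far
  (`normalization = "recording"`), which converges to the batch
  per-recording normalization while remaining causal. Per-window unit
  variance (the `"window"` option) rescales quiet windows to unit variance,
  amplifying noise and destroying the correspondence with the batch series.

Causality is strict at the sample level: emitted values depend only on
samples received so far, verified by a truncation test.

### Batch pre-echo and where features should come from

The batch VFCDM is zero phase, so an evoked SCR's narrowband envelope is
smeared symmetrically ~6 s in *both* directions — including backwards in
time. A pre-stimulus "painless" window taken from batch indices therefore
sees a pre-echo of the response, which specifically weakens max-type
MTVSymp/TVSymp features (mean features and dPhEDA are much less affected).
The causal streamed indices cannot pre-echo, and on them a strong evoked
effect yields MTVSymp-max AUROC ≈ 1.0. `extract_segments()` accepts either
series; batch is the default for reproducibility, but max-feature
discrimination is best assessed on the streamed path.

## Segments, statistics, evaluation

`extract_segments()` takes the 5 s before each stimulus as the painless
segment and the 5 s after as the pain segment (half-open windows: the
stimulus sample belongs to the pain segment), yielding per event a balanced
pair of rows with six features: mean and max of each index. Events too
close to a boundary are skipped, not clipped, so every window has exactly
10 samples at 2 Hz.

`compare_segment_features()` reports per feature: Fisher's ratio
`|mean0 − mean1| / (var0 + var1)` (sample variances), AUROC by the
Mann–Whitney midrank identity with a subject-stratified bootstrap CI (2000
resamples), Kolmogorov–Smirnov normality p-values per class (informational),
and a subject-nested permutation rank test: the statistic is the mean over
subjects of the within-subject rank-sum z-score, the null is built by
permuting labels within each subject, and the two-sided p-value is
`(1 + #extreme)/(1 + n_perm)`. A linear mixed-effects branch for normally
distributed features is deliberately not implemented; the permutation test
is assumption-free and is applied throughout. Its type-I error at nominal
0.05 calibrates to ~0.03–0.05 over 200 null simulations.

`evaluate_protocol1()` is leave-one-subject-out: for each held-out subject,
hyperparameters are chosen by subject-wise 5-fold grid search on the
remaining subjects (subjects shuffled by seed, assigned round-robin; all
segments of a subject stay together; ties break toward the earlier grid
row), standardization statistics are fitted on training data only, and fold
metrics are averaged with a normal-approximation 95% CI.
`evaluate_cross_dataset()` trains on one dataset and tests on another
(disjoint subjects enforced) with a bootstrap CI over test segments.

Classifier backends: SVMs via `e1071` (linear / 3rd-order polynomial / RBF;
C in 1/10/100/1000, gamma in 1e-4/1e-3/0.1), decision tree via `rpart`
(split = gini or information, the latter being the entropy criterion),
random forest via `randomForest` (which supports only the Gini criterion;
both grid values map to the same fit), KNN via `class` (K in 3/5/7/9),
logistic regression via `glm` (the solver grid labels — newton-cg, lbfgs,
liblinear, sag, saga — all denote optimizers of the same convex objective,
fitted here by IRLS), and a compact MLP written in this package: 1–3 hidden
layers of 100 units, logistic/tanh/relu activations, L-BFGS / Adam /
minibatch SGD with momentum, 100-epoch cap, and for SGD the learning rate is
divided by 5 whenever two consecutive epochs fail to improve the training
loss (no separate validation split is carved out inside grid-search folds).
MLP grid points are scored by cross-entropy (minimized); all others by
accuracy (maximized).

## The synthetic generator

`generate_dataset()` emulates a stimulus-locked pain experiment: per
subject, a Gaussian random-walk tonic level (2 µS baseline, 0.01 µS/√s
drift, clipped at 0.05 µS), 10 stimuli at uniform random 30–60 s intervals,
one evoked SCR per stimulus (Bateman kernel, `tau0 = 2 s`, `tau1 = 0.7 s`,
latency 1.5 s — placing the response inside the 5-s pain segment — amplitude
Normal(0.5, 0.1) µS floored at 0), spontaneous SCRs as a 2/min Poisson
process with mean amplitude 0.15 µS (spontaneous responses are
physiologically smaller than strong evoked pain responses; the generator
exposes this as its own parameter), white measurement noise (0.02 µS), and
120 Hz timestamps with ±20% uniform jitter. Tonic + phasic + noise equals
the stored conductance exactly, so every downstream stage can be scored
against ground truth. Per-subject seeds derive deterministically from the
master seed.

What the generator does **not** emulate: motion artifacts, electrode
detachment or polarisation drift, physiologically detailed sudomotor-nerve
dynamics, temperature/humidity effects, or inter-subject differences in SCR
shape. Passing tests therefore demonstrate that the computational chain
recovers what it models — not that the classifier accuracies reported on
synthetic data transfer to human recordings.

## Problem sizes and numerical conventions

The test-suite and acceptance computations use 300-s single-subject records
for signal-level checks and 10 subjects × 10 stimuli (~540 s each) for the
end-to-end classification checks; the permutation-test calibration uses 200
simulated null datasets of 6 subjects × 10 observations at 199 permutations.
Tie-breaks and degenerate inputs are explicit everywhere: zero-variance
TVSymp input is an error in batch mode and a zero series in streaming mode
(the correct limit for a constant stream); grid-search ties take the earlier
row; metrics with empty denominators are `NA`, never 0; event times snap to
the nearest 2 Hz sample; all randomized routines take explicit seeds and
restore the caller's RNG state.

## Known limitations

* Max-type features from batch (zero-phase) indices inherit the pre-echo
  discussed above; use streamed indices when segment timing matters.
* The streamed dPhEDA correlates with its batch counterpart more weakly
  (r ≈ 0.8) than TVSymp does, because the convex decomposition on a 25-s
  window sees far less tonic context than the full-record fit.
* The ideal band filters maximise frequency selectivity at the cost of
  ~6 s temporal smearing; applications needing faster index response should
  widen `bandwidth` at a documented cost in selectivity.
* `cvxeda_decompose()` builds dense operators; records much longer than
  ~20 min at 2 Hz should be decomposed in chunks.
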