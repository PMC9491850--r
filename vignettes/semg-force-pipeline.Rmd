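---
title: "Methods: sEMG interaction-force prediction with KPCA, a deep residual shrinkage network, and Mean Impact Value ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sEMG interaction-force prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

semgforce estimates the force a limb exerts on a sensor from multi-channel
surface electromyography (sEMG), and then asks which muscle's signal the
prediction actually relies on. This vignette is the package's account of
the methods: the models, their assumptions, the tunable parameters and the
reasoning behind every numerical choice. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## The pipeline

A recording is a synchronized table: one column per muscle channel (here
biceps brachii BB, triceps brachii TB, brachialis BR, brachioradialis BRD)
plus a load-cell force trace, sampled at `fs` = 1000 Hz. The pipeline is

1. **Windowing** — 200-sample (200 ms) windows with 50% overlap; each
   window's target is its mean force. The defaults balance the
   electromechanical-delay timescale of sEMG (tens of ms) against having
   enough windows to train on; both are configurable.
2. **Per-window representation** — Gaussian-kernel KPCA scores (default),
   linear PCA scores, classical time-domain features (MAV, VAR, ZC, WA),
   or the raw samples.
3. **Regression** — a 1-D deep residual shrinkage network (DRSN) maps the
   per-window representation to force.
4. **Attribution** — Mean Impact Value (MIV) ranks the muscle channels by
   their influence on the predicted force.

## Synthetic recordings

No public recordings accompany the problem, so the package ships a seeded
generator (`synth_config()`, `generate_recording()`) whose output has the
statistical structure the rest of the pipeline assumes, with planted
ground truth for validating the attribution step.

**Activation.** Tasks alternate 2 s rest and 2 s effort bouts. Effort
envelopes use raised-cosine ramps (0.25 s) and a shared random bout
amplitude in [0.7, 1], so envelopes are smooth (band-limited well below
5 Hz) and exactly zero at rest. Each task plants one dominant muscle
(flexion→BB, extension→TB, pronation→BRD, supination→BR) with weight 1;
the remaining channels co-activate at 0.35/0.20/0.10 of the dominant —
co-contraction levels typical of isometric elbow tasks.

**Identifiability.** Two muscle-specific perturbations are applied to the
shared envelope: a per-bout amplitude jitter (uniform ±30%) and a slow
(< 1 Hz) within-bout drive wander (±15%), emulating independent
motor-unit-pool fluctuations. These are not cosmetic: if every channel
carried the *same* envelope up to scale, the channels would be collinear
and no importance method — not even an exact linear-regression oracle —
could attribute force among them. The planted truth must be identifiable
for "ground truth" to mean anything. Jitter and wander streams are
assigned to channels by weight rank, which keeps the force trace exactly
invariant under a joint permutation of channels and weights (a property
the test suite checks).

**Carrier and artifacts.** Each channel is an envelope-modulated
stochastic carrier: Gaussian white noise band-passed to 20–150 Hz
(4th-order Butterworth, zero-phase), with 30% of carrier variance shared
across channels (volume-conduction-like correlation). On top of this sit
a 50 Hz powerline sinusoid and a narrowband ~110 Hz ECG-like artifact
(amplitude-modulated below 2 Hz so it is narrowband but not a pure tone),
at relative amplitudes 0.5 and 0.4 of each channel's carrier RMS —
"obvious contamination" levels at which both peaks stand clearly above
the local spectral background. White noise is added at an exactly
realized SNR (20 dB default).

**Force.** `force = force_scale * sum_c w_c g(env_c) + noise` with
`g(u) = tanh(s*u)/tanh(s)`, `s = 1.5`: monotone in activation and gently
saturating, as muscle force-activation curves are. `force_scale` = 10 N,
load-cell noise SD 0.05 N.

What the generator does **not** emulate: motion-artifact transients at
state changes, electrode lift-off, fatigue-induced spectral compression,
morphological ECG waveforms, or inter-subject variability. Passing tests
on this generator therefore show that the algorithms are implemented
correctly and behave as designed under controlled conditions — not that
they meet any particular accuracy on human recordings.

## KPCA and component selection

For windows `x_1..x_n`, the Gaussian kernel `K(x,y) = exp(-gamma ||x-y||^2)`
defines an implicit feature map. `kpca_fit()` double-centers the kernel
matrix in feature space (`K~ = K - 1K - K1 + 1K1`), eigendecomposes it,
and scales each eigenvector `alpha` by `1/sqrt(lambda)` so the
feature-space components have unit norm; projections of new samples apply
the stored centering statistics to the test kernel vector. Double
centering is the default because raw signal windows are nowhere near
centered in feature space; without it the leading "component" mostly
encodes the feature-space mean and projections are biased. `center =
FALSE` is available for inputs that are already centered.

Numerical choices: eigenvalues are clipped at zero (symmetric
eigendecompositions can return tiny negative values); components with
`lambda <= 1e-12 * lambda_max` are dropped; ties are broken by the stable
eigen ordering; each component's sign is fixed so its largest-magnitude
coefficient is positive, making projections reproducible. An
all-identical-samples input has a rank-0 centered kernel matrix and is
rejected with an explicit error.

`gamma` defaults to the median heuristic, `1/median(pairwise squared
distances)` — the standard data-driven bandwidth when none is prescribed.
The component count `P` is the smallest number whose cumulative
contribution rate `sum_{i<=P} lambda_i / sum_i lambda_i` reaches
`xi_threshold` (default 0.85).

**A limitation worth understanding.** On stationary band-limited
stochastic windows — which is what raw sEMG amplitude windows are — the
centered kernel spectrum is intrinsically *flat*: a 200 ms window of a
20–150 Hz process has on the order of `2 * bandwidth * T ≈ 50` effective
dimensions, and no 3 components can summarize it. On the default
synthetic recording the first three components carry roughly a quarter of
the total contribution, and `P` at `xi = 0.85` runs to well over a
hundred components (the acceptance script computes this number afresh on
every run). A three-component summary is only achievable when windows
concentrate near a low-dimensional manifold — for example when
representations are amplitude-dominated (time-domain features) or when a
few coherent components dominate the signal. Pipelines that need a small
fixed input width should set `n_components` explicitly.

## Time-domain features

The classical per-window EMG features, with their standard definitions:
mean absolute value `MAV = mean(|x|)`; sample variance `VAR` (denominator
L−1); zero crossings `ZC` = sign changes whose amplitude step exceeds a
threshold (default 0); Willison amplitude `WA` = consecutive-sample steps
exceeding a threshold (default 5% of the window RMS, making the count
scale-free). Feature tables are named `<feature>_<channel>`.

## The deep residual shrinkage network

The regression network is a 1-D convolutional residual network whose
residual branches *shrink* their features before rejoining the shortcut:

* **Soft thresholding** `y = sign(x) * max(|x| - tau, 0)` zeroes features
  in `[-tau, tau]` and pulls the rest toward zero — a denoising operator
  whose derivative is exactly 1 on the active set and 0 inside the dead
  zone, so backpropagated gradients are never amplified.
* **Learned thresholds.** Each residual shrinkage unit pools the absolute
  residual features per channel (`m_c = mean|r_c|`, an SE-style squeeze),
  passes the pooled vector through a small dense→batch-norm→ReLU→dense
  subnetwork, and squashes with a sigmoid: `tau_c = alpha_c * m_c`,
  `alpha_c ∈ (0,1)`. By construction every threshold is positive, never
  exceeds the channel's mean absolute activation, and adapts per sample —
  the three constraints a sensible shrinkage threshold must satisfy.
  `channel_wise` mode (default) learns one `alpha` per channel;
  `channel_shared` emits a single `alpha` for all channels.
* **Unit layout** conv→BN→ReLU→conv→BN→shrink, added to an identity
  shortcut (a 1×1 convolution `W_s` reshapes the shortcut when channels
  or stride change). With the residual branch zeroed the unit is an
  identity map — the property that lets depth never hurt representation.

Defaults: a kernel-3 stem convolution into 3 units with 8→16→32 channels
(stride 2 at each widening), global average pooling, and a dense scalar
head. Inputs are z-scored per channel and targets z-scored using training
statistics stored in the model, so predictions come back in Newtons.

**Training** is full backpropagation (implemented in R and verified
against central finite differences in the test suite) with Adam
(lr 1e-3, batch 32), mean-squared-error loss, and early stopping on
validation MSE (patience 10) that restores the best weights seen —
including the untrained initial model, so the final validation MSE can
never exceed the starting point. All randomness (initialization, batch
shuffling) derives from the config seed; two runs with the same seed
produce identical loss histories, and a saved checkpoint reproduces
predictions bit-identically. A non-finite loss aborts with the failing
epoch named rather than silently continuing.

A small decoupled weight decay (1e-4) is applied by default. The reason
is attribution, not accuracy: with correlated input channels, an
unregularized overparameterized network may place its weights anywhere in
the collinear subspace and fit equally well; decay biases training toward
minimum-norm solutions, which stabilizes sensitivity-based importance.
Set `weight_decay = 0` for plain MSE training.

`shrinkage = FALSE` disables soft thresholding (`tau ≡ 0`), giving an
otherwise-identical plain residual network — the ablation that isolates
what shrinkage contributes under noise. The test suite runs this ablation
at 5 dB SNR across five seeds and checks the shrinkage network's test MSE
is at least as good in the majority of them.

## Mean Impact Value

After training, each input variable is scaled by `(1 ± p)` (default
`p = 0.1`); the per-sample difference between the two perturbed
predictions is the impact value, its mean the MIV, and `|MIV|/sum|MIV|`
the normalized contribution. Variables are ranked by `|MIV|` and selected
as the smallest ranking prefix whose cumulative contribution reaches the
cutoff (default 0.90). For a linear model this reduces to
`MIV_j = 2 p beta_j mean(x_j)` — the closed form the tests check to
1e-10.

Two protocol choices matter:

* **Attribution in the muscle domain.** When the network consumes KPCA
  scores or features, perturbing an abstract component says nothing about
  muscles. `miv_muscles()` therefore perturbs each *raw channel* of the
  recording before windowing and reduction, so impacts attach to muscles
  regardless of representation. Held-out windows are used by default, so
  the ranking reflects generalizable sensitivity rather than training-set
  idiosyncrasy.
* **Ensemble averaging.** A single network's sensitivity is a
  high-variance estimator when channels are correlated: perturbing one
  channel probes the model off the data manifold, exactly where a single
  fit is unconstrained. The experiment-level protocol
  (`miv_muscles_ensemble()`, `miv_ensemble = 5` in `run_experiment()`)
  averages per-sample impact values over five independently seeded fits
  before ranking. The acceptance suite validates the protocol by checking
  that the ensemble ranking recovers the planted dominant muscle in all
  four tasks of the default suite.

## Evaluation and spectral checks

`metrics_suite()` reports MSE, its square root (RMS error, N), mean
absolute error (MAVE, N), and the Pearson correlation between measured
and predicted force in percent; a constant measured trace makes the
correlation undefined and is reported as `NA` with a warning.
`add_noise_snr()` scales white Gaussian noise so the realized
signal-to-noise ratio matches the request exactly.

`power_spectrum()` is an averaged modified periodogram: 1 s Hann-tapered
segments, 50% overlap, one-sided density normalized so the integrated
spectrum matches the signal variance (checked to 5% in the tests).
`detect_interference()` flags a narrowband peak when the local maximum
within ±1 Hz of the target exceeds the median density of the surrounding
±25 Hz band by a factor (default 3) — median, not mean, so the peak
itself cannot drag the reference up.

## Experiment harness

`run_experiment()` splits windows chronologically 60/20/20 with a
one-window-length guard gap after each boundary, so overlapping windows
never leak samples between training and evaluation — the reason a random
shuffle split would be wrong for overlapping windows. Every artifact
(flat key–value results file, MIV table, checkpoint, test predictions) is
a deterministic function of config + seed; reruns reproduce the files
byte-for-byte. Extra acquisition noise can be injected into the raw
channels at a configured SNR before processing, modeling degraded
recording conditions ahead of the pipeline rather than after reduction.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in a few minutes of one CPU: 60 s recordings
(≈600 windows per channel) for the KPCA spectrum, the four-task MIV
recovery (5-fit ensembles of a 1-unit network on MAV features, 40
epochs), and the 5-seed shrinkage ablation (3 units, 50 epochs); shorter
8–20 s recordings elsewhere. All sizes are ordinary function arguments
and scale up unchanged.

## Known limitations

* The synthetic generator validates mechanisms, not clinical accuracy;
  see the generator section for what it does not model.
* The three-component KPCA summary is unattainable on stochastic
  band-limited windows (see the KPCA section); treat `P` as data-driven
  output, not a guarantee.
* MIV attributes sensitivity, not causality; under strong co-activation
  it requires the ensemble protocol, and even then ranks only relative
  influence.
* Training is plain R; it is comfortable at the shipped scales but not
  engineered for large architectures or long sequences.
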