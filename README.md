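# semgforce

Predicting limb–sensor interaction force from multi-channel surface
electromyography (sEMG), and ranking how much each muscle contributes to
the prediction.

sEMG amplitude rises with muscle activation and precedes movement by tens
of milliseconds, which makes it a natural input for force estimation in
wearable-robot control. But a practical controller faces two questions:
how to turn a noisy, high-dimensional, nonlinear signal into an accurate
force estimate, and whether a single well-chosen muscle beats a
combination of muscles for a given contraction task. `semgforce`
implements a complete pipeline for both:

* **KPCA reduction** — sliding windows of each channel are reduced with
  Gaussian-kernel kernel principal component analysis: eigendecomposition
  of the double-centered kernel matrix `K(x,y) = exp(-γ‖x−y‖²)`, scores
  `h_k(x) = Σ_i α_i^k K̃(x_i, x)`, and component count chosen as the
  smallest `P` with cumulative contribution `Σ_{i≤P} λ_i / Σ_i λ_i ≥ ξ`.
  Linear PCA and classical time-domain features (MAV, VAR, ZC, WA) are
  provided as baselines.
* **DRSN regression** — a 1-D deep residual shrinkage network: residual
  units whose branches are soft-thresholded, `y = sign(x)·max(|x|−τ, 0)`,
  with `τ_c = α_c · mean|x_c|` learned per sample by a
  squeeze-and-excitation attention subnetwork (`α_c = sigmoid(·) ∈ (0,1)`,
  so thresholds are positive but bounded). Forward and backward passes
  are implemented from scratch in R and trained with Adam on MSE.
* **MIV attribution** — Mean Impact Value: scale each input by `(1 ± p)`
  (`p = 0.1`), average the prediction difference, rank channels by
  `|MIV|`, and select the smallest prefix of the ranking whose cumulative
  normalized contribution reaches 90%. Channel perturbations are applied
  to the *raw* recording before windowing, so contributions attach to
  muscles even when the network consumes KPCA scores.
* **Synthetic bench** — a seeded generator of 4-channel recordings
  (band-limited stochastic carriers, activation envelopes with planted
  per-task dominant muscles, 50 Hz powerline and ~110 Hz ECG-like
  interference, exact-SNR noise) with ground truth for validating the
  attribution step, plus spectral analysis and SNR-controlled noise
  injection for robustness experiments.

See `vignettes/semg-force-pipeline.Rmd` for the full methods account.

## Worked example

```r
library(semgforce)

# 60 s flexion recording: 4 muscle channels + force, planted dominant = BB
rec <- generate_recording(synth_config(duration = 60, task = "flexion", seed = 42))

pipe <- fit_force_pipeline(
  rec, reduction = "features",
  drsn = drsn_config(n_units = 1, channels = 8, epochs = 40, seed = 42)
)
pipe$metrics
#> # A tibble: 1 × 4
#>     mse   rms  mave   rho
#>   <dbl> <dbl> <dbl> <dbl>
#> 1  4.57  2.14  1.57  92.6

tidy(miv_muscles(pipe, rec))
#> # A tibble: 4 × 5
#>   variable     miv abs_normalized  rank selected
#>   <chr>      <dbl>          <dbl> <int> <lgl>
#> 1 BB        1.51           0.830      1 TRUE
#> 2 TB       -0.228          0.126      2 TRUE
#> 3 BR       -0.0519         0.0287     3 FALSE
#> 4 BRD       0.0272         0.0150     4 FALSE

detect_interference(power_spectrum(rec$BB, 1000), 50)
#> # A tibble: 1 × 4
#>   detected peak_hz peak_power ratio
#>   <lgl>      <dbl>      <dbl> <dbl>
#> 1 TRUE          50     0.0329  11.6
```

The metrics row says the held-out force prediction has a 2.14 N RMS error
and 92.6% correlation with the measured force. The MIV table attributes
83% of the model's sensitivity to the biceps channel — the muscle planted
as dominant for flexion — and the cumulative-90% rule selects BB + TB.
The spectral check finds the injected 50 Hz powerline peak at 11.6× the
local background. For stable rankings on correlated channels, use the
ensemble protocol (`miv_muscles_ensemble()` or `run_experiment()`'s
default `miv_ensemble = 5`); single fits can scatter attribution.

`autoplot()` methods exist for recordings, spectra, KPCA models, MIV
reports, and fitted pipelines; `tidy()`/`glance()` return tibbles.

A command-line front end ships at `inst/cli/semgforce`
(`simulate`, `run`, `compare-muscles`, `miv`, `spectrum` subcommands).

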