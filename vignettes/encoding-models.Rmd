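---
title: "Recurrent and ridge response models for continuous-design fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrent and ridge response models for continuous-design fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rebold)
```

## The model

An encoding model predicts a voxel's BOLD response from stimulus features.
`rebold` is about the *response model* — the map from a feature sequence
φ(x⁰), …, φ(xᵗ) ∈ ℝᵖ to responses yᵗ ∈ ℝᵐ sampled once per TR (1 s by
default). Continuous designs have no discrete trials: every sample depends on
the stimulus history through neurovascular coupling (the hemodynamic response
function, peaking ~5 s after neural activity with a later undershoot) and
possibly slower cognitive factors.

Two families are implemented.

**Feedforward ridge family.** The response is a linear readout of a design
matrix that hard-codes the hemodynamic delay: convolution with the canonical
double-gamma HRF (`R-C`), adding its temporal and dispersion derivatives
(`R-CTD`, a T × 3p design that absorbs small shifts of latency and width), or
a finite-impulse-response basis of features lagged 3–6 s (`R-F`, T × 4p,
deliberately without a lag-0 term). Coefficients are estimated per voxel by
minimizing the L²-penalized least squares loss analytically; one SVD of the
design is shared across voxels and the whole penalty grid.

**Recurrent family.** Two stacked recurrent layers (LSTM or GRU cells of
width 10, 50 or 100) process the feature sequence; all voxels of a group
share the recurrent trunk and differ only in a linear readout of the
second-layer hidden states. Gates are multiplicative sigmoids of the previous
hidden state and current input. One deliberate quirk: the LSTM *candidate*
cell update uses a sigmoid activation by default rather than the conventional
tanh, matching the formulation this package follows; `candidate_tanh = TRUE`
switches to the conventional cell. The GRU candidate is always tanh. Because
no automatic-differentiation framework is involved, the forward pass,
backpropagation through time and the Adam optimizer are authored here and are
checked against finite-difference gradients in the test suite.

## Data model and preprocessing

Data are organized as paired feature/response blocks with roles train /
validation / test. Sample *t* covers `[t, t+1)` seconds, block-locally;
nothing — convolution, recurrent state, cross-correlation — crosses block
boundaries, and recurrent state resets to zero at each block start. The
preprocessing conventions: the first 6 s of every block are discarded
(scanner/HRF settling), responses are z-scored per block and voxel, and the
last 45 s of each training block form the validation set. Detrending is
assumed to have happened upstream; the synthetic generator produces
drift-free data, and the package does not re-implement motion or drift
correction.

Validation blocks are *tails* of training blocks, so their responses carry
the hemodynamic history of the whole block. Scoring them cold (zero recurrent
state, zero-padded designs) would systematically understate validation
performance and distort both ridge penalty selection and RNN early stopping.
All validation evaluations therefore run the model over the parent training
block concatenated with its tail and score only the tail rows. Test blocks
are independent acquisitions and are scored cold, which matches how they are
generated.

Serialization uses a plain-text container: a JSON manifest plus one TSV per
matrix, doubles printed with 17 significant digits so that save → load round
trips are bit-exact. z-scoring is exposed per block (the default); whether a
session-level variant is preferable is left to the user via the flag.

## Parameters that matter

* **Canonical HRF** (`canonical_hrf`): response delay 6 s, undershoot delay
  16 s, unit dispersions, response:undershoot ratio 6, 32 s support, sampled
  at the TR and peak-normalized to 1 (regression weights absorb scale).
  Derivative kernels are finite differences (onset step 1 s, dispersion step
  0.01) scaled to unit norm.
* **Ridge penalty grid** (`select_lambda`): 20 log-spaced values in
  [10⁻³, 10⁶]; the per-voxel winner maximizes validation correlation, ties
  resolved toward the stronger penalty (prefer the simpler model when the
  data cannot distinguish).
* **Recurrent training** (`rnn_hyperparams`): truncation window 60 samples
  (about two HRF supports — long enough that the gradient sees the whole
  hemodynamic dependency), learning rate 10⁻³, dropout 0.5 on both hidden
  layers' outputs, at most 500 epochs, early stopping with the
  best-validation snapshot returned, and a reduce-on-plateau schedule
  (halve the rate, resume from the best snapshot, after 25 stale epochs).
  Weights start uniform ±1/√fan-in with the LSTM forget-gate bias at +1.
  Whether dropout should instead touch inputs or recurrent connections is
  genuinely open; outputs-only is the choice here. At the down-scaled sizes
  used throughout the vignette and tests, a gentler dropout (0.2) and a
  faster rate (3·10⁻³) are used — a 10-unit trunk on minutes of data is far
  below the regime the 0.5 default is meant for.
* **HRF probing** (`impulse_response`): all-ones impulse amplitude exactly as
  defined; since a trained RNN is nonlinear and amplitude-sensitive, the
  amplitude is exposed (`amplitude`) for sensitivity analyses. Horizon and
  baseline pre-period both default to 32 s. Ties in the delay extraction go
  to the earliest lag, and an undershoot is only reported when the post-peak
  minimum actually dips below baseline; otherwise the voxel is flagged
  rather than assigned a spurious delay.

## Statistical evaluation

Performance is the cross-validated Pearson correlation per voxel and the
*median* over a voxel group — medians everywhere, never means, so a handful
of exceptional voxels cannot carry a family. The noise ceiling is estimated
by Monte-Carlo simulation from the repeated test presentations: noise
variance is the mean squared SEM of the repeat-averaged response over time
(the variance of the SEMs is available as an alternative reading), signal
variance is the variance of the mean response minus the noise variance
floored at zero, and the ceiling is the median simulated correlation between
a Gaussian signal and itself plus Gaussian noise. Group medians divided by
the group's median ceiling give the ceiling-corrected performance (a
multiplicative correction; the precise adjustment is a documented choice).

Chance level uses permutation tests: a single time-index permutation shared
by all voxels, applied separately within the concatenated training and test
sets, with the model *retrained* on every permutation; the p-value is the
fraction of permutations whose group median meets or exceeds the observed
one, reported as `< 1/n_perm` when no permutation does, Bonferroni-corrected
over groups. Shuffling individual time points destroys autocorrelation as
well as the stimulus link, so these p-values are anticonservative on strongly
autocorrelated data; pair them with the noise-ceiling analysis rather than
over-reading them. Family comparisons bootstrap voxels with replacement
(difference of group medians, percentile CI at the Bonferroni-adjusted
level), and the threshold analysis partitions voxels by |r_a − r_b| > 0.1 to
show where a family's advantage lives.

## The synthetic generator

`generate_dataset` emulates the continuous-design layout: twelve 600 s
training blocks and nine 60 s test blocks presented 10 times, with a `scale`
parameter shrinking all durations proportionally (discard and validation
tails included, floored at one and two samples). Features are stationary
AR(1) sequences with time constant τ (τ ≈ 0 mimics fast "structural"
features, large τ slow "semantic" ones), z-scored per block. Each voxel gets
sparse half-normal feature weights, a gamma-difference HRF with response
delay drawn from 4–8 s (undershoot 8–12 s later), and white Gaussian noise
calibrated to a target SNR; test repeats are independent noise realizations
around the shared noiseless signal. The stored ground-truth delays are the
argmax/argmin of the *sampled* kernels, so recovery is judged against what
was actually generated, not against a nominal parameter.

Two generator choices deserve their rationale. Weights are non-negative
because impulse-based HRF estimation reads the response to an all-ones
feature frame: a voxel whose net drive is negative returns a sign-inverted
impulse response even under a perfect model, so recoverability requires
excitatorily driven voxels — a reasonable stance for energy-like features.
The default feature dimension is 8, comparable to the narrowest recurrent
trunk (10 units), so that desk-scale HRF-recovery experiments measure
hemodynamic learning rather than pure feature-compression capacity.

An optional pre-convolution nonlinearity (tanh saturation or half-wave
rectification) produces data that violate every linear design while
remaining learnable by the recurrent family — experiments using it state
that violation explicitly. What the generator does *not* emulate: motion,
drift, physiological noise, spatial correlation between voxels, and the
nonstationarity of real movie features. Passing tests on this generator
demonstrate correctness of the machinery and qualitative transfer of the
modeling claims, not performance on real recordings.

## Validation experiments and their problem sizes

The test suite and `scripts/acceptance.R` run at deliberately down-scaled
sizes chosen as the smallest that leave the phenomena measurable:

* *HRF recovery*: scale 0.25, 20 voxels, delays 4–8 s, SNR 2, one fixed
  seed, G-10. A majority of significant voxels recover their delay within
  ±1 s and the median estimated-vs-true curve correlation exceeds 0.8.
* *Family comparison*: scale 0.25, 60 voxels. With voxel-variable delays
  (3–10 s), white-noise features and rectified drive — conditions designed
  to break the shared-canonical-kernel assumption — G-10 beats R-C with a
  bootstrap CI excluding zero. On data generated exactly by the
  canonical-HRF linear model the comparison reverses, as it should: the
  correctly specified ridge model matches or beats the small GRU.
* *Calibration*: 100 null replicates × 50 permutations (uniform p-values),
  200 bootstrap replications of a known 0.2 median gap (coverage ≥ 93% at
  95% nominal), and the noise ceiling against its closed form
  σ_s/√(σ_s² + σ_n²) averaged over 12 voxels at T = 300 (a single voxel's
  moment estimates fluctuate by more than the Monte-Carlo error).
* *Lag analysis*: trained G-10 models probed with long stationary feature
  blocks; hidden units of the model trained on slow features (τ = 6 s) have
  more negative mean optimal lags than those of the fast-feature model
  (τ = 0.5 s), reproducing the expected direction of the feature-timescale
  effect. Short test blocks are unsuitable here — cross-correlations at lags
  near the block length are dominated by boundary artifacts — hence the
  long-block probe.

## Known limitations

* Pure-R training: fine for the tested sizes (seconds to ~a minute per
  model); hundreds of units over hours of data would want compiled code.
* The r = 0 convention for constant predictions, earliest-lag tie-breaks,
  and zero-floored signal variances are all flagged in the returned objects
  rather than silently absorbed.
* The permutation scheme's autocorrelation caveat above.
* Impulse probing of a *nonlinear* model characterizes its response to one
  particular stimulus; amplitude sensitivity is real, and the neuronal and
  hemodynamic contributions to the estimated kernel cannot be separated
  within this framework.
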