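---
title: "Interpretable full-epoch decoding: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable full-epoch decoding: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Multivariate pattern analysis of M/EEG usually decodes stimuli with linear
classifiers trained on short sliding windows, which yields an interpretable
accuracy time course but limited decoding performance. Full-epoch multiclass
decoders perform better, especially with many classes, but are harder to
interpret. `megdecode` implements a workflow that keeps both properties:

1. a **deep linear network** whose first layer is a learnable
   `channels x components` spatial projection (supervised dimensionality
   reduction), trained end to end on the full epoch;
2. **shrinkage LDA decoders** trained on features projected either through
   the network-learned matrix (LDA-NN) or through unsupervised,
   variance-ranked channel PCA (LDA-PCA);
3. **sliding-window and per-sensor LDA baselines**, the classical
   comparators;
4. a six-variant **permutation feature importance (PFI)** suite that reads
   temporal, spatial, spatiotemporal, spectral, spatio-spectral and
   temporo-spectral discriminative structure out of a single trained
   full-epoch model.

Everything is exercised on a synthetic MEG-like generator with planted
ground truth, so every attribution method has a known recovery target.

# Models

## The linear network

A trial is a `n_times x n_channels` matrix $X$. The network computes

$$\mathrm{logits} = \mathrm{vec}(X W_{dr})\, A_1 A_2 A_3 + \text{biases},$$

with $W_{dr} \in \mathbb{R}^{\text{channels} \times k}$ shared across
timepoints and `vec` the row-major (time-major) flattening. There is no
nonlinearity: in evaluation mode the whole network is one affine map
(`collapse_nn()` materialises it, and a test asserts equality to 1e-5).
Depth still matters during optimisation: gradient-descent dynamics of deep
linear networks differ from the collapsed parametrisation, and inverted
dropout (rate 0.7 before each of the three affine layers) regularises what
$W_{dr}$ learns. Training uses softmax cross-entropy and Adam
(learning rate 1e-3, mini-batches of 64; both are package defaults the
data size can override) for a fixed number of passes with no early
stopping; validation trials are only ever used for reporting.

Hidden sizes follow a geometric-spacing rule between the flattened input
size and the class count. For the 1440-feature, 8-class synthetic
benchmark this gives 256 and 48; the package defaults (1000, 300) suit
inputs of a few thousand features and ~100 classes.

## LDA with shrinkage

All classifiers downstream of a projection are multiclass LDA with a
shared covariance shrunk toward a scaled identity. `shrinkage = "auto"`
uses the Ledoit–Wolf analytic intensity computed from the class-centred
training features; this keeps the estimator well-posed when the flattened
feature dimension (e.g. `90 x 16 = 1440`) exceeds the trial count. Ties in
the arg-max decision rule break toward the lowest class index.

## Whitening

`fit_whitener()` performs PCA whitening of the pooled training-timepoint
channel covariance, retaining all components, with channel means removed
(a design choice; the procedure is standard PCA). It is estimated on
training trials only and applied unchanged to validation trials.
Rank-deficient covariance gets a ridge of `1e-12 * trace / n` with a
warning. Whitening lives inside the decoder pipeline, so permutation
importance always operates in original sensor space.

One deliberate exception: the adversarial supervised-vs-unsupervised
comparison (below) runs unwhitened. In-sample whitening drives the pooled
channel covariance to the identity exactly, which makes the eigenvalue
ranking that channel PCA truncates by degenerate — the comparison would
then measure an arbitrary rotation rather than the variance-ranking
failure mode it is designed to expose.

## Sliding windows

Windows are half-open sample ranges `[start, start + length)` advancing by
`step`, 0-based. The window count is `floor((n_times - length) / step)`:
the final placement flush with the epoch end is dropped, so 100 samples
with 10-sample windows at step 1 give 90 windows. A window is reported at
its centre time `start + length/2`, in seconds relative to stimulus
onset. The projection used by windowed LDA is fitted once on full-epoch
training data and shared across windows; each window's classifier is
otherwise independent (a test permutes data outside a window and asserts
the window's accuracy is unchanged).

# Permutation feature importance

All six variants disrupt a feature block of the *validation* trials and
report `baseline accuracy - disrupted accuracy`, with the per-repetition
losses retained (default 10 repetitions) so percentile confidence
intervals can be formed. One permutation is drawn per (block, repetition)
and applied to all evaluated trials: repetitions are then interpretable as
plan-level samples. A per-trial redraw would be equally defensible; the
shared draw is the default. All disruption is done on copies — a test
asserts the input array is bit-identical afterwards — and any model whose
`predict()` maps a `[trials, channels, times]` array to labels can be
attributed, not just the package's own decoders.

* **Temporal**: one random channel reordering applied at every timepoint
  of a 100 ms window (per-timepoint independent permutations available
  behind a flag).
* **Spatial**: per sensor site (2 gradiometers + 1 magnetometer), each
  channel's timepoint order permuted independently.
* **Spatiotemporal**: a site neighbourhood (site + 3 nearest, 12
  channels) x 100 ms block, flattened and shuffled jointly.
* **Spectral**: full-epoch DFT per channel (DFT length = epoch length, no
  padding, so 0.9 s at 100 Hz gives 1.11 Hz resolution); within a
  frequency band the coefficients are permuted across channels, with
  conjugate-symmetric bins moved consistently so the inverse transform is
  real to machine precision. Default bands are single DFT bins; arbitrary
  band edges are configurable and treated half-open `[lo, hi)` so
  adjacent bands never share a bin.
* **Spatio-spectral**: the spectral permutation restricted to one site
  neighbourhood at a time.
* **Temporo-spectral**: per-channel STFT with a 100 ms Hamming window and
  hop 1 ("maximal overlap"); a (band, window) block is permuted across
  channels in the window and its two immediate neighbours (clamped at the
  epoch edges), which smooths the temporal profile; the epoch is then
  rebuilt by weighted overlap-add. With the analysis window used as
  synthesis window and normalisation by the summed squared window, the
  inverse is exact for any positive window at hop 1 (asserted to 1e-8).
  With 10-sample windows the band centres are 0, 10, ..., 50 Hz and the
  0 Hz band carries only the true within-window mean.

Disrupting *any* high-power content costs accuracy even when it carries no
class information, because permuted trials are off the data manifold the
decoder was trained on. In `1/f` data this inflates low-frequency spectral
importance — the same effect visible in real-data spectral attributions —
which is why the spectral recovery checks use a generator whose
discriminative oscillation is genuinely narrowband.

# The synthetic generator

`generate_epochs()` builds each trial as

* band-limited (0.1–25 Hz) `1/f` background: independent unit-variance
  sources, one per channel, mixed by a seeded random orthonormal matrix so
  the channel covariance is non-trivial for the whitening step;
* white sensor noise (sd 0.3);
* the trial's class response: Hann-windowed sinusoidal bursts
  (`planted_pattern()`) loaded on the channels of chosen sites;
* optionally, high-variance non-discriminative spatial components drawn
  orthogonal to the discriminative subspace (`adversarial_variance`,
  `n_adversarial`).

Three calibration choices define the scale. First, loading rows are
normalised to unit RMS per channel, so `snr` is the per-channel response
amplitude in units of the background deviation — the number a
practitioner would read off an evoked plot. Second, `class_separation`
(default 0.3) splits each response into a shared stimulus-generic
profile plus a class-specific modulation, emulating the realistic regime
where most of the evoked deflection is common to all stimuli; 1 would
make responses fully class-specific. The class-specific energy is
equalised across a pattern's sites so that spatial attribution reflects
the planted amplitudes rather than draw luck. Third, `field_spread`
(default 0.45 in layout-distance units) leaks every response across
sites with Gaussian distance decay, emulating the smooth sensor-space
footprint of a magnetic source; without it, sensor maps have no spatial
gradients to recover. The defaults were fixed so that the reference
condition sits clearly above chance but below ceiling (full-epoch
LDA-NN around 0.95–1.0), where attribution contrasts are informative;
they are study conditions, not tuning knobs.

`benchmark_config()` pins four named conditions used throughout the tests:

* **standard** — 8 classes, 30 trials/class (the repetition count of
  the larger visual datasets this emulates), 10 sites (30 channels),
  0.9 s at 100 Hz, snr 5, and an evoked cascade: a dominant
  100–200 ms / 10 Hz burst on sites 2–3, a sustained weaker 10 Hz
  component (175–475 ms, sites 3–4, amplitude 0.4), a slow 4 Hz component
  (400–700 ms, sites 1–2, 0.25) and a weak late 10 Hz component
  (500–850 ms, sites 5–6, 0.2). The cascade gives the smooth temporal and
  spatial gradients seen in real accuracy profiles while keeping the
  dominant component unambiguous for arg-max recovery checks.
* **chance** — the same with `snr = 0`.
* **adversarial** — the dominant burst plus 20 orthogonal
  non-discriminative components of variance 16, so variance-ranked
  truncation to 16 components discards the signal subspace almost
  entirely.
* **two_window** — two bursts in disjoint windows with *complementary*
  loadings: each burst separates only one half of the classes (the other
  half shares one profile). No single 100 ms window carries full class
  information, but the full epoch does — the mechanism by which
  full-epoch decoding beats the best sliding window, isolated from
  max-statistic luck.

What the generator does **not** emulate: forward-model (leadfield)
physics — gradiometers and magnetometers differ only by a type tag;
artifacts (blinks, cardiac); trial-to-trial latency jitter;
subject-to-subject variability. Tests passing on this generator show the
estimators recover structure they are pointed at under realistic noise,
not that any particular real dataset will behave identically.

# Statistics

Decoder comparisons across replicates use Wilcoxon signed-rank tests with
each simulated dataset (distinct seed) playing the role of one subject;
zero differences are discarded (Wilcoxon's convention), the exact
distribution is used for n <= 25 without ties, otherwise the normal
approximation with tie correction. Multiple comparisons are Bonferroni
corrected (`min(1, p * m)`). Chance bands are exact binomial quantiles
around `1/n_classes`; when a whole family of accuracies is asserted to be
at chance jointly (e.g. all 80 windows of a time course), the band level
is Bonferroni-adjusted to keep familywise coverage — per-comparison 95%
bands would be expected to fail somewhere in any 80-window family by
construction.

# Problem sizes and determinism

The test suite trains networks of 16 components and hidden sizes 256/48
for 300 epochs on 128–192-trial training sets — past the point where
training accuracy plateaus on these data — and uses 15 seeded replicates
for the method-ordering comparisons, 6 for the two-window comparison.
Importance maps and their comparators are averaged across 5 seeded
replicates (3 for the costlier time-frequency variant) before peaks and
rank correlations are taken: single-replicate maps over 10 sites carry
substantial sampling noise in their weakly-informative entries, and the
map-level claims are about the averaged profiles, exactly as the
corresponding across-subject map figures are. Every
random draw flows through explicitly seeded private RNG streams
(generator, splits, initialisation, dropout, permutation plans), so
identical configurations are bit-reproducible and never disturb the
caller's RNG state.

# Known limitations

* The NN's own validation accuracy trails LDA-on-NN-features by a few
  points at these sample sizes; with hundreds of trials per class the gap
  closes. This is the familiar small-sample weakness of end-to-end
  networks relative to a well-regularised closed-form classifier on the
  same features.
* PFI attributes what the *model* uses, not all information present:
  a block can carry class information the decoder ignores (redundancy)
  and will then show little loss.
* Spectral attribution of short transients is intrinsically broad: a
  100 ms burst has ~20 Hz of spectral support regardless of its carrier.
* The epoch container is a plain-text bundle (JSON + CSV), chosen for
  portability and diffability over storage efficiency.
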