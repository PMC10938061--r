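# megdecode

Interpretable full-epoch multiclass decoding for epoched M/EEG-like data.

## The problem

Decoding studies of MEG/EEG usually slide a linear classifier over short
(~100 ms) windows of the epoch: the resulting accuracy time course is easy
to interpret, but each model sees only a sliver of the data and accuracy
suffers — especially with many stimulus classes. Training one multiclass
model on the *full epoch* decodes better, but a monolithic model no longer
tells you *where*, *when*, or *at which frequencies* the discriminative
activity lives.

`megdecode` implements a workflow that keeps both properties:

* a **deep linear neural network** whose first layer is a learnable
  `channels x components` spatial projection `W_dr` — supervised
  dimensionality reduction trained end to end for the classification
  objective (`train_nn()`). In evaluation mode the network collapses to a
  single affine map (`collapse_nn()`);
* **shrinkage LDA** (Ledoit–Wolf `"auto"` intensity) on features projected
  through the network matrix (**LDA-NN**) or through variance-ranked
  channel PCA (**LDA-PCA**), full-epoch or sliding-window (`fit_decoder()`,
  `train_windowed()`);
* a **permutation feature importance (PFI)** suite that reads temporal,
  spatial, spatiotemporal, spectral, spatio-spectral and temporo-spectral
  discriminative structure out of a *single* trained full-epoch model, as
  accuracy loss under block-wise permutation (`temporal_pfi()` and
  friends), including an exact weighted-overlap-add STFT for the
  time-frequency variant;
* a **synthetic MEG-like generator** (`generate_epochs()`) with 1/f
  background, co-located gradiometer/magnetometer sensor triplets and
  planted Gabor-like class responses, so every attribution method has a
  ground-truth recovery target;
* Wilcoxon signed-rank comparisons with Bonferroni correction and exact
  binomial chance bands (`wilcoxon_signed_rank()`, `chance_band()`).

The decoding model is the trained pipeline `whitening -> projection ->
flattening -> classifier`; PFI permutes raw sensor-space input, so maps are
always in sensor coordinates.

## Worked example

```r
library(megdecode)

# simulate the reference condition: 8 classes x 30 trials, 30 channels
# (10 sensor sites), 0.9 s at 100 Hz, with an evoked cascade whose
# dominant component is a 10 Hz burst at 100-200 ms on sites 2-3
gen   <- generate_epochs(benchmark_config("standard", seed = 1))
ep    <- gen$epochs
split <- stratified_split(ep$labels, ratio = 0.2, seed = 1)

# full-epoch decoder: supervised dimensionality reduction + shrinkage LDA
dec <- fit_decoder(ep, split, method = "lda_nn",
                   nn = nn_config(n_components = 16, h1 = 256, h2 = 48,
                                  n_epochs = 300, seed = 1))
accuracy(dec, ep, split$validation)
#> [1] 0.9583333

# where in time is the class information? permute channels window-by-window
tpfi <- temporal_pfi(dec, ep, split$validation, plan = pfi_plan(10, seed = 1))
s <- pfi_summary(tpfi)
s$center_s[which.max(s$mean_loss)] * 1000   # peak accuracy loss (ms)
#> [1] 130

# which sensors? permute each site's timepoints
spfi <- spatial_pfi(dec, ep, split$validation, plan = pfi_plan(10, seed = 1))
ss <- pfi_summary(spfi)
ss$site[order(-ss$mean_loss)][1:2]          # most informative sites
#> [1] 3 2
```

The decoder recovers the planted structure: validation accuracy 0.96
against a chance level of 0.125, the temporal importance peak at 130 ms
(inside the planted 100–200 ms window), and sites 3 and 2 — the planted
pair — as the most informative sensors. Sliding-window baselines
(`train_windowed()`, `per_sensor_lda()`) produce the classical accuracy
time courses and sensor maps these PFI profiles are validated against, and
`run_experiment()` drives the whole pipeline from a YAML configuration
(see `inst/cli/megdecode.R` for the command-line wrapper).

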