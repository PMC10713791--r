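# msstm

Cross-subject EEG emotion recognition via source microstate analysis
and style transfer mapping.

EEG *microstates* are brief (~80–120 ms) periods during which the
scalp topography stays quasi-stable; their statistics — how often each
map occurs, how long it lasts, how maps follow each other — carry
discriminative information about emotional state. Those statistics,
computed per frequency band, make good features; but they shift from
person to person, so a classifier trained on one group of subjects
degrades badly on an unseen subject. *Style transfer mapping* (STM)
repairs this with an affine correction, learned without ever looking
at the unseen subject's labels, that moves the new subject's feature
distribution toward the training distribution.

The package implements the full pipeline:

- **`sloreta_solve()`** — standardized distributed source localization
  (sLORETA), with exact zero localization error for noiseless single
  dipoles;
- **`compute_gfp()`, `cluster_microstates()`, `select_k()`,
  `backfit()`, `smooth_labels()`, `microstate_statistics()`** —
  GFP-peak microstate clustering (modified k-means), GEV/CV model
  selection, backfitting and temporal smoothing, microstate statistics;
- **`bandpass_filter()`, `notch_filter()`, `window_segments()`,
  `differential_entropy()`, `band_psd()`,
  `microstate_features_per_window()`, `fuse_bands()`** — band
  decomposition (delta/theta/alpha/beta/gamma) and per-window features:
  40 microstate dimensions per band, 200 after five-band fusion;
- **`learn_prototypes()`, `pair_targets()`, `solve_stm()`,
  `apply_map()`** — closed-form confidence-weighted STM with
  identity-ridge regularization;
- **`run_pipeline()`, `train_svm()`, `loso_folds()`** — the
  leave-one-subject-out protocol with linear SVMs (27-value cost
  grid), reporting with- and without-transfer accuracy side by side;
- **`simulate_dataset()`** — a synthetic multi-subject EEG generator
  with known prototypes, class-conditional microstate dynamics, and
  per-subject affine feature styles, so every estimator is testable
  against ground truth.

## Example

```r
library(msstm)

cfg <- generator_config(seed = 42)   # 6 subjects, 3 classes, 28 ch, 250 Hz
ds  <- simulate_dataset(cfg)
res <- run_pipeline(ds, seed = 42)   # ~3 minutes on one CPU
print(res)
#> Leave-one-subject-out cross-subject accuracy (%)
#>  target accuracy_no_stm accuracy_stm
#>       1           41.67        50.33
#>       2           48.00        73.33
#>       3           67.33        78.33
#>       4           63.33        72.33
#>       5           68.67        57.00
#>       6           55.00        69.67
#> mean without STM: 57.33 (sd 10.98)
#> mean with STM:    66.83 (sd 10.79)
#> chance level:     33.33
```

Smaller building blocks compose directly:

```r
rec  <- ds$recordings[[1]]
alpha <- bandpass_filter(rec, 8, 13)
g    <- compute_gfp(alpha)
maps <- t(alpha$data[, g$peak_indices])
ms   <- cluster_microstates(maps, k = 5)
seg  <- smooth_labels(backfit(alpha, ms))
microstate_statistics(seg)
```

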