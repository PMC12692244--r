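# spectramt

Cross-temporal classification of near-infrared (NIR, 1000–2500 nm)
reflectance spectra of stored eggs. Eggs of different commercial varieties
look alike but differ in composition; during refrigerated storage their
spectra *drift* — water bands at ~1450/1950 nm lose depth, the lipid C–H
doublet at 1720/1780 nm fades with oxidation, band centres creep — and a
classifier that ignores storage time degrades badly on aged samples.
`spectramt` implements, end to end and fully seeded:

* **two-point reflectance calibration** `(R_raw − R_dark)/(R_white − R_dark)`
  with region-of-interest mean spectra and replicate-scan averaging (CV
  stability check);
* **standard normal variate (SNV)** preprocessing, `(x − mean(x))/sd(x)` per
  spectrum;
* **CARS wavelength selection** (competitive adaptive reweighted sampling):
  Monte-Carlo PLS-DA fits, an exponentially decreasing forced-retention
  schedule `N_iter(r) = round(N·a·e^(−kr))` pinned to `N_iter(1) = p` and
  `N_iter(R) = 2`, importance-weighted resampling, RMSECV model choice, a
  **two-stage cross-temporal merge** (per-day selection → union → re-filter
  on pooled days), and **VIP scores** (`sum(VIP²) = p`);
* a **multi-task network**: 1-D CNN → squeeze-and-excitation channel gate
  `σ(W₂ ReLU(W₁ GAP(U)))` → sinusoidal positional encoding → four post-norm
  Transformer encoder layers (`softmax(QKᵀ/√d_k)V`, 4 heads) → global
  average pooling → two softmax heads (variety, storage period) under hard
  parameter sharing, trained by AdamW with cosine annealing and early
  stopping on the joint loss `α·L₁ + β·L₂` (α = β = 0.5); single-task and
  ablation variants (drop CNN and/or SE) are built from the same code path;
* **evaluation** sliced the way drift studies report it: variety accuracy
  per storage day, storage-period accuracy per variety, with one-vs-rest
  precision/recall/F1;
* a **synthetic spectra generator** with known informative bands, emulating
  variety-specific absorption amplitudes, storage decay, band-position
  drift, egg-level biological variability and the scatter/baseline/noise
  artifacts SNV removes — every stage is testable without any proprietary
  data.

The network core (forward, backpropagation, AdamW) is compiled
(RcppArmadillo); exported forward/gradient entry points run in double
precision and are verified against a pure-R reference implementation and
finite differences.

## Worked example

```r
library(spectramt)

cfg <- default_egg_sim_config()          # 3 varieties x 100 eggs x days {1,20,40}
cfg$seed <- 42L
scans <- simulate_dataset(cfg)           # 2700 scans x 273 bands
eggday <- average_scans(scans)           # 900 egg-day mean spectra
spec <- snv_table(eggday)

split <- stratified_egg_split(spec, 0.2, seed = 42)
train <- st_subset(spec, spec$egg_id %in% split$train_eggs)
test  <- st_subset(spec, spec$egg_id %in% split$test_eggs)

sel <- two_stage_select(train, cars_config(seed = 42))
sel
#> <two_stage_result> 19 final bands (union of 48), task 'joint'
#>   wavelengths (nm):  1110, 1336, 1375, 1447, 1507, 1562, 1728, 1772, 1789,
#>   1888, 1960, 2092, 2136, 2213, 2252, 2296, 2329, 2351, 2456

net <- build_network(model_config(n_bands_in = length(sel$final)),
                     "mt_ctse", seed = 1)
net <- fit_network(net, train, sel$final,
                   train_config(epochs = 200, seed = 1))
ev <- evaluate_sliced(net, test, "by_day")
round(sapply(ev$slices, `[[`, "accuracy"), 3)
#>     1    20    40
#> 0.917 0.817 0.983
ev$pooled
#> <eval_report> n = 180, accuracy = 0.9056, macro F1 = 0.9053
```

The selected wavelengths cluster on the lipid doublet (1728–1789 nm), the
water bands (1375–1507, 1888–1960 nm) and the protein/carbohydrate region
(2136–2351 nm) — the regions the generator makes informative — and the
multi-task model holds its accuracy on day-40 spectra, where a pooled
linear PLS-DA baseline trained across all days scores far lower.

One call runs the whole experiment (all variants × 5 seeds) and writes
comparison tables:

```r
res <- reproduce(pipeline_config(seed = 42), out_dir = "experiment")
res$variety_by_day$summary
```

A thin command-line front end with `simulate`, `preprocess`,
`select-bands`, `train`, `evaluate` and `reproduce` subcommands is
installed at `inst/cli/spectramt.R`.

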