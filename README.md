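# vitaspec

Predicting the percentage of live bacteria in a mixed live/dead sample
from quantitative SYTO 9 / propidium iodide (PI) fluorescence spectra.

Bacterial viability is routinely assessed by dual staining: SYTO 9 labels
all cells but dominates in live ones under counterstaining, while PI
enters only membrane-compromised ("dead") cells. A fibre-based
spectroscopic probe records, per sample, 500 consecutive emission spectra
(20 ms each, 10 s total) across 500–750 nm, and the task is to calibrate
those spectra against reference percent-live values (from flow
cytometry). `vitaspec` is aimed at researchers in quantitative
microbiology and chemometrics who want that calibration chain as tested,
reusable code.

## What it computes

With `SYTO9` and `PI` the integrated emission intensities over 509–529 nm
and 609–629 nm, the package implements four estimators of %live:

* **Dye ratio** `R = SYTO9 / PI` — the classical kit-manual proxy;
  under ideal staining `R = f/(100−f)`, intrinsically nonlinear in the
  live fraction `f`.
* **Adjusted dye ratio** `100·R/(1+R)` — linear in `f` under ideal
  staining, and exactly equal to it when both dyes report with equal
  efficiency.
* **Single-spectrum SVR** — linear ε-SVR on the mean-centred first frame,
  with hyperparameters (C, ε) tuned by grid search under group K-fold
  cross-validation (folds = whole experiments, so correlated measurements
  never leak across a split).
* **Multi-spectra SVR** — the same, on the first frame concatenated with
  frames taken at the photobleaching half-lives of the bound/unbound dye
  pools; candidate frame combinations are screened at default parameters
  (C = 1, ε = 0.1) before tuning.

Supporting machinery: spectral pre-processing (dark removal,
normalisation to 8 ms / 10 mW, saline-background subtraction, robust
median ± 3·MAD anomaly screening, frame selection, mean-centring),
double-exponential photobleaching fits `I(t) = A1·e^(−t/τ1) + A2·e^(−t/τ2)`
with half-life derivation and Welch comparisons, prediction validity
filtering (averaged predictions outside [0, 100] are excluded), agreement
statistics about the 1:1 line (RMSE, explained variance, R², standard
error, within-2-SE fraction), Bland–Altman analysis with a Shapiro–Wilk
normality check, and a PCA nearest-centroid gate that routes blind
samples to the calibration model of their concentration class.

Because instrument datasets of this kind are not generally deposited, the
package includes a synthetic measurement generator
(`generator_design()` / `generate_dataset()`) that emulates the
statistical structure of probe measurements — two dye emission bands with
bound/unbound pools, per-pool double-exponential photobleaching,
experiment-level variation, dark and shot-like noise, occasional
anomalous measurements, and reference-method error — so the entire
workflow runs and is tested offline. See the vignette
(`vignettes/viability-calibration.Rmd`) for the model, parameter
defaults, and what the generator does and does not emulate.

## Worked example

```r
library(vitaspec)

# simulate a small two-experiment study at 1e8 bacteria/mL
design <- generator_design(concentration_classes = 1e8, n_experiments = 2,
                           replicates_per_sample = 2, seed = 42)
train <- generate_dataset(design)
spectra <- lapply(train$measurements, preprocess_series)

# half-lives of the four dye pools from pure live/dead samples
half_life_table(spectra, train$samples)
#>     dye state half_life_ms     se_ms n
#> 1 SYTO9    mB     1255.650 0.9134116 4
#> 2 SYTO9    mU     1375.662 8.8197835 8
#> 3    PI    mB     1123.305 0.8230197 8
#> 4    PI    mU     1094.076 9.7785043 4

# per-sample dye-ratio statistics
head(sample_ratio_table(spectra, train$samples)[, c(1, 2, 5, 6)], 4)
#>               sample_id f_live_ref  dye_ratio adjusted_dye_ratio
#> 1 train_1e+08_e1_f000.0   0.000000 0.07188558           6.706460
#> 2 train_1e+08_e1_f002.5   3.044693 0.09771181           8.901408
#> 3 train_1e+08_e1_f005.0   5.949294 0.12718375          11.283320
#> 4 train_1e+08_e1_f010.0  10.606402 0.18173182          15.378432

# multi-spectra SVR calibrated on the first frame + mB-SYTO9 half-life
model <- train_calibration(spectra, train$samples,
                           timepoints = c(0, 1244),
                           C_values = c(0.5, 10), eps_values = c(0.001, 0.1))
model
#> <calibration_model> svr: 2 timepoints (0, 1244 ms), 502 features, C=0.5, eps=0.001

# predict a blind test set
test_design <- design; test_design$n_experiments <- 1; test_design$seed <- 99
test <- generate_dataset(test_design, id_prefix = "test")
preds <- predict_samples(model, lapply(test$measurements, preprocess_series),
                         test$samples)
ok <- preds$valid
m <- regression_metrics(preds$prediction[ok], preds$f_live_ref[ok])
cat(sprintf("standard error %.2f%%, %.0f%% of samples within 2 SE, %d invalid\n",
            m$standard_error,
            within_2se_fraction(preds$prediction[ok], preds$f_live_ref[ok],
                                m$standard_error),
            sum(!preds$valid)))
#> standard error 1.26%, 100% of samples within 2 SE, 1 invalid
```

Reading the output: the four recovered photobleaching half-lives sit
within a few percent of the generator's targets (1244 / 1472 / 1124 /
1084 ms); the dye ratio grows nonlinearly with the reference live
fraction while the adjusted ratio tracks it roughly linearly; grid search
selects C = 0.5 and ε = 0.001 for the multi-spectra model; and on the
blind test set the per-sample predictions sit within 1.26 percentage
points (1 SE) of the reference values, with one physically impossible
averaged prediction (outside [0, 100]) flagged and excluded.

The full orchestration — simulate, preprocess, fit kinetics, screen frame
combinations, tune, validate, and write every per-stage artifact (CSV
tables, JSON models and reports, a run manifest) — is one call:

```r
res <- run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
```

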