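---
title: "Calibrating percent-live predictions from dual-stain fluorescence spectra"
author: "vitaspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating percent-live predictions from dual-stain fluorescence spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitaspec)
```

## The measurement and the problem

A mixed population of live and dead bacteria stained with SYTO 9 and
propidium iodide (PI) emits a composite fluorescence spectrum: SYTO 9 is
membrane-permeant and dominates in live cells when counterstained, PI
enters only membrane-compromised cells. A fibre-based spectroscopic probe
records, for each sample, a time-resolved measurement: 500 consecutive
emission spectra of 20 ms each (10 s of continuous excitation), on a
wavelength grid covering roughly 500–750 nm (a 495 nm longpass filter
removes the excitation line). The goal is to predict the percentage of
live cells in a sample from such a measurement, calibrated against a
reference method (flow cytometry) that supplies per-sample percent-live
values.

`vitaspec` implements the complete calibration chain and, because
instrument datasets of this kind are rarely deposited, a synthetic
measurement generator with the same statistical structure, so that every
stage of the chain is exercised end to end by the test suite.

## Estimators

**Dye ratio.** With `SYTO9` and `PI` the integrated intensities over the
dye emission windows (509–529 nm and 609–629 nm; closed intervals,
trapezoid rule on the native grid, no resampling), the classical proxy is

\[ \%\mathrm{live} \propto R = \mathrm{SYTO9} / \mathrm{PI}. \]

`R` compares live signal to *dead* signal, not to total signal, so it is
intrinsically nonlinear in percent live: under ideal staining
`R = f/(100-f)`.

**Adjusted dye ratio.** Solving that proportionality for `f` gives

\[ \%\mathrm{live} \propto \frac{100\,R}{1 + R}, \]

which *is* linear in percent live under ideal staining, and equals it
exactly when the two dyes report live and dead cells with equal
efficiency. `adjusted_dye_ratio()` returns 100 at the boundary
`PI = 0, SYTO9 > 0` (the continuous limit `R -> Inf`, i.e. a fully live
sample); a negative PI integral is an error. For small `R` the adjusted
ratio reduces to `100 R`, i.e. the plain ratio up to scale.

**SVR calibration.** Ratio estimators use only two integrals. The
multivariate route regresses percent live on the whole mean-centred
spectrum with a linear epsilon-SVR (`e1071`/LIBSVM): single-spectrum
models use the first frame (the least photobleached spectrum);
multi-spectra models concatenate the first frame with frames selected at
the photobleaching half-lives of the four dye pools, where spectral-shape
change over time is most informative.

## Photobleaching kinetics

Each dye/state pool — mostly bound (mB) or mostly unbound (mU) SYTO 9 and
PI — bleaches along a double exponential
`I(t) = A1 exp(-t/tau1) + A2 exp(-t/tau2)`. `fit_double_exponential()`
fits per-measurement window traces by Levenberg–Marquardt
(`minpack.lm::nlsLM`) under non-negativity bounds. Such fits are
initialisation-sensitive, so a deterministic multi-start is used: both
time constants start from the crossed pairs of {0.2, 1, 5} s, amplitudes
split equally from the initial intensity, and the converged fit with the
lowest SSE wins (canonical order `tau1 <= tau2`). No constant offset term
is included by default — background subtraction is assumed to have
removed offsets — but `offset = TRUE` adds one.

The half-life is the unique root of `I(t) = I(0)/2`, found by bracketed
root finding (tolerance 1e-9 ms); it is invariant to amplitude scaling
and bounded by `min(tau) ln 2` and `max(tau) ln 2`. Half-lives are fitted
per measurement and then averaged (standard error = sd/sqrt(n)); the
alternative, fitting one pooled trace, would hide replicate variability.
The assignment of pools to samples follows the staining logic: live
samples yield mB-SYTO9 and mU-PI, dead samples yield mU-SYTO9 and mB-PI.
A sample counts as "live" when its reference value is at least 95% and
"dead" at or below 5%; with the default fraction series this captures
the 100% and the 0/2.5/5% samples, whose traces are dominated by the
intended pool.

Bound and unbound half-lives are compared with a Welch (unequal-variance)
two-sided t-test — the plain "t test" leaves the variance assumption
open, and Welch is the safer default for small unequal groups.

## Cross-validated calibration

Measurements from one experiment share correlated conditions (staining
batch, probe state, optical alignment), so folds of the cross-validation
are whole experiments: with `M` experiments, `M` folds, each holding out
exactly one experiment (`gkcv_folds()` guarantees the partition). The CV
error is the RMSE pooled over all held-out predictions — every
measurement is predicted exactly once — rather than an average of
per-fold RMSEs, which would weight small experiments up.

Candidate spectral combinations (the first frame alone; paired with each
of the four half-life frames; the two 3-frame bound/unbound sets; all
five frames) are screened at default parameters `C = 1, epsilon = 0.1`;
ties prefer fewer time points, since frames beyond the informative ones
add noise without adding compositional information. The chosen
combination is then tuned by exhaustive grid search over
`C in {0.01, 0.1, 0.5, 1, 10, 100}` and
`epsilon in {0.001, 0.01, 0.1, 1}` under the same grouped CV, and refitted
on all training data. The grid spans three decades either side of the
default because the optimum on mean-centred spectra of this scale tends
to sit at small `C` and small `epsilon`.

Two implementation notes. First, features are mean-centred with the
full-training per-timepoint mean rather than per-fold means: for a linear
SVR a common shift of all rows is absorbed entirely by the intercept, so
held-out predictions are identical either way, and the model can store
one set of training means. Second, trained models are immediately reduced
to primal form (weight vector + intercept) and persisted as JSON with 17
significant digits, which round-trips IEEE doubles exactly — a reloaded
model predicts bit-for-bit identically, and the weights are auditable.

## Prediction validity and validation statistics

Per-measurement predictions are averaged per sample; an averaged
prediction below 0 or above 100 percent is physically impossible, is
flagged invalid, and is excluded from agreement statistics (0 and 100
themselves are valid). Exclusion happens after averaging: the average is
the sample-level estimate, and replicates that disagree in sign should
not be silently censored one by one.

Agreement is always measured about the 1:1 line, not a refitted
regression: `rmse`; `explained_variance = 1 - Var(ref - pred)/Var(ref)`;
`r_squared = 1 - SS_res/SS_tot`, which is negative when predictions do
worse than the reference mean; and `standard_error =
sqrt(SS_res/(n - 1))`, the residual standard deviation about the 1:1 line.
"Standard error" in this sense also defines the acceptance band of the
validation plot: the within-2-SE fraction counts samples with
`|pred - ref| <= 2 SE` (inclusive). Bland–Altman agreement uses
`d = ref - pred`, bias `mean(d)`, 95% limits `bias ± 1.96 sd(d)`, and a
Shapiro–Wilk normality check on `d` (`NA` when `n < 3` or the differences
are constant).

Finally, because the models are trained per concentration class, blind
samples are routed by a PCA gate: frame-0 spectra of the two classes
differ by an order of magnitude in scale and separate cleanly in the
first two principal components, where a nearest-centroid rule assigns the
class.

## The synthetic generator

`generator_design()` encodes the study conditions: live fractions
0, 2.5, 5, 10, 25, 50, 75, 100%; concentration classes 1e8 and 1e7
bacteria/mL with 4 and 3 experiments respectively; 3 replicate
measurements per sample; 500 frames of 20 ms on a 500–750 nm grid at
1 nm spacing (the spectrometer's native spacing is not public; 1 nm is a
stand-in).

Each measurement is a sum over the four dye pools of
`amplitude x bleach(t) x shape(lambda)`:

* **Shapes** are Gaussians truncated at ±6 sigma: bound SYTO 9 at 519 nm
  (sigma 12 nm) with a small 501 nm shoulder (the nucleic-acid-bound
  emission, truncated by the grid edge); unbound SYTO 9 at 519 nm (sigma
  16); bound PI at 619 nm (sigma 14); unbound PI at 619 nm (sigma 18).
  The truncation gives compact support, so the two dye bands do not leak
  into each other's integration windows; the neglected tail mass is below
  1e-9 of a peak.
* **Amplitudes** follow `bound-SYTO9 = alpha1 L + alpha2 D` and
  `bound-PI = gamma D + gamma' L` with `L + D = 100` units for a 1e8/mL
  sample (defaults `alpha1 = gamma = 12`, `alpha2 = 0.3`,
  `gamma' = 0.1`): SYTO 9 stains dead cells weakly under counterstaining,
  and PI picks up a small signal from live cells. Unbound-dye amplitudes
  are fixed per class (60/40 counts at 1e8; 160/120 at 1e7): the dye dose
  is constant, so the lower concentration leaves more dye unbound — the
  dominant noise source at 1e7. No quantitative staining model is
  published; these coefficients are illustrative, chosen to reproduce the
  qualitative spectra (dual-stained dead samples show strongly reduced
  SYTO 9; the 1e7 class is dominated by unbound dye). An optional
  `pi_enhancement` coefficient (default 0) can emulate PI enhancement by
  SYTO 9.
* **Bleaching**: each pool decays along a double exponential built by
  `bleach_params_for_half_life()` to hit its target half-life exactly
  (defaults: mB-SYTO9 1244 ms, mU-SYTO9 1472 ms, mB-PI 1124 ms, mU-PI
  1084 ms; amplitude split 0.6/0.4, tau ratio 3).
* **Noise**: additive Gaussian dark noise (sd 2 counts), shot-like noise
  with sd `0.5 sqrt(counts)`, a log-normal per-experiment factor (log-sd
  0.05, the scale drift plausible for a power-monitored instrument), a
  2% chance that a measurement is anomalous (multiplied by 3; the tag is
  kept as ground truth but withheld from the pipeline), and Gaussian
  reference-method error (sd 1.5%, clipped to [0, 100]).

Reproducibility: one base seed per dataset; each measurement draws from a
substream derived deterministically from the seed, the sample index and
the replicate index, so datasets replay bit for bit.

**Ideal mode** (`ideal_mode = TRUE`) is the package's definition of ideal
staining: `alpha2 = gamma' = 0`, `gamma = alpha1`, no unbound dye, no
noise of any kind, equal peak widths, no shoulder peak, and one shared
bleach curve for both dyes. The shared bleach curve matters: with
different half-lives the two windows would carry slightly different
bleach factors already at the first frame midpoint (10 ms), breaking the
exact identity. Under ideal mode the frame-0 window ratio is exactly
`L/D` and the adjusted dye ratio equals percent live to machine
precision — the algebraic identity the test suite asserts — while the
plain dye ratio remains `f/(100-f)`, demonstrating the linear/nonlinear
contrast between the two estimators.

### What the generator does not emulate

* Kinetic variability between measurements: each pool's half-life is
  fixed. Real samples vary enough that the study found bound and unbound
  half-lives *not* significantly different; on synthetic data the Welch
  test detects the built-in difference with tiny p-values. The generator
  demonstrates the machinery, not the field significance result.
* Instrument artifacts other than a whole-measurement scale factor
  (wavelength drift, detector nonlinearity, probe fouling dynamics).
* Dye photochemistry: no dye–dye energy transfer beyond the optional
  enhancement coefficient, no concentration-dependent binding kinetics.

Passing tests on synthetic data therefore certify the correctness of the
computations and the internal consistency of the workflow, not the
field accuracy of the method on real instrument data.

## Numerical and degenerate-case choices

* Pre-processing order is fixed: dark removal, then normalisation by
  `(8 ms / t_int) x (10 mW / P)`, then background subtraction (whether
  the original workflow normalised before or after dark removal is
  unstated; dark-first is assumed, and for a constant dark offset the
  two orders differ only by a known scale on the offset). Negative
  post-background intensities are kept — clipping would bias window
  integrals — but a negative full-window integral is flagged.
* Anomaly screening is automated (the original exclusion was manual):
  a replicate whose frame-0 full-window integral deviates from the
  replicate median by more than 3 MAD is flagged. A single measurement is
  never flagged; with exactly two replicates no robust spread exists, so
  disagreement beyond 1.5x is reported for review without auto-flagging.
  Flags are advisory and logged; `run_pipeline()` excludes flagged
  measurements and writes the exclusion log.
* Frames carry midpoint timestamps; a time point maps to the nearest
  midpoint with ties broken toward the earlier (less bleached) frame; at
  most 5 frames may be selected per measurement. Ratio statistics use
  frame 0 only (whether the original integrated one frame or several is
  unstated; frame 0 is the least-bleached choice).
* Grid-search ties take the first minimum in C-major grid order;
  screening ties prefer fewer time points, then earlier candidates.
* `summary()` problem sizes: the test suite runs the workflow on reduced
  geometries (2 experiments, 2–4 fractions, 2–500 frames as each test
  needs), and the acceptance script runs the full default conditions;
  both finish in minutes on one CPU.

## Known limitations

* The amplitude model is linear in live/dead abundance; saturation of
  staining at high density is not modelled.
* The PCA gate separates classes by overall intensity scale; classes with
  overlapping scales would need a richer classifier.
* The half-life table requires pure (or near-pure) live and dead samples
  in the training set; designs without fractions at the extremes cannot
  estimate all four pools.
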