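Package: vitaspec
Title: Bacterial Viability from Dual-Stain Quantitative Fluorescence Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts the percentage of live bacteria in mixed live/dead
    samples from time-resolved SYTO 9 / propidium iodide fluorescence
    spectra recorded by a fibre-based spectroscopic probe. Implements the
    full calibration workflow: spectral pre-processing (dark-noise removal,
    normalisation to reference integration time and laser power, background
    subtraction, robust anomaly screening, frame selection and
    mean-centring), SYTO 9:PI dye-ratio and adjusted dye-ratio estimators,
    double-exponential photobleaching kinetics with half-life derivation,
    single- and multi-spectra linear epsilon-SVR calibration tuned by grid
    search under group K-fold cross-validation, prediction validity
    filtering, and a validation suite (RMSE, explained variance, standard
    error, within-2-SE fraction, Bland-Altman agreement with Shapiro-Wilk
    normality check, PCA-based concentration gating). Includes a synthetic
    measurement generator that emulates the statistical structure of
    optrode measurements so every stage is testable without instrument
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
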