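# fixtures are built in code; nothing on disk

# small constant-frame series on an arbitrary grid
toy_series <- function(n_frames = 4, wavelengths = seq(500, 520, by = 2),
                       value = 1, frame_duration_ms = 20,
                       measurement_id = "m1", sample_id = "s1",
                       integration_time_ms = frame_duration_ms,
                       normalised = FALSE) {
  new_measurement_series(
    wavelengths,
    matrix(value, length(wavelengths), n_frames),
    frame_duration_ms = frame_duration_ms,
    measurement_id = measurement_id, sample_id = sample_id,
    integration_time_ms = integration_time_ms,
    normalised = normalised)
}

# ideal-staining generator scaled down for unit tests
ideal_tiny_design <- function(n_experiments = 1, replicates_per_sample = 1,
                              n_frames = 3, seed = 7, ...) {
  generator_design(ideal_mode = TRUE, concentration_classes = 1e8,
                   n_experiments = n_experiments,
                   replicates_per_sample = replicates_per_sample,
                   n_frames = n_frames, seed = seed, ...)
}

# preprocess a whole generated dataset with default settings
preprocess_all <- function(dataset, config = preprocess_config()) {
  lapply(dataset$measurements, preprocess_series, config = config)
}

# scaled-down study conditions used for pipeline-level tests: one
# concentration class, two experiments, pure plus intermediate fractions,
# reduced hyperparameter grids
small_pipeline_config <- function(out_dir, seed = 5) {
  pipeline_config(
    out_dir = out_dir, seed = seed,
    design = generator_design(concentration_classes = 1e8,
                              n_experiments = 2,
                              live_fractions = c(0, 25, 75, 100),
                              replicates_per_sample = 2, seed = seed),
    C_values = c(0.5, 10), eps_values = c(0.001, 0.1))
}

# brute-force primal solver for a 1-feature linear eps-SVR:
# minimises 0.5 w^2 + C * sum(max(0, |y - (w x + b)| - eps)) by
# multi-start Nelder-Mead; independent of the LIBSVM route
primal_svr_1d <- function(x, y, C, eps) {
  obj <- function(p) {
    0.5 * p[1]^2 + C * sum(pmax(0, abs(y - (p[1] * x + p[2])) - eps))
  }
  best <- NULL
  for (w0 in c(-1, 0, 1, 2, 5)) {
    for (b0 in c(-10, 0, 10, mean(y))) {
      r <- stats::optim(c(w0, b0), obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
      if (is.null(best) || r$value < best$value) best <- r
    }
  }
  best$par
}
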