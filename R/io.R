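BUNDLE_VERSION <- "vitaspec-bundle-1"
MODEL_VERSION <- "vitaspec-model-1"

#' Write a measurement bundle
#'
#' A bundle is a directory holding one spectra table per measurement
#' (CSV: first column `wavelength_nm`, remaining columns
#' `frame_0000, frame_0001, ...` in acquisition order) plus a
#' `metadata.json` sidecar describing samples and measurements. All files
#' are plain text with deterministic column ordering, so bundles are
#' diffable and round-trip through [read_measurement_bundle()].
#'
#' @param measurements List of `vs_series`.
#' @param samples List of `vs_sample`; every referenced measurement must
#'   be present and vice versa.
#' @param path Bundle directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_measurement_bundle <- function(measurements, samples, path) {
  m_ids <- vapply(measurements, `[[`, "", "measurement_id")
  if (anyDuplicated(m_ids)) stop("duplicate measurement ids")
  referenced <- unlist(lapply(samples, `[[`, "measurement_ids"))
  missing_m <- setdiff(referenced, m_ids)
  if (length(missing_m)) {
    stop("samples reference missing measurements: ",
         paste(missing_m, collapse = ", "))
  }
  s_ids <- vapply(samples, `[[`, "", "sample_id")
  bad <- setdiff(vapply(measurements, `[[`, "", "sample_id"), s_ids)
  if (length(bad)) {
    stop("measurements reference unknown samples: ", paste(bad, collapse = ", "))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create bundle directory ", path)
  meta <- list(
    version = BUNDLE_VERSION,
    samples = lapply(samples, function(s) {
      list(sample_id = s$sample_id, experiment_id = s$experiment_id,
           concentration_class = s$concentration_class,
           f_live_ref = s$f_live_ref,
           measurement_ids = as.list(s$measurement_ids))
    }),
    measurements = lapply(measurements, function(m) {
      list(measurement_id = m$measurement_id, sample_id = m$sample_id,
           n_frames = ncol(m$intensities),
           frame_duration_ms = m$frame_duration_ms,
           integration_time_ms = m$integration_time_ms,
           laser_power_mw = m$laser_power_mw,
           normalised = m$normalised)
    }))
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  for (m in measurements) {
    df <- data.frame(wavelength_nm = m$wavelengths, m$intensities)
    names(df) <- c("wavelength_nm",
                   sprintf("frame_%04d", seq_len(ncol(m$intensities)) - 1L))
    utils::write.csv(df, file.path(path, paste0("spectra_", m$measurement_id,
                                                ".csv")),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a measurement bundle
#'
#' Inverse of [write_measurement_bundle()]. Wavelengths are checked for
#' monotonicity, frame counts against the metadata, and every
#' cross-reference between samples and measurements must resolve.
#'
#' @param path Bundle directory.
#' @return List with `measurements` (list of `vs_series`) and `samples`
#'   (list of `vs_sample`).
#' @export
read_measurement_bundle <- function(path) {
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path)) stop("not a bundle: missing ", meta_path)
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = FALSE)
  if (!identical(meta$version, BUNDLE_VERSION)) {
    stop("bundle version tag mismatch: found '", meta$version %||% "<none>", "'")
  }
  samples <- lapply(meta$samples, function(s) {
    new_sample_record(s$sample_id, s$experiment_id, s$concentration_class,
                      s$f_live_ref, unlist(s$measurement_ids))
  })
  measurements <- lapply(meta$measurements, function(mm) {
    f <- file.path(path, paste0("spectra_", mm$measurement_id, ".csv"))
    if (!file.exists(f)) {
      stop("spectra file missing for measurement ", mm$measurement_id)
    }
    df <- utils::read.csv(f, check.names = FALSE)
    if (!identical(names(df)[1], "wavelength_nm")) {
      stop("missing wavelength column in ", f)
    }
    wl <- df[[1]]
    if (any(diff(wl) <= 0)) stop("non-monotone wavelengths in ", f)
    inten <- as.matrix(df[, -1, drop = FALSE])
    if (ncol(inten) != mm$n_frames) {
      stop("frame count mismatch for measurement ", mm$measurement_id,
           ": metadata says ", mm$n_frames, ", file has ", ncol(inten))
    }
    new_measurement_series(wl, inten,
                           frame_duration_ms = mm$frame_duration_ms,
                           measurement_id = mm$measurement_id,
                           sample_id = mm$sample_id,
                           integration_time_ms = mm$integration_time_ms,
                           laser_power_mw = mm$laser_power_mw,
                           normalised = isTRUE(mm$normalised))
  })
  s_ids <- vapply(samples, `[[`, "", "sample_id")
  m_samples <- vapply(measurements, `[[`, "", "sample_id")
  bad <- setdiff(m_samples, s_ids)
  if (length(bad)) {
    stop("measurements reference unknown samples: ", paste(bad, collapse = ", "))
  }
  list(measurements = measurements, samples = samples)
}

#' Persist a calibration model as auditable text
#'
#' The linear SVR is stored in primal form (weight vector + intercept)
#' together with its full preprocessing state in a single JSON file, at
#' full floating-point precision, so a loaded model predicts identically
#' to the trained one.
#'
#' @param model A `calibration_model`.
#' @param path Output file path (`.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "calibration_model")) stop("not a calibration_model")
  obj <- list(version = MODEL_VERSION,
              kind = model$kind,
              timepoints_ms = model$timepoints_ms,
              wavelengths_nm = model$wavelengths_nm,
              mean_spectra = apply(model$mean_spectra, 1, identity,
                                   simplify = FALSE),
              weights = model$weights,
              intercept = model$intercept,
              C = model$C, epsilon = model$epsilon,
              concentration_class = model$concentration_class)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Load a persisted calibration model
#'
#' @param path JSON file written by [save_model()].
#' @return A `calibration_model`.
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("cannot parse model file ", path, " (truncated?): ",
                         conditionMessage(e))
                  })
  if (!identical(obj$version, MODEL_VERSION)) {
    stop("model version tag mismatch: found '", obj$version %||% "<none>", "'")
  }
  means <- obj$mean_spectra
  if (is.list(means)) means <- do.call(rbind, means)
  if (!is.matrix(means)) means <- matrix(means, nrow = 1)
  n_wl <- length(obj$wavelengths_nm)
  n_tp <- length(obj$timepoints_ms)
  if (!is.matrix(means) || nrow(means) != n_tp || ncol(means) != n_wl) {
    stop("corrupt model file: mean spectra do not match grid dimensions")
  }
  if (length(obj$weights) != n_tp * n_wl) {
    stop("corrupt model file: weight vector length ", length(obj$weights),
         " != ", n_tp * n_wl)
  }
  structure(
    list(version = obj$version, kind = obj$kind,
         timepoints_ms = as.numeric(obj$timepoints_ms),
         wavelengths_nm = as.numeric(obj$wavelengths_nm),
         mean_spectra = means,
         weights = as.numeric(obj$weights),
         intercept = obj$intercept,
         C = obj$C, epsilon = obj$epsilon,
         concentration_class = obj$concentration_class),
    class = "calibration_model")
}
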