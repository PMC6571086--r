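#' Construct a single fluorescence spectrum
#'
#' A spectrum is one wavelength-indexed intensity vector together with the
#' acquisition metadata needed for quantitative comparison: the CCD
#' integration time and the excitation laser power. Intensities are raw
#' fluorescence counts until [normalize_spectrum()] rescales them to the
#' reference acquisition conditions (8 ms, 10 mW).
#'
#' @param wavelengths Strictly increasing numeric grid, in nm.
#' @param intensities Numeric vector of fluorescence counts, same length as
#'   `wavelengths`.
#' @param integration_time_ms Integration time of the acquisition, ms (> 0).
#' @param laser_power_mw Excitation laser power, mW (> 0).
#' @param normalised Logical; `TRUE` once the spectrum has been rescaled to
#'   the reference integration time and power.
#' @return An object of class `"vs_spectrum"`.
#' @export
new_spectrum <- function(wavelengths, intensities,
                         integration_time_ms = 8, laser_power_mw = 10,
                         normalised = FALSE) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) < 2) stop("need at least 2 wavelengths")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (length(intensities) != length(wavelengths)) {
    stop("intensities and wavelengths must have the same length")
  }
  stop_if_not_scalar_pos(integration_time_ms, "integration_time_ms")
  stop_if_not_scalar_pos(laser_power_mw, "laser_power_mw")
  structure(
    list(wavelengths = wavelengths, intensities = intensities,
         integration_time_ms = integration_time_ms,
         laser_power_mw = laser_power_mw,
         normalised = isTRUE(normalised)),
    class = "vs_spectrum")
}

#' @export
print.vs_spectrum <- function(x, ...) {
  cat(sprintf("<vs_spectrum> %d points, %.0f-%.0f nm, t_int %g ms, P %g mW%s\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$integration_time_ms, x$laser_power_mw,
              if (x$normalised) ", normalised" else ""))
  invisible(x)
}

#' Construct a time-resolved measurement series
#'
#' One optrode measurement is a consecutive series of spectra (default
#' 500 frames of 20 ms each, i.e. 10 s of continuous excitation) sharing a
#' single wavelength grid. Frames are indexed 0-based; frame `k` covers the
#' acquisition interval `[k*d, (k+1)*d)` ms and carries the interval
#' midpoint as its nominal timestamp (see [frame_times()]).
#'
#' @param wavelengths Shared wavelength grid, nm, strictly increasing.
#' @param intensities Numeric matrix, `length(wavelengths)` rows, one column
#'   per frame, in acquisition order.
#' @param frame_duration_ms Duration of each frame, ms.
#' @param measurement_id,sample_id Opaque identifiers.
#' @param integration_time_ms Integration time of each frame, ms; defaults
#'   to the frame duration.
#' @param laser_power_mw Laser power during the measurement, mW.
#' @param normalised Logical; `TRUE` after [normalize_series()].
#' @param anomalous Logical flag set by anomaly screening (`NA` = not yet
#'   screened).
#' @return An object of class `"vs_series"`.
#' @export
new_measurement_series <- function(wavelengths, intensities,
                                   frame_duration_ms = 20,
                                   measurement_id = "m1", sample_id = "s1",
                                   integration_time_ms = frame_duration_ms,
                                   laser_power_mw = 10,
                                   normalised = FALSE, anomalous = NA) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.matrix(intensities)
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (nrow(intensities) != length(wavelengths)) {
    stop("intensity matrix must have one row per wavelength")
  }
  if (ncol(intensities) < 1) stop("series needs at least one frame")
  stop_if_not_scalar_pos(frame_duration_ms, "frame_duration_ms")
  stop_if_not_scalar_pos(integration_time_ms, "integration_time_ms")
  stop_if_not_scalar_pos(laser_power_mw, "laser_power_mw")
  dimnames(intensities) <- NULL
  structure(
    list(wavelengths = wavelengths, intensities = intensities,
         frame_duration_ms = frame_duration_ms,
         measurement_id = as.character(measurement_id),
         sample_id = as.character(sample_id),
         integration_time_ms = integration_time_ms,
         laser_power_mw = laser_power_mw,
         normalised = isTRUE(normalised),
         anomalous = anomalous),
    class = "vs_series")
}

#' @export
print.vs_series <- function(x, ...) {
  cat(sprintf(
    "<vs_series> %s (sample %s): %d frames x %g ms, %d wavelengths%s\n",
    x$measurement_id, x$sample_id, ncol(x$intensities), x$frame_duration_ms,
    length(x$wavelengths), if (x$normalised) ", normalised" else ""))
  invisible(x)
}

#' Number of frames in a series
#' @param series A `vs_series`.
#' @export
n_frames <- function(series) ncol(series$intensities)

#' Nominal frame timestamps (interval midpoints)
#'
#' Frame `k` (0-based) covers `[k*d, (k+1)*d)` ms; its nominal time is the
#' midpoint `(k + 0.5)*d`, so a default 500-frame series spans 10 ms to
#' 9990 ms.
#'
#' @param series A `vs_series`.
#' @return Numeric vector of midpoint times, ms.
#' @export
frame_times <- function(series) {
  (seq_len(n_frames(series)) - 0.5) * series$frame_duration_ms
}

#' Extract one frame of a series as a spectrum
#'
#' @param series A `vs_series`.
#' @param frame 0-based frame index (frame 0 is the first 20 ms of
#'   excitation).
#' @return A `vs_spectrum` inheriting the series acquisition metadata.
#' @export
get_frame <- function(series, frame) {
  if (frame < 0 || frame >= n_frames(series)) {
    stop("frame ", frame, " out of range [0, ", n_frames(series) - 1, "]")
  }
  new_spectrum(series$wavelengths, series$intensities[, frame + 1L],
               integration_time_ms = series$integration_time_ms,
               laser_power_mw = series$laser_power_mw,
               normalised = series$normalised)
}

#' Construct a sample record
#'
#' Links a stained bacterial sample to its replicate optrode measurements,
#' its experiment (the grouping key for group K-fold cross-validation), its
#' nominal total-concentration class and the reference percent-live value
#' (measured by flow cytometry in the original workflow).
#'
#' @param sample_id Opaque identifier.
#' @param experiment_id Experiment the sample was measured in; samples from
#'   one experiment share correlated conditions and are always held out
#'   together during cross-validation.
#' @param concentration_class Nominal total concentration, bacteria/mL
#'   (e.g. `1e8` or `1e7`).
#' @param f_live_ref Reference percent live, in `[0, 100]`.
#' @param measurement_ids Character vector of measurement identifiers.
#' @return An object of class `"vs_sample"`.
#' @export
new_sample_record <- function(sample_id, experiment_id, concentration_class,
                              f_live_ref, measurement_ids) {
  f_live_ref <- as.numeric(f_live_ref)
  concentration_class <- as.numeric(concentration_class)
  if (!is.numeric(f_live_ref) || length(f_live_ref) != 1L ||
      is.na(f_live_ref) || f_live_ref < 0 || f_live_ref > 100) {
    stop("f_live_ref must be a single value in [0, 100]")
  }
  stop_if_not_scalar_pos(concentration_class, "concentration_class")
  structure(
    list(sample_id = as.character(sample_id),
         experiment_id = as.character(experiment_id),
         concentration_class = concentration_class,
         f_live_ref = f_live_ref,
         measurement_ids = as.character(measurement_ids)),
    class = "vs_sample")
}

#' @export
print.vs_sample <- function(x, ...) {
  cat(sprintf("<vs_sample> %s (exp %s, %s/mL): %.1f%% live, %d measurements\n",
              x$sample_id, x$experiment_id, class_key(x$concentration_class),
              x$f_live_ref, length(x$measurement_ids)))
  invisible(x)
}

# named lookup list from a list of vs_sample records
sample_lookup <- function(samples) {
  stats::setNames(samples, vapply(samples, `[[`, "", "sample_id"))
}
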