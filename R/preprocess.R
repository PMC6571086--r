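#' Pre-processing configuration
#'
#' Bundles the parameters of the fixed pre-processing chain:
#' dark removal -> normalisation -> background subtraction -> anomaly
#' screen -> frame selection -> (optional summing) -> mean-centring.
#'
#' @param reference_integration_time_ms Integration time all spectra are
#'   rescaled to, ms (default 8).
#' @param reference_power_mw Laser power all spectra are rescaled to, mW
#'   (default 10).
#' @param dark Dark spectrum to subtract before normalisation: a scalar, a
#'   vector on the grid, or a `vs_spectrum` (default 0; synthetic data
#'   carry no dark offset).
#' @param background Mean saline background `vs_spectrum` to subtract after
#'   normalisation, or `NULL` for none.
#' @param anomaly_threshold Multiple of the MAD beyond which a replicate's
#'   frame-0 full-window integral is flagged anomalous (default 3).
#' @param two_rep_factor With exactly two replicates no MAD is defined; if
#'   their integrals differ by more than this factor the pair is reported
#'   for manual review (neither is auto-flagged).
#' @param timepoints Time points (ms) at which frames are selected for
#'   model features; must include 0 (the first 20 ms spectrum).
#' @return An object of class `"vs_preprocess_config"`.
#' @export
preprocess_config <- function(reference_integration_time_ms = 8,
                              reference_power_mw = 10,
                              dark = 0, background = NULL,
                              anomaly_threshold = 3, two_rep_factor = 1.5,
                              timepoints = 0) {
  stop_if_not_scalar_pos(reference_integration_time_ms,
                         "reference_integration_time_ms")
  stop_if_not_scalar_pos(reference_power_mw, "reference_power_mw")
  if (anomaly_threshold <= 0) stop("anomaly_threshold must be > 0")
  structure(list(reference_integration_time_ms = reference_integration_time_ms,
                 reference_power_mw = reference_power_mw,
                 dark = dark, background = background,
                 anomaly_threshold = anomaly_threshold,
                 two_rep_factor = two_rep_factor,
                 timepoints = timepoints),
            class = "vs_preprocess_config")
}

normalisation_factor <- function(integration_time_ms, laser_power_mw, config) {
  (config$reference_integration_time_ms / integration_time_ms) *
    (config$reference_power_mw / laser_power_mw)
}

#' Normalise a spectrum to the reference acquisition conditions
#'
#' Rescales intensities by
#' `(t_ref / t_int) * (P_ref / P)` so that spectra acquired with different
#' integration times and laser powers are directly comparable. Dark noise
#' must already have been removed (the scaling is only valid for
#' dark-corrected counts). Normalising twice is an error.
#'
#' @param s A `vs_spectrum`.
#' @param config A [preprocess_config()].
#' @return The normalised `vs_spectrum` (integration time and power set to
#'   the reference values, `normalised = TRUE`).
#' @export
normalize_spectrum <- function(s, config = preprocess_config()) {
  if (s$normalised) stop("spectrum is already normalised")
  f <- normalisation_factor(s$integration_time_ms, s$laser_power_mw, config)
  new_spectrum(s$wavelengths, s$intensities * f,
               integration_time_ms = config$reference_integration_time_ms,
               laser_power_mw = config$reference_power_mw,
               normalised = TRUE)
}

#' Normalise every frame of a measurement series
#'
#' @param series A `vs_series`.
#' @param config A [preprocess_config()].
#' @return The normalised `vs_series`.
#' @export
normalize_series <- function(series, config = preprocess_config()) {
  if (series$normalised) stop("series is already normalised")
  f <- normalisation_factor(series$integration_time_ms,
                            series$laser_power_mw, config)
  series$intensities <- series$intensities * f
  series$integration_time_ms <- config$reference_integration_time_ms
  series$laser_power_mw <- config$reference_power_mw
  series$normalised <- TRUE
  series
}

#' Remove the instrument dark offset
#'
#' @param x A `vs_spectrum` or `vs_series`.
#' @param dark Scalar offset, vector on the grid, or `vs_spectrum`.
#' @return `x` with the dark contribution subtracted.
#' @export
remove_dark <- function(x, dark = 0) {
  d <- if (inherits(dark, "vs_spectrum")) dark$intensities else dark
  if (inherits(x, "vs_spectrum")) {
    if (length(d) != 1 && length(d) != length(x$wavelengths)) {
      stop("dark spectrum length does not match the grid")
    }
    x$intensities <- x$intensities - d
  } else if (inherits(x, "vs_series")) {
    if (length(d) != 1 && length(d) != length(x$wavelengths)) {
      stop("dark spectrum length does not match the grid")
    }
    x$intensities <- x$intensities - d  # column-wise recycling over frames
  } else stop("x must be a vs_spectrum or vs_series")
  x
}

#' Subtract the averaged saline background spectrum
#'
#' Elementwise difference on a shared grid. Both inputs must already be
#' normalised so counts are on the same scale. Negative residual
#' intensities are kept (clipping would bias window integrals), but the
#' result is flagged (attribute `"negative_integral"`) when the full-window
#' integral goes negative.
#'
#' @param x A `vs_spectrum` or `vs_series`.
#' @param background A `vs_spectrum` on the same grid (normalised).
#' @return `x` minus the background.
#' @export
subtract_background <- function(x, background) {
  if (!inherits(background, "vs_spectrum")) stop("background must be a vs_spectrum")
  if (!background$normalised) stop("background must be normalised first")
  if (!isTRUE(all.equal(x$wavelengths, background$wavelengths))) {
    stop("wavelength grids of spectrum and background differ")
  }
  if (!x$normalised) stop("normalise before background subtraction")
  full <- range(x$wavelengths)
  tw <- trapz_weights(x$wavelengths, full)
  if (inherits(x, "vs_spectrum")) {
    x$intensities <- x$intensities - background$intensities
    neg <- sum(tw$weights * x$intensities[tw$idx]) < 0
  } else if (inherits(x, "vs_series")) {
    x$intensities <- x$intensities - background$intensities
    neg <- sum(tw$weights * rowMeans(x$intensities)[tw$idx]) < 0
  } else stop("x must be a vs_spectrum or vs_series")
  attr(x, "negative_integral") <- neg
  x
}

#' Apply the per-measurement pre-processing chain
#'
#' Dark removal, normalisation and (if configured) background subtraction,
#' in that fixed order.
#'
#' @param series A raw `vs_series`.
#' @param config A [preprocess_config()].
#' @return The processed `vs_series`.
#' @export
preprocess_series <- function(series, config = preprocess_config()) {
  series <- remove_dark(series, config$dark)
  series <- normalize_series(series, config)
  if (!is.null(config$background)) {
    series <- subtract_background(series, config$background)
  }
  series
}

#' Screen replicate measurements for anomalous intensity
#'
#' Replicates of one sample should have comparable overall intensity; a
#' measurement whose frame-0 full-window integral deviates from the
#' replicate median by more than `anomaly_threshold` MADs is flagged.
#' Degenerate cases: a single measurement is never flagged; with exactly
#' two replicates no robust spread exists, so a pair differing by more than
#' `two_rep_factor` is reported for manual review but neither is flagged
#' automatically. Flags are advisory; exclusion is the caller's decision.
#'
#' @param measurements List of `vs_series` (any mix of samples).
#' @param config A [preprocess_config()].
#' @return Data frame with `measurement_id`, `sample_id`, `integral`,
#'   `flagged`, `reason`.
#' @export
flag_anomalous <- function(measurements, config = preprocess_config()) {
  ids <- vapply(measurements, `[[`, "", "measurement_id")
  sids <- vapply(measurements, `[[`, "", "sample_id")
  integral <- vapply(measurements, function(m) {
    tw <- trapz_weights(m$wavelengths, range(m$wavelengths))
    sum(tw$weights * m$intensities[tw$idx, 1])
  }, 0)
  flagged <- logical(length(ids))
  reason <- character(length(ids))
  for (s in unique(sids)) {
    i <- which(sids == s)
    if (length(i) == 1) next
    if (length(i) == 2) {
      x <- integral[i]
      lo <- min(abs(x)); hi <- max(abs(x))
      if (lo == 0 || hi / lo > config$two_rep_factor) {
        reason[i] <- "two-replicate disagreement: manual review"
      }
      next
    }
    med <- stats::median(integral[i])
    spread <- stats::mad(integral[i])
    dev <- abs(integral[i] - med)
    bad <- dev > config$anomaly_threshold * spread
    flagged[i][bad] <- TRUE
    reason[i][bad] <- sprintf("frame-0 integral %.3g vs replicate median %.3g (> %g MAD)",
                              integral[i][bad], med, config$anomaly_threshold)
  }
  data.frame(measurement_id = ids, sample_id = sids, integral = integral,
             flagged = flagged, reason = reason, stringsAsFactors = FALSE)
}

#' Map a time point to its nearest frame
#'
#' Frames carry midpoint timestamps; the frame whose midpoint is nearest to
#' the requested time is chosen, with ties broken toward the earlier frame
#' (less photobleached). Time 0 maps to frame 0.
#'
#' @param timepoint_ms Time point, ms, in `[0, n_frames * frame_duration)`.
#' @param frame_duration_ms Frame duration, ms.
#' @param n_frames Number of frames in the series.
#' @return 0-based frame index.
#' @export
frame_for_timepoint <- function(timepoint_ms, frame_duration_ms, n_frames) {
  if (timepoint_ms < 0 || timepoint_ms >= n_frames * frame_duration_ms) {
    stop("timepoint ", timepoint_ms, " ms is outside the measurement duration")
  }
  k0 <- floor(timepoint_ms / frame_duration_ms)
  candidates <- unique(pmin(pmax(c(k0 - 1, k0, k0 + 1), 0), n_frames - 1))
  mid <- (candidates + 0.5) * frame_duration_ms
  d <- abs(mid - timepoint_ms)
  best <- candidates[d == min(d)]
  min(best)  # tie -> earlier frame
}

#' Select frames of a series at given time points
#'
#' Returns, for each time point, the frame with the nearest midpoint
#' timestamp (ties toward the earlier frame). At most 5 frames may be
#' selected from a series.
#'
#' @param series A `vs_series`.
#' @param timepoints Numeric vector of times, ms, each within the
#'   measurement duration.
#' @return A list of `vs_spectrum`, one per time point, in input order.
#' @export
select_frames <- function(series, timepoints) {
  if (length(timepoints) < 1) stop("at least one timepoint is required")
  if (length(timepoints) > 5) {
    stop("at most 5 frames may be selected from one measurement")
  }
  idx <- vapply(timepoints, frame_for_timepoint,
                0, series$frame_duration_ms, n_frames(series))
  lapply(idx, function(k) get_frame(series, k))
}

#' Sum a contiguous range of frames
#'
#' Elementwise sum of the frames in `frame_range` (0-based, inclusive).
#' The returned spectrum records the summed effective integration time so
#' later normalisation semantics stay consistent.
#'
#' @param series A `vs_series`.
#' @param frame_range Length-2 vector `c(first, last)`, 0-based inclusive.
#' @return A `vs_spectrum`.
#' @export
sum_frames <- function(series, frame_range) {
  if (length(frame_range) != 2) stop("frame_range must be c(first, last)")
  first <- frame_range[1]; last <- frame_range[2]
  if (first > last) stop("empty frame range")
  if (first < 0 || last >= n_frames(series)) {
    stop("frame range out of bounds [0, ", n_frames(series) - 1, "]")
  }
  cols <- (first:last) + 1L
  sum_int <- rowSums(series$intensities[, cols, drop = FALSE])
  s <- new_spectrum(series$wavelengths, sum_int,
                    integration_time_ms = series$integration_time_ms * length(cols),
                    laser_power_mw = series$laser_power_mw,
                    normalised = series$normalised)
  s
}

#' Mean-centre spectra against a training mean
#'
#' Subtracts the training-set mean spectrum from each row. Test data must
#' always be centred with the training means, never their own.
#'
#' @param x Numeric matrix (rows = spectra) or a single numeric vector.
#' @param center Training mean spectrum (numeric vector of matching
#'   length).
#' @return Centred matrix or vector of the same shape.
#' @export
mean_center <- function(x, center) {
  if (is.matrix(x)) {
    if (ncol(x) != length(center)) stop("grid mismatch in mean_center")
    sweep(x, 2, center)
  } else {
    if (length(x) != length(center)) stop("grid mismatch in mean_center")
    x - center
  }
}

#' Per-timepoint training mean spectra
#'
#' @param measurements List of preprocessed `vs_series` (the training
#'   set).
#' @param timepoints Time points, ms.
#' @return Matrix with one row per time point and one column per
#'   wavelength.
#' @export
compute_timepoint_means <- function(measurements, timepoints) {
  if (length(measurements) == 0) stop("no measurements supplied")
  wl <- measurements[[1]]$wavelengths
  means <- matrix(0, length(timepoints), length(wl))
  for (m in measurements) {
    if (!isTRUE(all.equal(m$wavelengths, wl))) stop("inconsistent wavelength grids")
    fr <- select_frames(m, timepoints)
    for (j in seq_along(fr)) means[j, ] <- means[j, ] + fr[[j]]$intensities
  }
  means / length(measurements)
}
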