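#' Integrated intensity over an emission window
#'
#' Trapezoidal integral of the intensity over a closed wavelength window on
#' the native grid (no resampling). The default windows used throughout the
#' package are 509-529 nm for SYTO 9 and 609-629 nm for PI, the emission
#' peaks of the two dyes.
#'
#' @param s A `vs_spectrum`, or a numeric intensity vector (then
#'   `wavelengths` must be given).
#' @param window Length-2 numeric `c(lower, upper)` nm, inside the grid.
#' @param wavelengths Grid for a bare intensity vector.
#' @return Scalar integrated intensity.
#' @export
integrated_intensity <- function(s, window, wavelengths = NULL) {
  if (inherits(s, "vs_spectrum")) {
    wavelengths <- s$wavelengths
    intensities <- s$intensities
  } else {
    if (is.null(wavelengths)) stop("wavelengths required for a bare vector")
    intensities <- s
  }
  tw <- trapz_weights(wavelengths, window)
  sum(tw$weights * intensities[tw$idx])
}

#' SYTO 9 and PI window signals of a spectrum
#'
#' @param s A `vs_spectrum`.
#' @param syto9_window,pi_window Integration windows, nm.
#' @return List with `syto9` and `pi` integrated intensities and the
#'   windows used.
#' @export
dye_signals <- function(s, syto9_window = c(509, 529),
                        pi_window = c(609, 629)) {
  list(syto9 = integrated_intensity(s, syto9_window),
       pi = integrated_intensity(s, pi_window),
       syto9_window = syto9_window, pi_window = pi_window)
}

signal_pair <- function(syto9, pi) {
  if (is.list(syto9) && missing(pi)) {
    pi <- syto9$pi; syto9 <- syto9$syto9
  }
  c(syto9 = syto9, pi = pi)
}

#' SYTO 9:PI dye ratio
#'
#' The classical viability proxy `R = SYTO9 / PI`: the ratio of the
#' integrated SYTO 9 and PI emission intensities, expected (under the kit's
#' model) to grow with the percentage of live bacteria. Note that `R` is
#' live:dead, not live:total, so it is intrinsically nonlinear in percent
#' live.
#'
#' @param syto9 Integrated SYTO 9 intensity, or the list returned by
#'   [dye_signals()].
#' @param pi Integrated PI intensity (> 0).
#' @return The ratio.
#' @export
dye_ratio <- function(syto9, pi) {
  p <- signal_pair(syto9, pi)
  if (p[["pi"]] <= 0) stop("dye ratio undefined: PI integral must be > 0")
  p[["syto9"]] / p[["pi"]]
}

#' Adjusted dye ratio (percent-live scale)
#'
#' `100 * R / (1 + R)` with `R = SYTO9 / PI`. Treating the PI signal as
#' proportional to the dead count and the SYTO 9 signal as proportional to
#' the live count, this quantity is linear in percent live (and equals it
#' exactly under ideal staining). For small `R` it reduces to `100 * R`,
#' i.e. the plain dye ratio up to scale. The boundary `R -> Inf` (no PI
#' signal, positive SYTO 9 signal) returns 100 by continuity; a negative PI
#' integral is an error.
#'
#' @inheritParams dye_ratio
#' @return Percent-scale value; in `(0, 100)` for finite positive `R`.
#' @export
adjusted_dye_ratio <- function(syto9, pi) {
  p <- signal_pair(syto9, pi)
  if (p[["pi"]] < 0) stop("adjusted dye ratio undefined: PI integral < 0")
  if (p[["pi"]] == 0) {
    if (p[["syto9"]] > 0) return(100)  # continuous limit R -> Inf
    stop("adjusted dye ratio undefined: both window integrals are 0")
  }
  r <- p[["syto9"]] / p[["pi"]]
  100 * r / (1 + r)
}

#' Linear calibration of a ratio statistic against reference percent live
#'
#' Ordinary least squares of the reference percent-live values on the ratio
#' statistic. The returned `r_squared` is `1 - SS_res / SS_tot`; for an OLS
#' fit on its own training data this is non-negative, but the same
#' definition applied to fixed coefficients on new data (see
#' [regression_metrics()]) can be negative, meaning the line predicts worse
#' than the mean.
#'
#' @param values Ratio statistic per sample.
#' @param f_live_refs Reference percent live per sample.
#' @return List with `slope`, `intercept`, `r_squared`, `std_error`
#'   (residual standard error) and `fitted`.
#' @export
fit_ratio_calibration <- function(values, f_live_refs) {
  if (length(values) != length(f_live_refs)) stop("length mismatch")
  if (length(values) < 3) stop("at least 3 samples are required")
  if (stats::var(values) == 0) stop("zero variance in the ratio values")
  fit <- stats::lm(f_live_refs ~ values)
  sm <- suppressWarnings(summary(fit))  # perfect collinear fits warn
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       std_error = sm$sigma,
       fitted = unname(stats::fitted(fit)))
}

#' Per-sample dye-ratio table
#'
#' Computes the frame-0 window signals of every measurement, averages them
#' over the replicates of each sample, and reports both ratio statistics.
#' Samples whose mean PI integral is not positive get `NA` ratios.
#'
#' @param measurements List of preprocessed `vs_series`.
#' @param samples List of `vs_sample` records.
#' @param syto9_window,pi_window Integration windows, nm.
#' @return Data frame with one row per sample: `sample_id`, `f_live_ref`,
#'   `syto9`, `pi`, `dye_ratio`, `adjusted_dye_ratio`, `n_measurements`.
#' @export
sample_ratio_table <- function(measurements, samples,
                               syto9_window = c(509, 529),
                               pi_window = c(609, 629)) {
  by_sample <- split(measurements,
                     vapply(measurements, `[[`, "", "sample_id"))
  rows <- lapply(samples, function(sr) {
    ms <- by_sample[[sr$sample_id]]
    if (is.null(ms)) stop("sample ", sr$sample_id, " has no measurements")
    sig <- vapply(ms, function(m) {
      s0 <- get_frame(m, 0)
      c(integrated_intensity(s0, syto9_window),
        integrated_intensity(s0, pi_window))
    }, numeric(2))
    syto9 <- mean(sig[1, ]); pi <- mean(sig[2, ])
    data.frame(sample_id = sr$sample_id, f_live_ref = sr$f_live_ref,
               syto9 = syto9, pi = pi,
               dye_ratio = if (pi > 0) syto9 / pi else NA_real_,
               adjusted_dye_ratio =
                 if (pi > 0 || syto9 > 0) adjusted_dye_ratio(syto9, max(pi, 0))
                 else NA_real_,
               n_measurements = length(ms), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
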