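#' Extract a photobleaching decay trace from a measurement
#'
#' Integrates each frame over a dye emission window (trapezoid rule) and
#' returns the resulting intensity-versus-time trace; times are the frame
#' midpoints, so a default 500-frame series yields 500 points from 10 to
#' 9990 ms.
#'
#' @param series A preprocessed `vs_series`.
#' @param window Integration window `c(lower, upper)` nm, e.g.
#'   `c(509, 529)` for SYTO 9 or `c(609, 629)` for PI.
#' @return List with `times_ms` and `intensities`.
#' @export
extract_decay_trace <- function(series, window) {
  tw <- trapz_weights(series$wavelengths, window)
  trace <- as.vector(tw$weights %*% series$intensities[tw$idx, , drop = FALSE])
  list(times_ms = frame_times(series), intensities = trace)
}

#' Fit a double-exponential photobleaching decay
#'
#' Least-squares fit of `I(t) = A1 exp(-t/tau1) + A2 exp(-t/tau2)` with
#' non-negative amplitudes and positive time constants. Double-exponential
#' fits are initialisation-sensitive, so a deterministic multi-start is
#' used: time-constant starts from the crossed pairs of `{0.2, 1, 5}` s and
#' amplitudes split equally from the initial intensity; the converged fit
#' with the lowest residual sum of squares wins. Parameters are returned in
#' the canonical order `tau1 <= tau2`. No constant offset term is included
#' (background subtraction is assumed to have removed offsets); set
#' `offset = TRUE` to add one.
#'
#' @param times_ms Times, ms (>= 8 points).
#' @param intensities Trace intensities; the initial intensity must be
#'   positive.
#' @param offset Include an additive constant term (default `FALSE`).
#' @return An object of class `"photobleach_fit"`: `A1`, `tau1`, `A2`,
#'   `tau2`, optional `C`, `residual_norm`, `n`.
#' @export
fit_double_exponential <- function(times_ms, intensities, offset = FALSE) {
  if (length(times_ms) != length(intensities)) stop("length mismatch")
  if (length(times_ms) < 8) stop("at least 8 points are required")
  i0 <- intensities[which.min(times_ms)]
  if (!is.finite(i0) || i0 <= 0) stop("initial intensity must be positive")
  df <- data.frame(t = times_ms, y = intensities)
  tau_starts <- c(200, 1000, 5000)
  starts <- list()
  for (t1 in tau_starts) for (t2 in tau_starts) {
    if (t1 <= t2) starts[[length(starts) + 1L]] <- c(t1, t2)
  }
  best <- NULL
  for (st in starts) {
    start <- list(A1 = i0 / 2, tau1 = st[1], A2 = i0 / 2, tau2 = st[2])
    lower <- c(A1 = 0, tau1 = 1e-6, A2 = 0, tau2 = 1e-6)
    if (offset) { start$C <- 0; lower <- c(lower, C = -Inf) }
    form <- if (offset) y ~ A1 * exp(-t / tau1) + A2 * exp(-t / tau2) + C
            else y ~ A1 * exp(-t / tau1) + A2 * exp(-t / tau2)
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        form, data = df, start = start, lower = lower,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) stop("double-exponential fit failed to converge from all starts")
  p <- stats::coef(best$fit)
  if (p[["tau1"]] > p[["tau2"]]) {
    p[c("A1", "tau1", "A2", "tau2")] <- p[c("A2", "tau2", "A1", "tau1")]
  }
  structure(
    list(A1 = unname(p[["A1"]]), tau1 = unname(p[["tau1"]]),
         A2 = unname(p[["A2"]]), tau2 = unname(p[["tau2"]]),
         C = if (offset) unname(p[["C"]]) else 0,
         residual_norm = sqrt(best$sse), n = length(times_ms)),
    class = "photobleach_fit")
}

#' @export
print.photobleach_fit <- function(x, ...) {
  cat(sprintf(
    "<photobleach_fit> A1=%.4g tau1=%.4g ms, A2=%.4g tau2=%.4g ms, half-life %.1f ms\n",
    x$A1, x$tau1, x$A2, x$tau2, half_life(x)))
  invisible(x)
}

# closed-form half-life of A1 exp(-t/tau1) + A2 exp(-t/tau2), by bracketed
# root finding on the (strictly decreasing) curve
double_exp_half_life <- function(A1, tau1, A2, tau2) {
  i0 <- A1 + A2
  if (i0 <= 0) stop("initial intensity is zero; half-life undefined")
  f <- function(t) A1 * exp(-t / tau1) + A2 * exp(-t / tau2) - i0 / 2
  upper <- 2 * max(tau1, tau2)
  while (f(upper) > 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-9)$root
}

#' Photobleaching half-life of a fitted decay
#'
#' The unique time at which the fitted curve falls to half its initial
#' value, found by bracketed root finding (the curve is strictly
#' decreasing, so the root is unique). For a single exponential this is
#' `tau * ln 2`; for a double exponential it lies between
#' `min(tau) * ln 2` and `max(tau) * ln 2`.
#'
#' @param fit A `photobleach_fit`, or any list with `A1`, `tau1`, `A2`,
#'   `tau2`.
#' @return Half-life, ms.
#' @export
half_life <- function(fit) {
  double_exp_half_life(fit$A1, fit$tau1, fit$A2, fit$tau2)
}

#' Compare two groups of photobleaching half-lives
#'
#' Two-sided Welch (unequal-variance) two-sample t-test, used to ask
#' whether the half-life of a dye differs between its mostly bound and
#' mostly unbound states (or between dyes).
#'
#' @param group_a,group_b Numeric vectors of half-lives (each n >= 2).
#' @return List with `t`, `p_value`, `df`, group means.
#' @export
compare_half_lives <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 half-lives")
  }
  res <- tryCatch(
    stats::t.test(group_a, group_b, var.equal = FALSE),
    error = function(e) {
      stop("t-test failed (", conditionMessage(e),
           "); zero-variance groups cannot be compared - ",
           "check that the half-lives were fitted per measurement")
    })
  list(t = unname(res$statistic), p_value = res$p.value,
       df = unname(res$parameter),
       mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Half-life summary table for the four dye/state pools
#'
#' Reproduces the half-life bookkeeping of the calibration workflow: in
#' dual-stained live samples SYTO 9 is mostly bound and PI mostly unbound,
#' so their traces estimate the mB-SYTO9 and mU-PI half-lives; dual-stained
#' dead samples conversely give mU-SYTO9 and mB-PI. Each measurement's
#' window trace is fitted separately and the per-measurement half-lives are
#' averaged (standard error = sd / sqrt(n)).
#'
#' @param measurements List of preprocessed `vs_series`.
#' @param samples List of `vs_sample`.
#' @param live_threshold Reference percent live at or above which a sample
#'   counts as "live" (default 95).
#' @param dead_threshold Reference percent live at or below which a sample
#'   counts as "dead" (default 5).
#' @param syto9_window,pi_window Integration windows, nm.
#' @return Data frame with `dye`, `state`, `half_life_ms`, `se_ms`, `n`,
#'   plus a `"fits"` attribute holding the per-measurement half-lives.
#' @export
half_life_table <- function(measurements, samples,
                            live_threshold = 95, dead_threshold = 5,
                            syto9_window = c(509, 529),
                            pi_window = c(609, 629)) {
  lk <- sample_lookup(samples)
  refs <- vapply(measurements,
                 function(m) lk[[m$sample_id]]$f_live_ref, 0)
  pools <- list(
    list(dye = "SYTO9", state = "mB", live = TRUE, window = syto9_window),
    list(dye = "SYTO9", state = "mU", live = FALSE, window = syto9_window),
    list(dye = "PI", state = "mB", live = FALSE, window = pi_window),
    list(dye = "PI", state = "mU", live = TRUE, window = pi_window))
  per_pool <- list()
  rows <- lapply(pools, function(p) {
    use <- if (p$live) refs >= live_threshold else refs <= dead_threshold
    hl <- vapply(measurements[use], function(m) {
      tr <- extract_decay_trace(m, p$window)
      half_life(fit_double_exponential(tr$times_ms, tr$intensities))
    }, 0)
    per_pool[[paste(p$state, p$dye, sep = "_")]] <<- hl
    data.frame(dye = p$dye, state = p$state,
               half_life_ms = mean(hl),
               se_ms = stats::sd(hl) / sqrt(length(hl)),
               n = length(hl), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- per_pool
  out
}
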