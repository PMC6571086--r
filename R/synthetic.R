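#' Double-exponential photobleaching curve
#'
#' Normalised bleaching factor
#' `b(t) = (A1 exp(-t/tau1) + A2 exp(-t/tau2)) / (A1 + A2)`, so `b(0) = 1`
#' and `b` is non-increasing for non-negative amplitudes.
#'
#' @param params Named numeric with `A1`, `tau1`, `A2`, `tau2` (amplitudes
#'   >= 0, time constants in ms > 0).
#' @param t Times, ms.
#' @return Numeric vector of bleaching factors in `(0, 1]`.
#' @export
bleach_curve <- function(params, t) {
  A1 <- params[["A1"]]; A2 <- params[["A2"]]
  tau1 <- params[["tau1"]]; tau2 <- params[["tau2"]]
  if (A1 < 0 || A2 < 0 || A1 + A2 <= 0) stop("amplitudes must be >= 0 and not both 0")
  if (tau1 <= 0 || tau2 <= 0) stop("time constants must be > 0")
  (A1 * exp(-t / tau1) + A2 * exp(-t / tau2)) / (A1 + A2)
}

#' Double-exponential parameters with a prescribed half-life
#'
#' Builds `(A1, tau1, A2, tau2)` whose decay reaches half its initial value
#' exactly at `target_half_life_ms`. The shape is fixed by the amplitude
#' split and the tau ratio; both time constants are then rescaled, which
#' rescales the half-life linearly, so the target is hit to floating-point
#' accuracy.
#'
#' @param target_half_life_ms Desired half-life, ms.
#' @param tau_ratio Ratio `tau2 / tau1` (> = 1) of the slow to fast
#'   component.
#' @param a1 Fractional amplitude of the fast component, in `[0, 1]`.
#' @return Named numeric vector `c(A1, tau1, A2, tau2)`.
#' @export
bleach_params_for_half_life <- function(target_half_life_ms, tau_ratio = 3,
                                        a1 = 0.6) {
  stop_if_not_scalar_pos(target_half_life_ms, "target_half_life_ms")
  if (tau_ratio < 1) stop("tau_ratio must be >= 1")
  if (a1 < 0 || a1 > 1) stop("a1 must be in [0, 1]")
  base <- c(A1 = a1, tau1 = 1, A2 = 1 - a1, tau2 = tau_ratio)
  h0 <- double_exp_half_life(base[["A1"]], base[["tau1"]],
                             base[["A2"]], base[["tau2"]])
  scale <- target_half_life_ms / h0
  c(A1 = a1, tau1 = scale, A2 = 1 - a1, tau2 = tau_ratio * scale)
}

#' Define one emission component of the generator
#'
#' A component is one (dye, binding state) pool: mostly bound (mB) or
#' mostly unbound (mU) SYTO 9 or propidium iodide. Its emission is a sum of
#' Gaussian peaks (unit peak amplitude after scaling) and it photobleaches
#' along its own double-exponential decay. Gaussians are truncated at
#' +/- 6 sigma, giving compact support: the SYTO 9 and PI emission bands
#' then do not overlap each other's integration windows.
#'
#' @param dye `"SYTO9"` or `"PI"`.
#' @param state `"bound"` or `"unbound"`.
#' @param peak_centers Peak centre(s), nm.
#' @param peak_widths Gaussian sigma(s), nm (> 0).
#' @param relative_weights Relative peak weights (>= 0); recycled.
#' @param target_half_life_ms Photobleaching half-life the bleach curve
#'   must reproduce (within 1 ms; checked).
#' @param bleach_params Optional explicit double-exponential parameters;
#'   defaults to [bleach_params_for_half_life()] of the target.
#' @return An object of class `"vs_component"`.
#' @export
emission_component <- function(dye, state, peak_centers, peak_widths,
                               relative_weights = 1,
                               target_half_life_ms = 1000,
                               bleach_params = NULL) {
  dye <- match.arg(dye, c("SYTO9", "PI"))
  state <- match.arg(state, c("bound", "unbound"))
  if (any(peak_widths <= 0)) stop("peak widths must be > 0")
  if (any(relative_weights < 0)) stop("peak weights must be >= 0")
  bleach_params <- bleach_params %||%
    bleach_params_for_half_life(target_half_life_ms)
  achieved <- double_exp_half_life(bleach_params[["A1"]], bleach_params[["tau1"]],
                                   bleach_params[["A2"]], bleach_params[["tau2"]])
  if (abs(achieved - target_half_life_ms) > 1) {
    stop(sprintf("bleach_params give half-life %.2f ms, target %.2f ms (> 1 ms off)",
                 achieved, target_half_life_ms))
  }
  structure(
    list(dye = dye, state = state,
         peak_centers = as.numeric(peak_centers),
         peak_widths = rep_len(as.numeric(peak_widths), length(peak_centers)),
         relative_weights = rep_len(as.numeric(relative_weights),
                                    length(peak_centers)),
         bleach_params = bleach_params,
         target_half_life_ms = target_half_life_ms),
    class = "vs_component")
}

#' Unit-amplitude emission spectrum of a component
#'
#' Sum of truncated Gaussians on the supplied grid, rescaled so the maximum
#' is 1 (an all-zero-weight component stays all zero).
#'
#' @param component A `vs_component`.
#' @param wavelengths Wavelength grid, nm.
#' @return Non-negative numeric vector, one value per wavelength.
#' @export
component_spectrum <- function(component, wavelengths) {
  if (any(component$peak_centers < min(wavelengths) |
          component$peak_centers > max(wavelengths))) {
    stop("peak centre outside the wavelength grid")
  }
  g <- numeric(length(wavelengths))
  for (i in seq_along(component$peak_centers)) {
    z <- (wavelengths - component$peak_centers[i]) / component$peak_widths[i]
    v <- exp(-0.5 * z^2)
    v[abs(z) > 6] <- 0  # compact support
    g <- g + component$relative_weights[i] * v
  }
  m <- max(g)
  if (m > 0) g / m else g
}

#' Generator design: the study conditions the synthetic data emulate
#'
#' Defines everything [generate_dataset()] needs: the live-fraction series
#' and concentration classes measured, how many experiments and replicate
#' measurements per sample, the staining amplitude model, the
#' photobleaching half-lives of the four dye/state pools, and the noise
#' structure (experiment-level multiplicative spread, additive dark noise,
#' signal-dependent shot-like noise, occasional anomalous measurements, and
#' reference-method error).
#'
#' The amplitude model is
#' `bound-SYTO9 = alpha1*L + alpha2*D`, `bound-PI = gamma*D + gamma_prime*L`
#' with `L`/`D` the live/dead cell abundances (in units where a 1e8/mL
#' sample has `L + D = 100`), plus fixed per-class unbound-dye amplitudes.
#' Lower concentration keeps the same amount of dye in the cuvette, so the
#' unbound amplitudes are larger relative to the bound signal in the
#' 1e7/mL class.
#'
#' `ideal_mode = TRUE` collapses the design to the ideal staining model:
#' SYTO 9 reports only live cells, PI only dead cells, with equal staining
#' efficiency, no unbound dye, identical peak shapes and bleaching for both
#' dyes, and no noise of any kind. Under that model the adjusted dye ratio
#' equals percent live exactly.
#'
#' @param live_fractions Percent-live levels measured.
#' @param concentration_classes Total concentrations, bacteria/mL.
#' @param n_experiments Experiments per class (recycled to match
#'   `concentration_classes`); experiments are the CV groups.
#' @param replicates_per_sample Optrode measurements per sample.
#' @param alpha1,alpha2 Bound-SYTO9 counts per live / dead abundance unit.
#' @param gamma,gamma_prime Bound-PI counts per dead / live abundance unit.
#' @param unbound_syto9,unbound_pi Named amplitudes of unbound dye per
#'   class key (`"1e+08"`, `"1e+07"`).
#' @param pi_enhancement Optional fractional enhancement of bound-PI
#'   emission in the presence of SYTO 9 (default 0 = off).
#' @param half_lives_ms Named target half-lives of the four pools, ms.
#' @param syto9_center,syto9_width,pi_center,pi_width Bound-pool peak
#'   parameters, nm.
#' @param unbound_width_syto9,unbound_width_pi Unbound-pool sigmas, nm.
#' @param dual_peak Include the short-wavelength bound-SYTO9 sub-peak
#'   (nucleic-acid-bound emission near 501 nm, truncated by the >= 500 nm
#'   grid).
#' @param experiment_sd Log-scale sd of the per-experiment multiplicative
#'   factor.
#' @param dark_noise_sd Additive Gaussian dark-noise sd, counts.
#' @param shot_noise_scale Signal-dependent noise sd = scale * sqrt(counts).
#' @param anomaly_prob Probability a measurement is anomalous.
#' @param anomaly_factor Multiplicative factor applied to an anomalous
#'   measurement.
#' @param fcm_error_sd Gaussian sd of the reference percent-live error.
#' @param wavelengths Wavelength grid, nm.
#' @param n_frames,frame_duration_ms Series geometry.
#' @param ideal_mode Logical; see Details.
#' @param seed Base RNG seed for [generate_dataset()].
#' @return An object of class `"vs_design"`.
#' @export
generator_design <- function(live_fractions = c(0, 2.5, 5, 10, 25, 50, 75, 100),
                             concentration_classes = c(1e8, 1e7),
                             n_experiments = c(4, 3),
                             replicates_per_sample = 3,
                             alpha1 = 12, alpha2 = 0.3,
                             gamma = 12, gamma_prime = 0.1,
                             unbound_syto9 = c("1e+08" = 60, "1e+07" = 160),
                             unbound_pi = c("1e+08" = 40, "1e+07" = 120),
                             pi_enhancement = 0,
                             half_lives_ms = c(mB_SYTO9 = 1244, mU_SYTO9 = 1472,
                                               mB_PI = 1124, mU_PI = 1084),
                             syto9_center = 519, syto9_width = 12,
                             pi_center = 619, pi_width = 14,
                             unbound_width_syto9 = 16, unbound_width_pi = 18,
                             dual_peak = TRUE,
                             experiment_sd = 0.05,
                             dark_noise_sd = 2,
                             shot_noise_scale = 0.5,
                             anomaly_prob = 0.02,
                             anomaly_factor = 3,
                             fcm_error_sd = 1.5,
                             wavelengths = 500:750,
                             n_frames = 500, frame_duration_ms = 20,
                             ideal_mode = FALSE,
                             seed = 1) {
  if (any(live_fractions < 0 | live_fractions > 100)) {
    stop("live_fractions must be in [0, 100]")
  }
  if (any(c(experiment_sd, dark_noise_sd, shot_noise_scale, fcm_error_sd) < 0)) {
    stop("all noise standard deviations must be >= 0")
  }
  if (anomaly_prob < 0 || anomaly_prob > 1) stop("anomaly_prob must be in [0, 1]")
  n_experiments <- rep_len(n_experiments, length(concentration_classes))
  design <- list(
    live_fractions = live_fractions,
    concentration_classes = concentration_classes,
    n_experiments = n_experiments,
    replicates_per_sample = replicates_per_sample,
    alpha1 = alpha1, alpha2 = alpha2, gamma = gamma, gamma_prime = gamma_prime,
    unbound_syto9 = unbound_syto9, unbound_pi = unbound_pi,
    pi_enhancement = pi_enhancement,
    half_lives_ms = half_lives_ms,
    syto9_center = syto9_center, syto9_width = syto9_width,
    pi_center = pi_center, pi_width = pi_width,
    unbound_width_syto9 = unbound_width_syto9,
    unbound_width_pi = unbound_width_pi,
    dual_peak = dual_peak,
    experiment_sd = experiment_sd, dark_noise_sd = dark_noise_sd,
    shot_noise_scale = shot_noise_scale,
    anomaly_prob = anomaly_prob, anomaly_factor = anomaly_factor,
    fcm_error_sd = fcm_error_sd,
    wavelengths = as.numeric(wavelengths),
    n_frames = n_frames, frame_duration_ms = frame_duration_ms,
    ideal_mode = isTRUE(ideal_mode),
    seed = seed)
  if (design$ideal_mode) {
    design$alpha2 <- 0
    design$gamma_prime <- 0
    design$gamma <- design$alpha1
    design$unbound_syto9[] <- 0
    design$unbound_pi[] <- 0
    design$pi_enhancement <- 0
    design$pi_width <- design$syto9_width
    design$dual_peak <- FALSE
    # one shared bleach curve so the two windows carry identical time factors
    design$half_lives_ms[] <- design$half_lives_ms[["mB_SYTO9"]]
    design$experiment_sd <- 0
    design$dark_noise_sd <- 0
    design$shot_noise_scale <- 0
    design$anomaly_prob <- 0
    design$fcm_error_sd <- 0
  }
  class(design) <- "vs_design"
  design
}

# the four emission components of a design (shapes are class-independent)
design_components <- function(design) {
  hl <- design$half_lives_ms
  syto9_centers <- design$syto9_center
  syto9_widths <- design$syto9_width
  syto9_weights <- 1
  if (design$dual_peak) {
    # bound SYTO 9 shows a subtle short-wavelength shoulder (DNA/RNA-bound
    # emission near 501 nm), truncated by the 500 nm grid edge
    syto9_centers <- c(design$syto9_center, 501)
    syto9_widths <- c(design$syto9_width, 4)
    syto9_weights <- c(1, 0.15)
  }
  list(
    mB_SYTO9 = emission_component("SYTO9", "bound", syto9_centers,
                                  syto9_widths, syto9_weights,
                                  target_half_life_ms = hl[["mB_SYTO9"]]),
    mU_SYTO9 = emission_component("SYTO9", "unbound", design$syto9_center,
                                  design$unbound_width_syto9,
                                  target_half_life_ms = hl[["mU_SYTO9"]]),
    mB_PI = emission_component("PI", "bound", design$pi_center,
                               design$pi_width,
                               target_half_life_ms = hl[["mB_PI"]]),
    mU_PI = emission_component("PI", "unbound", design$pi_center,
                               design$unbound_width_pi,
                               target_half_life_ms = hl[["mU_PI"]]))
}

# amplitude of each pool for a given live fraction and concentration class;
# abundance units: L + D = 100 for the 1e8/mL class, scaled pro rata
component_amplitudes <- function(f_live, concentration_class, design) {
  key <- class_key(concentration_class)
  if (!key %in% names(design$unbound_syto9)) {
    stop("no unbound-dye amplitudes configured for class ", key)
  }
  total <- 100 * concentration_class / 1e8
  L <- f_live / 100 * total
  D <- total - L
  c(mB_SYTO9 = design$alpha1 * L + design$alpha2 * D,
    mU_SYTO9 = unname(design$unbound_syto9[key]),
    mB_PI = (design$gamma * D + design$gamma_prime * L) *
      (1 + design$pi_enhancement),
    mU_PI = unname(design$unbound_pi[key]))
}

#' Simulate one optrode measurement
#'
#' Frame `k` of the returned series is
#' `sum_pools amplitude(f_live, class) * bleach(t_k) * shape(lambda)` plus
#' additive dark noise and signal-dependent (shot-like) noise, all scaled
#' by the experiment factor; with probability `anomaly_prob` the whole
#' measurement is additionally multiplied by `anomaly_factor` and its
#' `anomalous` field records the fact (ground truth; [generate_dataset()]
#' withholds it from the pipeline-facing records).
#'
#' @param f_live True percent live, in `[0, 100]`.
#' @param concentration_class Class, bacteria/mL.
#' @param design A `vs_design`.
#' @param experiment_factor Multiplicative experiment-level factor.
#' @param seed Optional seed; when given the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @param measurement_id,sample_id Identifiers stamped on the series.
#' @return A `vs_series` (raw counts; not normalised).
#' @export
simulate_measurement <- function(f_live, concentration_class, design,
                                 experiment_factor = 1, seed = NULL,
                                 measurement_id = "m1", sample_id = "s1") {
  if (f_live < 0 || f_live > 100) stop("f_live must be in [0, 100]")
  comps <- design_components(design)
  amps <- component_amplitudes(f_live, concentration_class, design)
  t_mid <- (seq_len(design$n_frames) - 0.5) * design$frame_duration_ms
  wl <- design$wavelengths
  signal <- matrix(0, length(wl), design$n_frames)
  for (nm in names(comps)) {
    if (amps[[nm]] == 0) next
    shape <- component_spectrum(comps[[nm]], wl)
    signal <- signal + amps[[nm]] *
      outer(shape, bleach_curve(comps[[nm]]$bleach_params, t_mid))
  }
  draw <- function() {
    n <- length(signal)
    noisy <- signal
    if (design$dark_noise_sd > 0) {
      noisy <- noisy + matrix(stats::rnorm(n, 0, design$dark_noise_sd),
                              nrow(signal))
    }
    if (design$shot_noise_scale > 0) {
      noisy <- noisy + matrix(stats::rnorm(n), nrow(signal)) *
        (design$shot_noise_scale * sqrt(pmax(signal, 0)))
    }
    anomalous <- design$anomaly_prob > 0 &&
      stats::runif(1) < design$anomaly_prob
    list(intensities = noisy * experiment_factor *
           (if (anomalous) design$anomaly_factor else 1),
         anomalous = anomalous)
  }
  res <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  new_measurement_series(wl, res$intensities,
                         frame_duration_ms = design$frame_duration_ms,
                         measurement_id = measurement_id,
                         sample_id = sample_id,
                         integration_time_ms = design$frame_duration_ms,
                         laser_power_mw = 10,
                         normalised = FALSE,
                         anomalous = res$anomalous)
}

#' Generate a full synthetic measurement dataset
#'
#' One sample per (live fraction x concentration class x experiment), each
#' measured `replicates_per_sample` times. Reference percent-live values
#' are the true fractions plus clipped Gaussian reference-method error.
#' Per-measurement RNG substreams are derived deterministically from the
#' design seed, the sample index and the replicate index, so the dataset is
#' bit-reproducible.
#'
#' @param design A `vs_design`.
#' @param id_prefix Prefix for generated identifiers (lets training and
#'   test sets coexist).
#' @return A list with `measurements` (list of `vs_series`, anomaly tags
#'   blanked), `samples` (list of `vs_sample`) and `truth` (data frame of
#'   per-measurement ground truth: true fraction, experiment factor,
#'   anomaly tag).
#' @export
generate_dataset <- function(design, id_prefix = "train") {
  measurements <- list()
  samples <- list()
  truth <- list()
  withr::with_seed(design$seed, {
    sample_index <- 0L
    for (ci in seq_along(design$concentration_classes)) {
      cls <- design$concentration_classes[ci]
      for (e in seq_len(design$n_experiments[ci])) {
        experiment_id <- sprintf("%s_%s_e%d", id_prefix, class_key(cls), e)
        exp_factor <- exp(stats::rnorm(1, 0, design$experiment_sd))
        for (f in design$live_fractions) {
          sample_index <- sample_index + 1L
          sample_id <- sprintf("%s_%s_e%d_f%05.1f", id_prefix,
                               class_key(cls), e, f)
          f_ref <- min(100, max(0, f + stats::rnorm(1, 0, design$fcm_error_sd)))
          m_ids <- character(design$replicates_per_sample)
          for (r in seq_len(design$replicates_per_sample)) {
            m_id <- sprintf("%s_m%d", sample_id, r)
            m_ids[r] <- m_id
            m <- simulate_measurement(
              f, cls, design, experiment_factor = exp_factor,
              seed = substream_seed(design$seed, sample_index, r),
              measurement_id = m_id, sample_id = sample_id)
            truth[[length(truth) + 1L]] <- data.frame(
              measurement_id = m_id, sample_id = sample_id,
              experiment_id = experiment_id, concentration_class = cls,
              true_f_live = f, f_live_ref = f_ref,
              experiment_factor = exp_factor, anomalous = m$anomalous,
              stringsAsFactors = FALSE)
            m$anomalous <- NA  # ground truth withheld from the pipeline
            measurements[[length(measurements) + 1L]] <- m
          }
          samples[[length(samples) + 1L]] <- new_sample_record(
            sample_id, experiment_id, cls, f_ref, m_ids)
        }
      }
    }
  })
  list(measurements = measurements, samples = samples,
       truth = do.call(rbind, truth))
}
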