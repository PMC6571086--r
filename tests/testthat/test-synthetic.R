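test_that("component spectra peak where specified and integrate like Gaussians", {
  wl <- 500:750
  comp <- emission_component("PI", "bound", peak_centers = 617,
                             peak_widths = 18, target_half_life_ms = 1124)
  g <- component_spectrum(comp, wl)
  expect_true(all(g >= 0))
  expect_equal(wl[which.max(g)], 617)
  expect_equal(max(g), 1)

  # quadrature oracle: closed-form area of a unit-amplitude Gaussian,
  # corrected for the +/- 6 sigma truncation
  area <- integrated_intensity(g, c(540, 694), wavelengths = wl)
  sigma <- 18
  closed_form <- sigma * sqrt(2 * pi) * (stats::pnorm(6) - stats::pnorm(-6))
  expect_equal(area, closed_form, tolerance = 1e-4)

  zero <- emission_component("PI", "bound", 617, 18, relative_weights = 0,
                             target_half_life_ms = 1124)
  expect_equal(component_spectrum(zero, wl), rep(0, length(wl)))
  expect_error(component_spectrum(
    emission_component("PI", "bound", 400, 18, target_half_life_ms = 1124), wl),
    "outside")
})

test_that("bleach parameter construction hits the target half-life", {
  for (target in c(1244, 1472, 1124, 1084)) {
    p <- bleach_params_for_half_life(target)
    b <- bleach_curve(p, c(0, target))
    expect_equal(b[1], 1)
    expect_equal(b[2], 0.5, tolerance = 1e-9)
  }
  # curve is non-increasing over the 10-s measurement
  p <- bleach_params_for_half_life(1244)
  v <- bleach_curve(p, seq(0, 10000, by = 10))
  expect_true(all(diff(v) <= 0))
  # the component constructor rejects parameters off the target
  expect_error(
    emission_component("PI", "bound", 617, 18, target_half_life_ms = 500,
                       bleach_params = bleach_params_for_half_life(600)),
    "1 ms")
})

test_that("ideal-mode samples carry one dye's signal at the extremes", {
  d <- ideal_tiny_design(n_frames = 2)
  live <- simulate_measurement(100, 1e8, d)
  dead <- simulate_measurement(0, 1e8, d)
  s_live <- get_frame(live, 0)
  s_dead <- get_frame(dead, 0)
  expect_equal(integrated_intensity(s_live, c(609, 629)), 0)
  expect_gt(integrated_intensity(s_live, c(509, 529)), 0)
  expect_equal(integrated_intensity(s_dead, c(509, 529)), 0)
  expect_gt(integrated_intensity(s_dead, c(609, 629)), 0)
})

test_that("a fixed seed reproduces a measurement bit for bit", {
  d <- generator_design(concentration_classes = 1e8, n_experiments = 1,
                        n_frames = 4, seed = 3)
  m1 <- simulate_measurement(50, 1e8, d, seed = 123)
  m2 <- simulate_measurement(50, 1e8, d, seed = 123)
  expect_identical(m1$intensities, m2$intensities)
  m3 <- simulate_measurement(50, 1e8, d, seed = 124)
  expect_false(identical(m1$intensities, m3$intensities))
})

test_that("dataset generation produces the designed counts and metadata", {
  d <- generator_design(live_fractions = c(0, 2.5, 5, 10, 25, 50, 75, 100),
                        concentration_classes = 1e8, n_experiments = 3,
                        replicates_per_sample = 3, n_frames = 2,
                        fcm_error_sd = 0, seed = 9)
  ds <- generate_dataset(d)
  expect_length(ds$samples, 24)       # 8 fractions x 1 class x 3 experiments
  expect_length(ds$measurements, 72)  # x 3 replicates
  expect_equal(nrow(ds$truth), 72)
  # fcm_error_sd = 0: the reference equals the true fraction exactly
  expect_identical(ds$truth$f_live_ref, ds$truth$true_f_live)
  # every measurement resolves to exactly one sample
  ref_ids <- unlist(lapply(ds$samples, `[[`, "measurement_ids"))
  expect_setequal(ref_ids, vapply(ds$measurements, `[[`, "", "measurement_id"))
  # anomaly tags are withheld from the series, kept in the truth table
  expect_true(all(is.na(vapply(ds$measurements, `[[`, NA, "anomalous"))))
  expect_type(ds$truth$anomalous, "logical")
})

test_that("regeneration with the same design seed is an exact replay", {
  d <- generator_design(concentration_classes = 1e8, n_experiments = 2,
                        live_fractions = c(0, 50, 100),
                        replicates_per_sample = 2, n_frames = 3,
                        anomaly_prob = 0.3, seed = 77)
  a <- generate_dataset(d)
  b <- generate_dataset(d)
  expect_identical(a$truth, b$truth)
  expect_gt(sum(a$truth$anomalous), 0)  # prob 0.3 over 24 draws
  for (i in seq_along(a$measurements)) {
    expect_identical(a$measurements[[i]]$intensities,
                     b$measurements[[i]]$intensities)
  }
})

test_that("the lower concentration class has more unbound dye relative to bound", {
  d <- generator_design(seed = 1)
  ratio <- function(cls) {
    a <- vitaspec:::component_amplitudes(100, cls, d)
    a[["mU_SYTO9"]] / a[["mB_SYTO9"]]
  }
  expect_gt(ratio(1e7), ratio(1e8))
})

test_that("per-component decay in a noiseless series follows its double exponential", {
  d <- ideal_tiny_design(n_frames = 100)
  m <- simulate_measurement(100, 1e8, d)
  tr <- extract_decay_trace(m, c(509, 529))
  comp <- vitaspec:::design_components(d)$mB_SYTO9
  expected <- tr$intensities[1] *
    bleach_curve(comp$bleach_params, tr$times_ms) /
    bleach_curve(comp$bleach_params, tr$times_ms[1])
  expect_equal(tr$intensities, expected, tolerance = 1e-10)
})
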