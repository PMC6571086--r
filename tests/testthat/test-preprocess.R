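test_that("normalisation rescales to 8 ms and 10 mW", {
  cfg <- preprocess_config()
  wl <- 500:510
  ref <- new_spectrum(wl, rep(10, 11), integration_time_ms = 8,
                      laser_power_mw = 10)
  expect_equal(normalize_spectrum(ref, cfg)$intensities, rep(10, 11))

  s20 <- new_spectrum(wl, rep(10, 11), integration_time_ms = 20,
                      laser_power_mw = 10)
  expect_equal(normalize_spectrum(s20, cfg)$intensities, rep(4, 11))

  # independent factor computation: (8/16) * (10/5) = 1
  s <- new_spectrum(wl, rep(10, 11), integration_time_ms = 16,
                    laser_power_mw = 5)
  expect_equal(normalize_spectrum(s, cfg)$intensities, rep(10, 11))

  n <- normalize_spectrum(s, cfg)
  expect_true(n$normalised)
  expect_error(normalize_spectrum(n, cfg), "already normalised")
})

test_that("normalisation is scale-equivariant in integration time", {
  d <- generator_design(concentration_classes = 1e8, n_frames = 3, seed = 5)
  m <- simulate_measurement(50, 1e8, d, seed = 21)
  doubled <- m
  doubled$intensities <- m$intensities * 2
  doubled$integration_time_ms <- m$integration_time_ms * 2
  cfg <- preprocess_config()
  expect_identical(normalize_series(m, cfg)$intensities,
                   normalize_series(doubled, cfg)$intensities)
})

test_that("background subtraction is an exact inverse of addition", {
  cfg <- preprocess_config()
  wl <- 500:520
  bg <- new_spectrum(wl, stats::dnorm(wl, 510, 4) * 100, normalised = TRUE)
  sig <- stats::dnorm(wl, 515, 3) * 50
  s <- new_spectrum(wl, sig + bg$intensities, normalised = TRUE)
  out <- subtract_background(s, bg)
  expect_equal(out$intensities, sig)
  expect_false(attr(out, "negative_integral"))

  same <- subtract_background(bg, bg)
  expect_equal(same$intensities, rep(0, 21))

  zero_bg <- new_spectrum(wl, rep(0, 21), normalised = TRUE)
  expect_equal(subtract_background(s, zero_bg)$intensities, s$intensities)

  over <- new_spectrum(wl, bg$intensities + 1, normalised = TRUE)
  expect_true(attr(subtract_background(bg, over), "negative_integral"))
  expect_error(subtract_background(s, new_spectrum(400:420, rep(1, 21),
                                                   normalised = TRUE)),
               "grids")
})

test_that("anomaly screening flags the deviant replicate and spares degenerate cases", {
  mk <- function(id, sid, value) toy_series(n_frames = 2, value = value,
                                            measurement_id = id, sample_id = sid)
  # three identical replicates: nothing flagged
  f <- flag_anomalous(list(mk("a", "s1", 1), mk("b", "s1", 1), mk("c", "s1", 1)))
  expect_false(any(f$flagged))

  # two identical + one at 3x: MAD of {1,1,3} integrals is 0, deviation of
  # the 3x replicate is positive, so only it exceeds 3 * MAD
  f <- flag_anomalous(list(mk("a", "s1", 1), mk("b", "s1", 1), mk("c", "s1", 3)))
  expect_identical(f$flagged, c(FALSE, FALSE, TRUE))

  # single measurement: never flagged
  f <- flag_anomalous(list(mk("a", "s1", 5)))
  expect_false(any(f$flagged))

  # exactly two replicates: disagreement reported for review, neither flagged
  f <- flag_anomalous(list(mk("a", "s1", 1), mk("b", "s1", 2)))
  expect_false(any(f$flagged))
  expect_true(all(grepl("manual review", f$reason)))
  f <- flag_anomalous(list(mk("a", "s1", 1), mk("b", "s1", 1.2)))
  expect_false(any(nzchar(f$reason)))
})

test_that("anomaly screening catches most generator-injected anomalies", {
  caught <- 0L; injected <- 0L
  for (seed in 1:4) {
    d <- generator_design(concentration_classes = 1e8, n_experiments = 2,
                          live_fractions = c(0, 10, 50, 90),
                          replicates_per_sample = 4, n_frames = 2,
                          anomaly_prob = 0.06, seed = seed)
    ds <- generate_dataset(d)
    flags <- flag_anomalous(preprocess_all(ds))
    truth <- ds$truth$anomalous[match(flags$measurement_id,
                                      ds$truth$measurement_id)]
    injected <- injected + sum(truth)
    caught <- caught + sum(truth & flags$flagged)
  }
  expect_gt(injected, 3)
  expect_gte(caught / injected, 0.9)
})

test_that("frame selection maps time points to nearest-midpoint frames", {
  s <- toy_series(n_frames = 500)
  # midpoints are 10, 30, ..., so 1244 ms sits nearest 1250 ms = frame 62
  # and 1124 ms nearest 1130 ms = frame 56 (enumerated by hand)
  expect_equal(frame_for_timepoint(0, 20, 500), 0)
  expect_equal(frame_for_timepoint(1244, 20, 500), 62)
  expect_equal(frame_for_timepoint(1124, 20, 500), 56)
  # 20 ms is equidistant from midpoints 10 and 30: earlier frame wins
  expect_equal(frame_for_timepoint(20, 20, 500), 0)
  expect_error(frame_for_timepoint(10000, 20, 500), "outside")

  picked <- select_frames(s, c(0, 1244))
  expect_length(picked, 2)
  expect_s3_class(picked[[1]], "vs_spectrum")
  expect_error(select_frames(s, c(0, 1, 2, 3, 4, 5)), "at most 5")
})

test_that("frame summing accumulates intensity and integration time", {
  s <- toy_series(n_frames = 4, value = 2)
  one <- sum_frames(s, c(1, 1))
  expect_equal(one$intensities, get_frame(s, 1)$intensities)
  two <- sum_frames(s, c(0, 1))
  expect_equal(two$intensities, rep(4, 11))
  expect_equal(two$integration_time_ms, 40)
  expect_error(sum_frames(s, c(3, 1)), "empty")
  expect_error(sum_frames(s, c(0, 4)), "out of bounds")

  # quadrature oracle: summing all frames of a noiseless single-component
  # series equals the spectral shape times the summed bleach factors
  d <- ideal_tiny_design(n_frames = 50)
  m <- simulate_measurement(100, 1e8, d)
  total <- sum_frames(m, c(0, 49))
  comp <- vitaspec:::design_components(d)$mB_SYTO9
  bleach_sum <- sum(bleach_curve(comp$bleach_params, frame_times(m)))
  shape <- m$intensities[, 1] / bleach_curve(comp$bleach_params, 10)
  expect_equal(total$intensities, shape * bleach_sum, tolerance = 1e-10)
})

test_that("mean-centring uses training means and inverts exactly", {
  d <- ideal_tiny_design(n_experiments = 2, replicates_per_sample = 2,
                         n_frames = 3)
  ds <- generate_dataset(d)
  ms <- preprocess_all(ds)
  means <- compute_timepoint_means(ms, 0)
  feats <- build_features(ms, 0, means = means)
  # centring the training set itself: column means are zero
  expect_equal(colMeans(feats$X), rep(0, ncol(feats$X)), tolerance = 1e-12)
  # centred value + training mean restores the original spectrum
  restored <- feats$X[3, ] + means[1, ]
  expect_equal(restored, get_frame(ms[[3]], 0)$intensities)
  expect_error(mean_center(feats$X, means[1, 1:10]), "grid mismatch")
  # identical spectra centred on their own mean vanish
  same <- rbind(means[1, ], means[1, ])
  expect_equal(mean_center(same, means[1, ]), matrix(0, 2, ncol(means)))
})
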