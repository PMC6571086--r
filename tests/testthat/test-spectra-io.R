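test_that("constructors enforce the basic invariants", {
  expect_error(new_spectrum(c(500, 500, 501), c(1, 2, 3)), "strictly increasing")
  expect_error(new_spectrum(500:502, c(1, 2)), "same length")
  expect_error(new_spectrum(500:502, 1:3, integration_time_ms = 0), "positive")
  expect_error(new_measurement_series(500:502, matrix(1, 2, 4)), "one row per wavelength")
  expect_error(new_sample_record("s", "e", 1e8, 101, "m"), "\\[0, 100\\]")
  s <- toy_series(n_frames = 500)
  expect_equal(frame_times(s)[1], 10)
  expect_equal(frame_times(s)[500], 9990)
  expect_equal(get_frame(s, 0)$intensities, rep(1, 11))
  expect_error(get_frame(s, 500), "out of range")
})

test_that("a measurement bundle round-trips through write and read", {
  d <- generator_design(concentration_classes = 1e8, n_experiments = 1,
                        live_fractions = c(0, 50, 100),
                        replicates_per_sample = 3, n_frames = 6, seed = 42)
  ds <- generate_dataset(d)
  path <- withr::local_tempdir()
  write_measurement_bundle(ds$measurements, ds$samples, file.path(path, "b"))
  back <- read_measurement_bundle(file.path(path, "b"))

  expect_length(back$measurements, length(ds$measurements))
  expect_length(back$samples, length(ds$samples))
  for (i in seq_along(ds$samples)) {
    expect_identical(back$samples[[i]]$sample_id, ds$samples[[i]]$sample_id)
    expect_identical(back$samples[[i]]$experiment_id, ds$samples[[i]]$experiment_id)
    expect_identical(back$samples[[i]]$f_live_ref, ds$samples[[i]]$f_live_ref)
    expect_identical(back$samples[[i]]$measurement_ids,
                     ds$samples[[i]]$measurement_ids)
  }
  for (i in seq_along(ds$measurements)) {
    expect_identical(back$measurements[[i]]$wavelengths,
                     ds$measurements[[i]]$wavelengths)
    expect_equal(back$measurements[[i]]$intensities,
                 ds$measurements[[i]]$intensities, tolerance = 1e-12)
  }
})

test_that("writing a bundle twice produces identical files", {
  d <- ideal_tiny_design(n_frames = 2)
  d$live_fractions <- c(25, 75)
  ds <- generate_dataset(d)
  root <- withr::local_tempdir()
  write_measurement_bundle(ds$measurements, ds$samples, file.path(root, "a"))
  back <- read_measurement_bundle(file.path(root, "a"))
  write_measurement_bundle(back$measurements, back$samples, file.path(root, "c"))
  for (f in list.files(file.path(root, "a"))) {
    expect_identical(readLines(file.path(root, "a", f)),
                     readLines(file.path(root, "c", f)),
                     label = paste("file", f))
  }
})

test_that("bundle reading reports broken cross-references by id", {
  d <- ideal_tiny_design(n_frames = 2)
  d$live_fractions <- 50
  ds <- generate_dataset(d)
  root <- withr::local_tempdir()
  b <- file.path(root, "b")
  write_measurement_bundle(ds$measurements, ds$samples, b)
  bad_id <- ds$measurements[[1]]$measurement_id
  file.remove(file.path(b, paste0("spectra_", bad_id, ".csv")))
  expect_error(read_measurement_bundle(b), bad_id, fixed = TRUE)
  expect_error(read_measurement_bundle(withr::local_tempdir()), "metadata")
})

test_that("an empty sample list still yields a readable bundle", {
  root <- withr::local_tempdir()
  write_measurement_bundle(list(), list(), file.path(root, "e"))
  back <- read_measurement_bundle(file.path(root, "e"))
  expect_length(back$measurements, 0)
  expect_length(back$samples, 0)
})

test_that("a persisted model predicts identically after reload", {
  d <- ideal_tiny_design(n_experiments = 2, replicates_per_sample = 2,
                         n_frames = 2)
  ds <- generate_dataset(d)
  ms <- preprocess_all(ds)
  model <- train_calibration(ms, ds$samples, 0, C_values = 10,
                             eps_values = 0.1, concentration_class = 1e8)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  p1 <- stats::predict(model, ms[1:5])
  p2 <- stats::predict(back, ms[1:5])
  expect_identical(p1$prediction, p2$prediction)
  expect_length(back$weights,
                length(back$timepoints_ms) * length(back$wavelengths_nm))
})

test_that("model loading rejects wrong version tags and truncated files", {
  d <- ideal_tiny_design(n_experiments = 2, n_frames = 2)
  ds <- generate_dataset(d)
  ms <- preprocess_all(ds)
  model <- train_calibration(ms, ds$samples, 0, C_values = 1, eps_values = 0.1)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)

  txt <- readLines(path)
  bad <- sub("vitaspec-model-1", "other-model-9", txt)
  path2 <- withr::local_tempfile(fileext = ".json")
  writeLines(bad, path2)
  expect_error(load_model(path2), "version tag mismatch")

  path3 <- withr::local_tempfile(fileext = ".json")
  writeLines(txt[1:(length(txt) %/% 2)], path3)
  expect_error(load_model(path3))
})
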