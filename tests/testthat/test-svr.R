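test_that("feature rows are concatenated centred frames in timepoint order", {
  d <- ideal_tiny_design(n_experiments = 2, n_frames = 100)
  ds <- generate_dataset(d)
  ms <- preprocess_all(ds)
  n_wl <- length(ms[[1]]$wavelengths)

  f1 <- build_features(ms, 0)
  expect_equal(ncol(f1$X), n_wl)
  f2 <- build_features(ms, c(0, 1244))
  expect_equal(ncol(f2$X), 2 * n_wl)

  # reordering timepoints permutes the feature blocks identically
  f2r <- build_features(ms, c(1244, 0),
                        means = f2$means[c(2, 1), , drop = FALSE])
  expect_equal(f2r$X[, 1:n_wl], f2$X[, n_wl + 1:n_wl])
  expect_equal(f2r$X[, n_wl + 1:n_wl], f2$X[, 1:n_wl])
})

test_that("primal weights reproduce the trainer's predictions exactly", {
  withr::with_seed(5, {
    X <- matrix(stats::rnorm(200), 40)
    y <- drop(X %*% c(3, -1, 2, 0, 1)) + 50 + stats::rnorm(40, 0, 0.3)
  })
  for (C in c(0.5, 10)) {
    fit <- svr_train(X, y, C, 0.1)
    ref <- e1071::svm(x = X, y = y, type = "eps-regression",
                      kernel = "linear", cost = C, epsilon = 0.1,
                      scale = FALSE)
    expect_equal(svr_predict(fit, X), unname(stats::predict(ref, X)),
                 tolerance = 1e-12)
  }
})

test_that("group folds partition the data with one experiment held out each", {
  groups <- c("e2", "e1", "e1", "e3", "e2", "e3", "e1")
  folds <- gkcv_folds(groups)
  expect_named(folds, c("e1", "e2", "e3"))
  expect_setequal(unlist(folds), seq_along(groups))
  for (g in names(folds)) {
    expect_true(all(groups[folds[[g]]] == g))
    expect_true(all(groups[-folds[[g]]] != g))
  }
  expect_error(gkcv_folds(rep("e1", 5)), "at least 2 groups")
})

test_that("grouped CV error matches a brute-force primal QP oracle", {
  x <- c(0, 1, 2, 3, 4, 5)
  y <- c(0.3, 2.2, 3.9, 6.3, 8.0, 10.2)
  groups <- c(1, 1, 1, 2, 2, 2)
  C <- 10; eps <- 0.1
  preds <- numeric(6)
  for (held in list(1:3, 4:6)) {
    par <- primal_svr_1d(x[-held], y[-held], C, eps)
    preds[held] <- par[1] * x[held] + par[2]
  }
  oracle <- sqrt(mean((preds - y)^2))
  ours <- gkcv_rmse(matrix(x), y, groups, C, eps)
  expect_equal(as.numeric(ours), oracle, tolerance = 1e-6)
})

test_that("a realisable linear target is recovered to within the tube", {
  # noise-free targets that are an exact linear functional of the features
  withr::with_seed(11, {
    X <- matrix(stats::rnorm(90), 30)
    y <- drop(X %*% c(10, -5, 2)) + 50
  })
  groups <- rep(1:3, each = 10)
  r <- gkcv_rmse(X, y, groups, C = 1000, epsilon = 0.1)
  expect_lte(as.numeric(r), 0.1 + 1e-6)
  # constant targets are predicted by the intercept alone
  r0 <- gkcv_rmse(X, rep(42, 30), groups, C = 10, epsilon = 0.1)
  expect_lte(as.numeric(r0), 0.1)
})

test_that("screening ranks candidate sets by grouped CV error and prefers parsimony", {
  # information lives only in frame 0; later frames are pure noise, so the
  # single-spectrum candidate should win over its noisier supersets
  wl <- seq(500, 540, by = 10)
  withr::with_seed(19, {
    ms <- list(); samples <- list(); k <- 0
    for (e in 1:2) for (f in c(0, 25, 50, 75, 100)) {
      k <- k + 1
      sid <- sprintf("s%d", k)
      frames <- cbind(f * stats::dnorm(wl, 520, 8) + stats::rnorm(5, 0, 0.1),
                      matrix(stats::rnorm(10, 0, 5), 5))
      ms[[k]] <- new_measurement_series(wl, frames, frame_duration_ms = 20,
                                        measurement_id = paste0("m", k),
                                        sample_id = sid, normalised = TRUE)
      samples[[k]] <- new_sample_record(sid, paste0("e", e), 1e8, f,
                                        paste0("m", k))
    }
  })
  cand <- list(S1 = 0, "S1+t30" = c(0, 30), "S1+t30+t50" = c(0, 30, 50))
  sc <- screen_timepoint_sets(ms, samples, cand)
  expect_identical(sc$chosen, "S1")
  # ranking is self-consistent with independent per-candidate calls
  tg <- measurement_targets(ms, samples)
  indep <- vapply(cand, function(tp) {
    as.numeric(gkcv_rmse(build_features(ms, tp)$X, tg$y, tg$groups, 1, 0.1))
  }, 0)
  expect_equal(sc$table$rmse, unname(indep))
  expect_error(screen_timepoint_sets(ms, samples, list(bad = c(30))),
               "timepoint 0")
})

test_that("grid tuning returns the exhaustive minimum and refits on all data", {
  d <- ideal_tiny_design(n_experiments = 3, replicates_per_sample = 1,
                         n_frames = 2)
  ds <- generate_dataset(d)
  ms <- preprocess_all(ds)
  tg <- measurement_targets(ms, ds$samples)
  ft <- build_features(ms, 0)

  one <- tune_svr(ft$X, tg$y, tg$groups, C_values = 7, eps_values = 0.05)
  expect_equal(one$C, 7)
  expect_equal(one$epsilon, 0.05)

  grid_C <- c(0.5, 10); grid_eps <- c(0.01, 0.1)
  tuned <- tune_svr(ft$X, tg$y, tg$groups, grid_C, grid_eps)
  # exhaustive oracle: independently recompute every grid point
  best <- NULL
  for (C in grid_C) for (eps in grid_eps) {
    r <- as.numeric(gkcv_rmse(ft$X, tg$y, tg$groups, C, eps))
    if (is.null(best) || r < best$r) best <- list(C = C, eps = eps, r = r)
  }
  expect_equal(tuned$C, best$C)
  expect_equal(tuned$epsilon, best$eps)
  expect_equal(tuned$rmse, best$r)

  model <- train_calibration(ms, ds$samples, 0, grid_C, grid_eps,
                             concentration_class = 1e8)
  expect_s3_class(model, "calibration_model")
  expect_equal(model$C, best$C)
  # tuned model fits training data at least as well as the default params
  def <- svr_train(ft$X, tg$y, 1, 0.1)
  rmse <- function(p) sqrt(mean((p - tg$y)^2))
  expect_lte(rmse(svr_predict(model, ft$X)),
             rmse(svr_predict(def, ft$X)) + 0.05)
})

test_that("per-sample predictions average replicates and flag impossible values", {
  wl <- c(500, 510)
  model <- structure(
    list(version = "vitaspec-model-1", kind = "svr",
         timepoints_ms = 0, wavelengths_nm = wl,
         mean_spectra = matrix(0, 1, 2),
         weights = c(1, 0), intercept = 0,
         C = 1, epsilon = 0.1, concentration_class = 1e8),
    class = "calibration_model")
  mk <- function(id, sid, v) new_measurement_series(
    wl, matrix(c(v, 0), 2, 1), measurement_id = id, sample_id = sid,
    normalised = TRUE)
  ms <- list(mk("m1", "A", -5), mk("m2", "A", -5),
             mk("m3", "B", 100.1),
             mk("m4", "C", 100), mk("m5", "D", 40), mk("m6", "D", 60),
             mk("m7", "E", 0))
  samples <- list(new_sample_record("A", "e1", 1e8, 0, c("m1", "m2")),
                  new_sample_record("B", "e1", 1e8, 100, "m3"),
                  new_sample_record("C", "e1", 1e8, 100, "m4"),
                  new_sample_record("D", "e1", 1e8, 50, c("m5", "m6")),
                  new_sample_record("E", "e1", 1e8, 0, "m7"))
  ps <- predict_samples(model, ms, samples)
  ps <- ps[order(ps$sample_id), ]
  expect_equal(ps$prediction, c(-5, 100.1, 100, 50, 0))
  expect_equal(ps$valid, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(ps$n_measurements, c(2L, 1L, 1L, 2L, 1L))
})

test_that("ideal noise-free data give held-out error within the tube", {
  d <- ideal_tiny_design(n_experiments = 3, replicates_per_sample = 2,
                         n_frames = 3)
  ds <- generate_dataset(d)
  ms <- preprocess_all(ds)
  tg <- measurement_targets(ms, ds$samples)
  ft <- build_features(ms, 0)
  r <- gkcv_rmse(ft$X, tg$y, tg$groups, C = 100, epsilon = 0.1)
  expect_lte(as.numeric(r), 0.1 + 1e-3)
})
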