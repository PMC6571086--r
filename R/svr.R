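#' Train a linear epsilon-SVR and extract its primal form
#'
#' Thin wrapper around the LIBSVM eps-regression implementation (linear
#' kernel, no feature scaling). The fitted model is immediately reduced to
#' its primal form - a weight vector and an intercept - so predictions are
#' a plain dot product and the model can be persisted as text.
#'
#' @param X Feature matrix, one row per measurement.
#' @param y Targets (reference percent live).
#' @param C Penalty factor (> 0).
#' @param epsilon Margin of tolerance (>= 0).
#' @return List with `weights`, `intercept`, `C`, `epsilon`.
#' @export
svr_train <- function(X, y, C, epsilon) {
  if (C <= 0) stop("C must be > 0")
  if (epsilon < 0) stop("epsilon must be >= 0")
  X <- as.matrix(X)
  # fitted = FALSE: skip the internal prediction pass, which errors on the
  # legitimate zero-support-vector solution (all targets inside the tube)
  fit <- e1071::svm(x = X, y = y, type = "eps-regression",
                    kernel = "linear", cost = C, epsilon = epsilon,
                    scale = FALSE, fitted = FALSE)
  w <- if (fit$tot.nSV == 0) numeric(ncol(X))
       else drop(crossprod(fit$coefs, fit$SV))
  list(weights = as.numeric(w), intercept = -fit$rho,
       C = C, epsilon = epsilon)
}

#' Predict from a primal linear SVR
#'
#' @param fit A list with `weights` and `intercept` ([svr_train()] output
#'   or a loaded [load_model()] object).
#' @param X Feature matrix or single feature vector.
#' @return Numeric predictions.
#' @export
svr_predict <- function(fit, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  drop(X %*% fit$weights + fit$intercept)
}

#' Group K-fold partition
#'
#' One fold per distinct group; each fold's held-out set is exactly the
#' rows of one group, so the folds partition the data and no experiment
#' ever contributes to both sides of a split.
#'
#' @param groups Group label per row (experiment ids).
#' @return Named list of held-out index vectors, one per group (sorted
#'   group order).
#' @export
gkcv_folds <- function(groups) {
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  if (length(lv) < 2) stop("group K-fold CV needs at least 2 groups")
  stats::setNames(lapply(lv, function(g) which(groups == g)), lv)
}

#' Group K-fold cross-validated RMSE of a linear epsilon-SVR
#'
#' For each of the M groups, trains on the remaining groups and predicts
#' the held-out group; the RMSE is pooled over all held-out predictions
#' (every row is predicted exactly once).
#'
#' @param X Feature matrix.
#' @param y Targets.
#' @param groups Group label per row.
#' @param C,epsilon SVR hyperparameters.
#' @return Pooled RMSE. The per-row held-out predictions are attached as
#'   attribute `"predictions"`.
#' @export
gkcv_rmse <- function(X, y, groups, C, epsilon) {
  X <- as.matrix(X)
  folds <- gkcv_folds(groups)
  preds <- rep(NA_real_, length(y))
  for (held in folds) {
    fit <- svr_train(X[-held, , drop = FALSE], y[-held], C, epsilon)
    preds[held] <- svr_predict(fit, X[held, , drop = FALSE])
  }
  out <- sqrt(mean((preds - y)^2))
  attr(out, "predictions") <- preds
  out
}

#' Build concatenated-spectra features
#'
#' One row per measurement: the frames selected at the requested time
#' points, mean-centred against the per-timepoint training means and
#' concatenated in timepoint order. Row length is
#' `length(timepoints) * length(wavelength grid)`.
#'
#' @param measurements List of preprocessed `vs_series`.
#' @param timepoints Time points, ms (first must correspond to frame 0 for
#'   calibration use).
#' @param means Per-timepoint training mean matrix
#'   ([compute_timepoint_means()]); computed from `measurements` when
#'   `NULL` (training use only - test data must be centred with the
#'   training means).
#' @return List with `X`, `means`, `timepoints`, `wavelengths`,
#'   `measurement_ids`, `sample_ids`.
#' @export
build_features <- function(measurements, timepoints, means = NULL) {
  if (length(measurements) == 0) stop("no measurements supplied")
  wl <- measurements[[1]]$wavelengths
  if (is.null(means)) means <- compute_timepoint_means(measurements, timepoints)
  if (!is.matrix(means) || nrow(means) != length(timepoints) ||
      ncol(means) != length(wl)) {
    stop("means matrix must be n_timepoints x n_wavelengths")
  }
  X <- matrix(0, length(measurements), length(timepoints) * length(wl))
  for (i in seq_along(measurements)) {
    m <- measurements[[i]]
    if (!isTRUE(all.equal(m$wavelengths, wl))) stop("inconsistent wavelength grids")
    fr <- select_frames(m, timepoints)
    X[i, ] <- unlist(lapply(seq_along(fr), function(j) {
      fr[[j]]$intensities - means[j, ]
    }))
  }
  list(X = X, means = means, timepoints = timepoints, wavelengths = wl,
       measurement_ids = vapply(measurements, `[[`, "", "measurement_id"),
       sample_ids = vapply(measurements, `[[`, "", "sample_id"))
}

#' Targets and CV groups for a set of measurements
#'
#' @param measurements List of `vs_series`.
#' @param samples List of `vs_sample`.
#' @return List with `y` (reference percent live per measurement) and
#'   `groups` (experiment id per measurement).
#' @export
measurement_targets <- function(measurements, samples) {
  lk <- sample_lookup(samples)
  miss <- setdiff(vapply(measurements, `[[`, "", "sample_id"), names(lk))
  if (length(miss)) stop("unknown sample ids: ", paste(miss, collapse = ", "))
  list(y = vapply(measurements, function(m) lk[[m$sample_id]]$f_live_ref, 0),
       groups = vapply(measurements,
                       function(m) lk[[m$sample_id]]$experiment_id, ""))
}

#' Default candidate timepoint sets
#'
#' The eight spectral combinations screened for multi-spectra calibration:
#' the first spectrum alone; the first spectrum paired with each of the
#' four photobleaching half-lives (mB-SYTO9, mB-PI, mU-SYTO9, mU-PI); the
#' two 3-spectra bound / unbound combinations; and all five together.
#'
#' @param half_lives_ms Named numeric with `mB_SYTO9`, `mB_PI`,
#'   `mU_SYTO9`, `mU_PI` half-lives, ms.
#' @return Named list of timepoint vectors (ms), each starting at 0.
#' @export
default_timepoint_sets <- function(half_lives_ms) {
  h <- half_lives_ms
  list(
    "S1" = 0,
    "S1+mB-SYTO9" = c(0, h[["mB_SYTO9"]]),
    "S1+mB-PI" = c(0, h[["mB_PI"]]),
    "S1+mU-SYTO9" = c(0, h[["mU_SYTO9"]]),
    "S1+mU-PI" = c(0, h[["mU_PI"]]),
    "S1+mB-SYTO9+mB-PI" = c(0, h[["mB_SYTO9"]], h[["mB_PI"]]),
    "S1+mU-SYTO9+mU-PI" = c(0, h[["mU_SYTO9"]], h[["mU_PI"]]),
    "S1+all-half-lives" = c(0, h[["mB_SYTO9"]], h[["mB_PI"]],
                            h[["mU_SYTO9"]], h[["mU_PI"]]))
}

#' Screen candidate timepoint sets at default SVR parameters
#'
#' Evaluates each candidate spectral combination by group K-fold CV at the
#' default screening parameters (C = 1, epsilon = 0.1) and picks the
#' combination with the lowest pooled RMSE. Ties are broken toward fewer
#' time points (parsimony: later spectra can add noise without adding
#' compositional information), then toward earlier list order.
#'
#' @param measurements List of preprocessed `vs_series`.
#' @param samples List of `vs_sample`.
#' @param candidate_sets Named list of timepoint vectors (ms); every set
#'   must include time 0.
#' @param C,epsilon Screening parameters (defaults 1 and 0.1).
#' @return List with `table` (data frame: set, n_timepoints, rmse) and
#'   `chosen` (name of the winning set).
#' @export
screen_timepoint_sets <- function(measurements, samples, candidate_sets,
                                  C = 1, epsilon = 0.1) {
  if (length(candidate_sets) < 1) stop("at least one candidate set is required")
  if (is.null(names(candidate_sets))) {
    names(candidate_sets) <- vapply(candidate_sets, function(tp)
      paste(tp, collapse = "+"), "")
  }
  if (any(!vapply(candidate_sets, function(tp) 0 %in% tp, TRUE))) {
    stop("every candidate set must include timepoint 0 (the first spectrum)")
  }
  tg <- measurement_targets(measurements, samples)
  rmse <- vapply(seq_along(candidate_sets), function(i) {
    feats <- build_features(measurements, candidate_sets[[i]])
    as.numeric(gkcv_rmse(feats$X, tg$y, tg$groups, C, epsilon))
  }, 0)
  n_tp <- vapply(candidate_sets, length, 0L)
  tab <- data.frame(set = names(candidate_sets), n_timepoints = n_tp,
                    rmse = rmse, stringsAsFactors = FALSE)
  ord <- order(tab$rmse, tab$n_timepoints, seq_len(nrow(tab)))
  list(table = tab, chosen = tab$set[ord[1]])
}

#' Grid search for SVR hyperparameters under group K-fold CV
#'
#' Exhaustively evaluates every (C, epsilon) pair by [gkcv_rmse()] and
#' returns the pair minimising the pooled RMSE (first pair in grid order on
#' ties; grid order is C-major).
#'
#' @param X Feature matrix.
#' @param y Targets.
#' @param groups Group label per row.
#' @param C_values,eps_values Candidate grids. The defaults span the
#'   useful range for percent-live targets on mean-centred spectra.
#' @return List with `C`, `epsilon`, `rmse`, and `grid` (the full RMSE
#'   table).
#' @export
tune_svr <- function(X, y, groups,
                     C_values = c(0.01, 0.1, 0.5, 1, 10, 100),
                     eps_values = c(0.001, 0.01, 0.1, 1)) {
  if (length(C_values) < 1 || length(eps_values) < 1) stop("empty grid")
  grid <- expand.grid(epsilon = eps_values, C = C_values,
                      KEEP.OUT.ATTRS = FALSE)[, c("C", "epsilon")]
  grid$rmse <- vapply(seq_len(nrow(grid)), function(i) {
    as.numeric(gkcv_rmse(X, y, groups, grid$C[i], grid$epsilon[i]))
  }, 0)
  best <- which.min(grid$rmse)  # first minimum in grid order
  list(C = grid$C[best], epsilon = grid$epsilon[best],
       rmse = grid$rmse[best], grid = grid)
}

#' Train a full viability calibration model
#'
#' The complete calibration step for one concentration class: computes the
#' per-timepoint training means, builds concatenated mean-centred
#' features, tunes (C, epsilon) by grid search under group K-fold CV, and
#' refits on all training data. The returned model carries its full
#' preprocessing state (time points, wavelength grid, training means) plus
#' the primal weights, so it is self-contained and persistable with
#' [save_model()].
#'
#' @param measurements List of preprocessed training `vs_series`.
#' @param samples List of `vs_sample`.
#' @param timepoints Time points of the chosen spectral combination, ms.
#' @param C_values,eps_values Tuning grids (see [tune_svr()]); pass
#'   length-1 vectors to skip tuning.
#' @param concentration_class Class the model is trained for (recorded).
#' @return An object of class `"calibration_model"`.
#' @export
train_calibration <- function(measurements, samples, timepoints,
                              C_values = c(0.01, 0.1, 0.5, 1, 10, 100),
                              eps_values = c(0.001, 0.01, 0.1, 1),
                              concentration_class = NA_real_) {
  timepoints <- sort(as.numeric(timepoints))
  if (timepoints[1] != 0) stop("the first timepoint must be 0 (frame 0)")
  feats <- build_features(measurements, timepoints)
  tg <- measurement_targets(measurements, samples)
  tuned <- tune_svr(feats$X, tg$y, tg$groups, C_values, eps_values)
  fit <- svr_train(feats$X, tg$y, tuned$C, tuned$epsilon)
  structure(
    list(version = "vitaspec-model-1",
         kind = "svr",
         timepoints_ms = timepoints,
         wavelengths_nm = feats$wavelengths,
         mean_spectra = feats$means,
         weights = fit$weights,
         intercept = fit$intercept,
         C = tuned$C, epsilon = tuned$epsilon,
         concentration_class = concentration_class,
         cv_rmse = tuned$rmse, cv_grid = tuned$grid),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> %s: %d timepoints (%s ms), %d features, C=%g, eps=%g\n",
    x$kind, length(x$timepoints_ms),
    paste(round(x$timepoints_ms), collapse = ", "),
    length(x$weights), x$C, x$epsilon))
  invisible(x)
}

#' Predict percent live for measurements
#'
#' Selects the model's frames from each measurement, centres them with the
#' model's training means, and evaluates the primal linear SVR.
#'
#' @param object A `calibration_model`.
#' @param measurements List of preprocessed `vs_series` on the model's
#'   wavelength grid.
#' @param ... Unused.
#' @return Data frame with `measurement_id`, `sample_id`, `prediction`.
#' @export
predict.calibration_model <- function(object, measurements, ...) {
  feats <- build_features(measurements, object$timepoints_ms,
                          means = object$mean_spectra)
  if (!isTRUE(all.equal(feats$wavelengths, object$wavelengths_nm))) {
    stop("measurement wavelength grid differs from the model grid")
  }
  data.frame(measurement_id = feats$measurement_ids,
             sample_id = feats$sample_ids,
             prediction = svr_predict(object, feats$X),
             stringsAsFactors = FALSE)
}

#' Per-sample predictions with validity filtering
#'
#' Predictions from the replicate measurements of each sample are
#' averaged; an averaged prediction below 0 or above 100 percent is
#' physically impossible and is flagged invalid (to be excluded from
#' agreement statistics). The boundary values 0 and 100 are valid.
#'
#' @param model A `calibration_model`.
#' @param measurements List of preprocessed `vs_series`.
#' @param samples List of `vs_sample` (for reference values).
#' @return Data frame with one row per sample: `sample_id`, `f_live_ref`,
#'   `prediction`, `valid`, `n_measurements`, `sd_measurements`.
#' @export
predict_samples <- function(model, measurements, samples) {
  per_meas <- stats::predict(model, measurements)
  lk <- sample_lookup(samples)
  miss <- setdiff(unique(per_meas$sample_id), names(lk))
  if (length(miss)) stop("unknown sample ids: ", paste(miss, collapse = ", "))
  agg <- split(per_meas$prediction, per_meas$sample_id)
  rows <- lapply(names(agg), function(sid) {
    p <- mean(agg[[sid]])
    data.frame(sample_id = sid,
               f_live_ref = lk[[sid]]$f_live_ref,
               prediction = p,
               valid = p >= 0 && p <= 100,
               n_measurements = length(agg[[sid]]),
               sd_measurements = stats::sd(agg[[sid]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "per_measurement") <- per_meas
  out
}
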