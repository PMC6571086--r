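#' Pipeline configuration
#'
#' One configuration object drives the full workflow: simulate (or load) a
#' training and a blind test bundle, preprocess, fit photobleaching
#' half-lives, screen spectral combinations, tune and train the
#' calibration models, predict the test samples, and write the validation
#' report. All randomness derives from `seed`.
#'
#' @param out_dir Run directory for artifacts (required).
#' @param seed Base seed; the training design uses it directly and the
#'   test design uses a derived substream.
#' @param design Training [generator_design()]; built from `seed` and the
#'   default study conditions when `NULL`.
#' @param test_design Test-set design; defaults to the training conditions
#'   with two blind experiments per class.
#' @param timepoint_sets Named list of candidate timepoint sets; derived
#'   from the fitted half-lives via [default_timepoint_sets()] when
#'   `NULL`.
#' @param C_values,eps_values Hyperparameter grids for tuning.
#' @param screen_C,screen_epsilon Default screening parameters.
#' @param preprocess A [preprocess_config()].
#' @return A list of class `"vs_pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            design = NULL, test_design = NULL,
                            timepoint_sets = NULL,
                            C_values = c(0.01, 0.1, 0.5, 1, 10, 100),
                            eps_values = c(0.001, 0.01, 0.1, 1),
                            screen_C = 1, screen_epsilon = 0.1,
                            preprocess = preprocess_config()) {
  if (missing(out_dir) || is.null(out_dir)) {
    stop("pipeline config is missing the required key 'out_dir'")
  }
  design <- design %||% generator_design(seed = seed)
  if (is.null(test_design)) {
    test_design <- design
    test_design$n_experiments <- rep_len(2, length(design$concentration_classes))
    test_design$seed <- substream_seed(seed, 999983, 1)
  }
  structure(list(out_dir = out_dir, seed = seed, design = design,
                 test_design = test_design, timepoint_sets = timepoint_sets,
                 C_values = C_values, eps_values = eps_values,
                 screen_C = screen_C, screen_epsilon = screen_epsilon,
                 preprocess = preprocess),
            class = "vs_pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the end-to-end calibration workflow
#'
#' Executes, per concentration class: synthetic data generation (training
#' plus blind test sets), preprocessing with anomaly exclusion,
#' per-measurement photobleaching fits and the half-life summary table,
#' screening of the candidate spectral combinations at default SVR
#' parameters, hyperparameter tuning by grid search under group K-fold CV,
#' training of the single-spectrum and chosen multi-spectra models,
#' per-sample prediction of the blind test set with validity filtering,
#' and the validation report (agreement metrics, within-2-SE fraction,
#' Bland-Altman with Shapiro-Wilk). When more than one concentration class
#' is configured, a PCA concentration gate is trained on the training
#' frame-0 spectra and evaluated on the test set. Every artifact is a CSV
#' or JSON file under `config$out_dir`; a manifest records the seed and a
#' digest of the configuration, and a fixed seed reproduces every file
#' byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the key results and artifact paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "vs_pipeline_config")) {
    stop("config must be built with pipeline_config()")
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  train <- run_stage("simulate", {
    tr <- generate_dataset(config$design, id_prefix = "train")
    write_measurement_bundle(tr$measurements, tr$samples,
                             file.path(out, "bundle_train"))
    jsonlite::write_json(tr$truth, file.path(out, "bundle_train", "truth.json"),
                         dataframe = "rows", digits = I(17), pretty = TRUE)
    tr
  })
  test <- run_stage("simulate", {
    te <- generate_dataset(config$test_design, id_prefix = "test")
    write_measurement_bundle(te$measurements, te$samples,
                             file.path(out, "bundle_test"))
    jsonlite::write_json(te$truth, file.path(out, "bundle_test", "truth.json"),
                         dataframe = "rows", digits = I(17), pretty = TRUE)
    te
  })

  pp <- config$preprocess
  prep <- run_stage("preprocess", {
    prep_set <- function(ds) {
      ms <- lapply(ds$measurements, preprocess_series, config = pp)
      flags <- flag_anomalous(ms, pp)
      keep <- !flags$flagged
      list(measurements = ms[keep], samples = ds$samples, flags = flags)
    }
    ptr <- prep_set(train)
    pte <- prep_set(test)
    excl <- rbind(cbind(set = "train", ptr$flags), cbind(set = "test", pte$flags))
    utils::write.csv(excl[excl$flagged | nzchar(excl$reason), ],
                     file.path(out, "exclusions.csv"), row.names = FALSE)
    list(train = ptr, test = pte)
  })

  classes <- config$design$concentration_classes
  results <- list()
  for (cls in classes) {
    key <- class_key(cls)
    in_class <- function(prepped) {
      lk <- sample_lookup(prepped$samples)
      keep_m <- vapply(prepped$measurements, function(m)
        lk[[m$sample_id]]$concentration_class == cls, TRUE)
      keep_s <- vapply(prepped$samples, function(s)
        s$concentration_class == cls, TRUE)
      list(measurements = prepped$measurements[keep_m],
           samples = prepped$samples[keep_s])
    }
    tr <- in_class(prep$train)
    te <- in_class(prep$test)

    hl_tab <- run_stage(paste0("photobleach_", key), {
      tab <- half_life_table(tr$measurements, tr$samples)
      utils::write.csv(tab, file.path(out, paste0("half_lives_", key, ".csv")),
                       row.names = FALSE)
      tab
    })
    hl <- stats::setNames(hl_tab$half_life_ms,
                          paste(hl_tab$state, hl_tab$dye, sep = "_"))
    sets <- config$timepoint_sets %||% default_timepoint_sets(
      c(mB_SYTO9 = unname(hl["mB_SYTO9"]), mU_SYTO9 = unname(hl["mU_SYTO9"]),
        mB_PI = unname(hl["mB_PI"]), mU_PI = unname(hl["mU_PI"])))

    screen <- run_stage(paste0("screen_", key), {
      sc <- screen_timepoint_sets(tr$measurements, tr$samples, sets,
                                  C = config$screen_C,
                                  epsilon = config$screen_epsilon)
      utils::write.csv(sc$table, file.path(out, paste0("screening_", key, ".csv")),
                       row.names = FALSE)
      sc
    })

    models <- run_stage(paste0("train_", key), {
      single <- train_calibration(tr$measurements, tr$samples, 0,
                                  config$C_values, config$eps_values,
                                  concentration_class = cls)
      multi <- train_calibration(tr$measurements, tr$samples,
                                 sets[[screen$chosen]],
                                 config$C_values, config$eps_values,
                                 concentration_class = cls)
      save_model(single, file.path(out, paste0("model_single_", key, ".json")))
      save_model(multi, file.path(out, paste0("model_multi_", key, ".json")))
      utils::write.csv(multi$cv_grid,
                       file.path(out, paste0("cv_grid_multi_", key, ".csv")),
                       row.names = FALSE)
      list(single = single, multi = multi)
    })

    train_metrics <- run_stage(paste0("train_metrics_", key), {
      rows <- lapply(names(models), function(nm) {
        ps <- predict_samples(models[[nm]], tr$measurements, tr$samples)
        ok <- ps$valid
        m <- regression_metrics(ps$prediction[ok], ps$f_live_ref[ok])
        data.frame(model = nm, rmse = m$rmse,
                   explained_variance = m$explained_variance,
                   r_squared = m$r_squared, n_samples = m$n,
                   stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      utils::write.csv(tab, file.path(out, paste0("train_metrics_", key, ".csv")),
                       row.names = FALSE)
      tab
    })

    validation <- run_stage(paste0("validate_", key), {
      val_rows <- list(); ba <- NULL; preds_out <- list()
      for (nm in names(models)) {
        ps <- predict_samples(models[[nm]], te$measurements, te$samples)
        preds_out[[nm]] <- cbind(model = nm, ps)
        ok <- ps$valid
        m <- regression_metrics(ps$prediction[ok], ps$f_live_ref[ok])
        w2 <- within_2se_fraction(ps$prediction[ok], ps$f_live_ref[ok],
                                  m$standard_error)
        val_rows[[nm]] <- data.frame(
          model = nm,
          timepoints = paste(round(models[[nm]]$timepoints_ms), collapse = "+"),
          standard_error = m$standard_error, pct_within_2se = w2,
          n_invalid = sum(!ps$valid), n_samples = m$n,
          rmse = m$rmse, explained_variance = m$explained_variance,
          stringsAsFactors = FALSE)
        if (nm == "multi") {
          ba <- bland_altman(ps$prediction[ok], ps$f_live_ref[ok])
        }
      }
      tab <- do.call(rbind, val_rows)
      utils::write.csv(tab, file.path(out, paste0("validation_", key, ".csv")),
                       row.names = FALSE)
      utils::write.csv(do.call(rbind, preds_out),
                       file.path(out, paste0("predictions_", key, ".csv")),
                       row.names = FALSE)
      jsonlite::write_json(ba, file.path(out, paste0("bland_altman_", key, ".json")),
                           auto_unbox = TRUE, digits = I(17), pretty = TRUE)
      list(table = tab, bland_altman = ba)
    })

    results[[key]] <- list(half_lives = hl_tab, screening = screen,
                           models = models, train_metrics = train_metrics,
                           validation = validation)
  }

  gate_report <- NULL
  if (length(classes) > 1) {
    gate_report <- run_stage("gate", {
      frame0 <- function(ms) t(vapply(ms, function(m) m$intensities[, 1],
                                      numeric(length(ms[[1]]$wavelengths))))
      lk <- sample_lookup(prep$train$samples)
      cls_of <- function(ms, lk) vapply(ms, function(m)
        class_key(lk[[m$sample_id]]$concentration_class), "")
      gate <- pca_concentration_gate(frame0(prep$train$measurements),
                                     cls_of(prep$train$measurements, lk))
      lk_te <- sample_lookup(prep$test$samples)
      truth_te <- cls_of(prep$test$measurements, lk_te)
      pred_te <- classify_concentration(
        gate, frame0(prep$test$measurements))$class
      rep <- list(accuracy = mean(pred_te == truth_te),
                  n_test = length(truth_te),
                  classes = gate$classes)
      jsonlite::write_json(rep, file.path(out, "gate_report.json"),
                           auto_unbox = TRUE, digits = I(17), pretty = TRUE)
      rep
    })
  }

  manifest <- list(
    package = "vitaspec",
    package_version = as.character(utils::packageVersion("vitaspec")),
    seed = config$seed,
    config_digest = config_digest(list(
      seed = config$seed,
      design = config$design[setdiff(names(config$design), "wavelengths")],
      C_values = config$C_values, eps_values = config$eps_values)),
    concentration_classes = lapply(classes, class_key),
    n_train_measurements = length(prep$train$measurements),
    n_test_measurements = length(prep$test$measurements),
    n_excluded = sum(prep$train$flags$flagged) + sum(prep$test$flags$flagged))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)

  invisible(list(out_dir = out, results = results, gate = gate_report,
                 manifest = manifest))
}
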