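#' Agreement metrics about the 1:1 line
#'
#' All metrics measure agreement between predicted and reference percent
#' live about the identity line (not a refitted regression line):
#' `rmse = sqrt(mean((pred - ref)^2))`;
#' `explained_variance = 1 - Var(ref - pred) / Var(ref)` (insensitive to a
#' constant offset); `r_squared = 1 - SS_res / SS_tot` with residuals about
#' the 1:1 line, which is negative when the predictions do worse than the
#' reference mean; `standard_error = sqrt(sum((pred - ref)^2) / (n - 1))`,
#' the residual standard deviation about the 1:1 line that also defines the
#' within-2-SE acceptance band.
#'
#' @param predictions,references Numeric vectors of equal length (>= 2),
#'   invalid predictions excluded upstream.
#' @return List with `rmse`, `explained_variance`, `r_squared`,
#'   `standard_error`, `n`.
#' @export
regression_metrics <- function(predictions, references) {
  if (length(predictions) != length(references)) stop("length mismatch")
  n <- length(predictions)
  if (n < 2) stop("at least 2 points are required")
  resid <- predictions - references
  ss_res <- sum(resid^2)
  ss_tot <- sum((references - mean(references))^2)
  if (stats::var(references) == 0) {
    stop("references have zero variance; explained variance undefined")
  }
  list(rmse = sqrt(mean(resid^2)),
       explained_variance = 1 - stats::var(references - predictions) /
         stats::var(references),
       r_squared = 1 - ss_res / ss_tot,
       standard_error = sqrt(ss_res / (n - 1)),
       n = n)
}

#' Fraction of samples predicted within two standard errors
#'
#' Percentage of samples whose prediction lies within `2 * SE` of the 1:1
#' line (the shaded acceptance band of the validation plots). The
#' comparison is inclusive, so with `SE = 0` only points exactly on the
#' line count.
#'
#' @param predictions,references Numeric vectors.
#' @param standard_error The `standard_error` from the same evaluation.
#' @return Percent in `[0, 100]`.
#' @export
within_2se_fraction <- function(predictions, references, standard_error) {
  if (length(predictions) != length(references)) stop("length mismatch")
  100 * mean(abs(predictions - references) <= 2 * standard_error)
}

#' Bland-Altman agreement between reference and predicted percent live
#'
#' Differences are `d = reference - prediction`; the bias is `mean(d)` and
#' the 95% limits of agreement are `bias +/- 1.96 * sd(d)`. Normality of
#' the differences is checked with the Shapiro-Wilk test (needs n >= 3 and
#' non-constant differences; otherwise `shapiro_p` is `NA`).
#'
#' @param predictions,references Numeric vectors of equal length.
#' @return List with `bias`, `loa_low`, `loa_high`, `sd_diff`,
#'   `shapiro_p`, `n`.
#' @export
bland_altman <- function(predictions, references) {
  if (length(predictions) != length(references)) stop("length mismatch")
  d <- references - predictions
  bias <- mean(d)
  s <- if (length(d) > 1) stats::sd(d) else 0
  shapiro_p <- NA_real_
  if (length(d) >= 3 && length(d) <= 5000 && s > 0) {
    shapiro_p <- stats::shapiro.test(d)$p.value
  }
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, shapiro_p = shapiro_p, n = length(d))
}

#' Train a PCA concentration gate
#'
#' Blind samples must be routed to the calibration model of their
#' concentration class. First-frame spectra of the two classes separate
#' cleanly in the space of the first two principal components, so a
#' nearest-centroid classifier in that score space is used as the gate.
#'
#' @param spectra Matrix of frame-0 spectra, one row per measurement
#'   (preprocessed).
#' @param classes Concentration class per row.
#' @return An object of class `"concentration_gate"` with the PCA centre,
#'   2-component rotation, per-class score centroids and training scores.
#' @export
pca_concentration_gate <- function(spectra, classes) {
  spectra <- as.matrix(spectra)
  classes <- as.character(classes)
  if (nrow(spectra) != length(classes)) stop("one class per spectrum required")
  tab <- table(classes)
  if (length(tab) == 1) {
    warning("single training class: the gate degenerates to a constant classifier")
  } else if (any(tab < 2)) {
    stop("need at least 2 spectra per class")
  }
  pc <- stats::prcomp(spectra, center = TRUE, scale. = FALSE, rank. = 2)
  scores <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  centroids <- do.call(rbind, lapply(split(seq_len(nrow(scores)), classes),
                                     function(i) colMeans(scores[i, , drop = FALSE])))
  structure(list(center = pc$center,
                 rotation = pc$rotation[, seq_len(ncol(scores)), drop = FALSE],
                 centroids = centroids,
                 classes = rownames(centroids),
                 scores = scores, train_classes = classes),
            class = "concentration_gate")
}

#' Classify spectra into concentration classes
#'
#' Projects frame-0 spectra onto the gate's principal components and
#' assigns each to the class of the nearest centroid.
#'
#' @param gate A [pca_concentration_gate()] object.
#' @param spectra Matrix of frame-0 spectra (or a single vector).
#' @return List with `class` (character vector) and `scores` (score
#'   coordinates).
#' @export
classify_concentration <- function(gate, spectra) {
  if (!is.matrix(spectra)) spectra <- matrix(spectra, nrow = 1)
  sc <- sweep(spectra, 2, gate$center) %*% gate$rotation
  d2 <- vapply(seq_len(nrow(gate$centroids)), function(k) {
    rowSums(sweep(sc, 2, gate$centroids[k, ])^2)
  }, numeric(nrow(sc)))
  d2 <- matrix(d2, nrow = nrow(sc))
  list(class = gate$classes[max.col(-d2, ties.method = "first")],
       scores = sc)
}
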