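#' PCA scores and loadings
#'
#' Principal component analysis of a data matrix via singular value
#' decomposition (through [stats::prcomp()]), after centering or
#' autoscaling. A deterministic sign convention is applied: within each
#' component the largest-magnitude loading element is made positive.
#'
#' @param x numeric matrix, samples x variables (>= 2 samples).
#' @param scaling `"center"` (mean centering only, the convention for
#'   derivative spectra) or `"autoscale"` (unit variance, the convention for
#'   GC composition data).
#' @param ncomp maximum number of components returned.
#' @return list with `scores`, `loadings`, `explained` (variance
#'   fractions).
#' @export
pca_scores <- function(x, scaling = c("center", "autoscale"), ncomp = NULL) {
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least 2 samples")
  if (any(!is.finite(x))) stop("PCA input must be finite")
  if (scaling == "autoscale") x <- autoscale(x)$scaled
  pr <- stats::prcomp(x, center = scaling == "center", scale. = FALSE)
  k <- if (is.null(ncomp)) ncol(pr$rotation) else min(ncomp, ncol(pr$rotation))
  scores <- pr$x[, 1:k, drop = FALSE]
  loadings <- pr$rotation[, 1:k, drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings,
       explained = (pr$sdev^2 / sum(pr$sdev^2))[1:k])
}

#' Parsimonious component count from an RMSE curve
#'
#' Implements the rule "the lowest number of components whose RMSE is
#' insignificantly higher than the minimum": with k* the RMSE-minimising
#' count, return the smallest k <= k* with
#' RMSE(k) <= RMSE(k*) + SE(k*), where SE(k*) is the between-segment
#' standard error at the minimum (the one-standard-error convention). With
#' SE = 0 the rule reduces to the argmin; ties break toward fewer
#' components. The result never exceeds the argmin.
#'
#' @param rmse_by_ncomp numeric RMSE per component count.
#' @param se_by_ncomp matching between-segment standard errors (a single
#'   number is recycled).
#' @return integer component count.
#' @export
select_components <- function(rmse_by_ncomp, se_by_ncomp = 0) {
  rmse <- as.numeric(rmse_by_ncomp)
  se <- rep_len(as.numeric(se_by_ncomp), length(rmse))
  if (!length(rmse)) stop("empty RMSE curve")
  k_star <- which.min(rmse)
  threshold <- rmse[k_star] + se[k_star]
  min(which(rmse[seq_len(k_star)] <= threshold))
}

#' Day-segmented cross-validation of a PLS calibration
#'
#' Leave-one-day-out cross-validation: all samples collected on the same
#' cultivation day form one segment; each segment is held out in turn and
#' predicted from a model fitted on the remaining days, for every component
#' count 1..`max_ncomp`. Day segmentation is what makes the error estimate
#' honest here — replicates of the same culture never sit on both sides of
#' a split.
#'
#' When `wavenumbers` is supplied, EMSC is refitted inside every fold: the
#' reference is the mean of the *training* spectra and the held-out day is
#' corrected against it, so no information from the left-out segment leaks
#' into preprocessing (set `emsc_refit = FALSE` to reproduce the simpler
#' global-reference practice: one correction of the full set up front).
#' Model centering is always computed from the training rows only.
#'
#' @param X predictor matrix (for `emsc_refit`, the SG-derivative spectra on
#'   the combined region, *before* EMSC).
#' @param y response vector.
#' @param day per-sample segment labels (cultivation day).
#' @param max_ncomp largest component count scanned (capped by fold rank).
#' @param wavenumbers grid matching `X`'s columns; required for
#'   `emsc_refit = TRUE`.
#' @param emsc_refit refit the EMSC reference per fold (leak-free default)
#'   or correct once globally before splitting.
#' @param emsc_poly_order EMSC polynomial order, see [emsc()].
#' @param response name stored in the result.
#' @return a `cv_result`: `rmse_by_ncomp`, `se_by_ncomp` (between-segment
#'   SE of segment RMSEs), `chosen_ncomp`, `cv_predictions` (`data.frame`
#'   of per-sample prediction at the chosen count plus its held-out
#'   segment), `predictions_by_ncomp`, `segments`.
#' @export
day_segmented_cv <- function(X, y, day, max_ncomp = 25, wavenumbers = NULL,
                             emsc_refit = !is.null(wavenumbers),
                             emsc_poly_order = 2, response = "y") {
  X <- as.matrix(X); y <- as.numeric(y); day <- as.vector(day)
  n <- nrow(X)
  if (length(y) != n || length(day) != n) stop("X, y and day are not aligned")
  days <- unique(day)
  if (length(days) < 2) stop("day-segmented CV needs at least 2 distinct days")
  if (emsc_refit && is.null(wavenumbers)) {
    stop("per-fold EMSC refitting needs the wavenumber grid")
  }
  if (!emsc_refit && !is.null(wavenumbers)) {
    ref <- colMeans(X)
    X <- .emsc_matrix(X, wavenumbers, ref, emsc_poly_order)
  }
  max_ncomp <- min(max_ncomp, ncol(X), n - max(table(day)) - 1)
  if (max_ncomp < 1) stop("a single day contains (almost) all samples; cannot segment")
  pred <- matrix(NA_real_, n, max_ncomp)
  for (d in days) {
    test <- which(day == d); train <- which(day != d)
    Xtr <- X[train, , drop = FALSE]; Xte <- X[test, , drop = FALSE]
    if (emsc_refit) {
      ref <- colMeans(Xtr)
      Xtr <- .emsc_matrix(Xtr, wavenumbers, ref, emsc_poly_order)
      Xte <- .emsc_matrix(Xte, wavenumbers, ref, emsc_poly_order)
    }
    fit <- pls_fit(Xtr, y[train], ncomp = min(max_ncomp, length(train) - 1, ncol(Xtr)))
    for (a in seq_len(max_ncomp)) {
      pred[test, a] <- predict(fit, Xte, ncomp = min(a, fit$n_components))
    }
  }
  err <- pred - y
  rmse <- sqrt(colMeans(err^2))
  seg_rmse <- t(vapply(days, function(d) {
    sqrt(colMeans(err[day == d, , drop = FALSE]^2))
  }, numeric(max_ncomp)))
  se <- apply(seg_rmse, 2, stats::sd) / sqrt(length(days))
  chosen <- select_components(rmse, se)
  structure(list(response = response,
                 rmse_by_ncomp = rmse, se_by_ncomp = se,
                 chosen_ncomp = chosen,
                 cv_predictions = data.frame(observed = y,
                                             predicted = pred[, chosen],
                                             segment = day),
                 predictions_by_ncomp = pred,
                 segment_rmse = seg_rmse, segments = days,
                 max_ncomp = max_ncomp),
            class = "cv_result")
}

# EMSC correction of a bare matrix against a fixed reference (fast path
# used inside CV folds; mirrors emsc())
.emsc_matrix <- function(A, wavenumbers, reference, poly_order = 2) {
  wn <- wavenumbers
  p1 <- (wn - (max(wn) + min(wn)) / 2) / ((max(wn) - min(wn)) / 2)
  D <- matrix(1, length(wn), 1)
  if (poly_order >= 1) D <- cbind(D, p1)
  if (poly_order >= 2) D <- cbind(D, p1^2)
  D <- cbind(D, reference)
  B <- qr.coef(qr(D), t(A))
  b <- B[nrow(B), ]
  if (any(!is.finite(b) | abs(b) < 1e-8)) {
    stop("degenerate EMSC fit inside a CV fold")
  }
  baseline <- D[, -ncol(D), drop = FALSE] %*% B[-nrow(B), , drop = FALSE]
  t((t(A) - baseline) / rep(b, each = length(wn)))
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> response '", x$response, "': ", length(x$segments),
      " day segments, RMSECV(", x$chosen_ncomp, " comp) = ",
      signif(x$rmse_by_ncomp[x$chosen_ncomp], 4), "\n", sep = "")
  invisible(x)
}

#' Calibration quality metrics
#'
#' Table-style summary of one cross-validated calibration: reference range,
#' mean and SD (n - 1), the cross-validated squared Pearson correlation
#' R^2, RMSECV = sqrt(mean squared CV error), and the residual predictive
#' deviation RPD_CV = SD / RMSECV. The identity RPD * RMSECV = SD holds
#' exactly before any rounding; perfect predictions give RMSECV 0, R^2 1
#' and infinite RPD.
#'
#' @param cv a `cv_result`, or a numeric vector of cross-validated
#'   predictions aligned with `y`.
#' @param y reference values; defaults to the observations stored in `cv`.
#' @param pls_factors component count to report (default: the chosen one).
#' @param response response name for the row.
#' @return one-row `data.frame` with columns `response`, `n`, `range_min`,
#'   `range_max`, `mean`, `sd`, `r2_cv`, `rmsecv`, `rpd_cv`,
#'   `pls_factors`.
#' @export
calibration_metrics <- function(cv, y = NULL, pls_factors = NULL,
                                response = NULL) {
  if (inherits(cv, "cv_result")) {
    pred <- cv$cv_predictions$predicted
    if (is.null(y)) y <- cv$cv_predictions$observed
    if (is.null(pls_factors)) pls_factors <- cv$chosen_ncomp
    if (is.null(response)) response <- cv$response
  } else {
    pred <- as.numeric(cv)
    if (is.null(y)) stop("supply the reference values y")
    if (is.null(response)) response <- "y"
  }
  y <- as.numeric(y)
  if (length(pred) != length(y)) stop("predictions and reference are not aligned")
  if (stats::sd(y) == 0) stop("constant reference values: R^2 undefined")
  rmsecv <- sqrt(mean((pred - y)^2))
  r2 <- if (rmsecv == 0) 1 else stats::cor(pred, y)^2
  data.frame(response = response, n = length(y),
             range_min = min(y), range_max = max(y),
             mean = mean(y), sd = stats::sd(y),
             r2_cv = r2, rmsecv = rmsecv,
             rpd_cv = if (rmsecv == 0) Inf else stats::sd(y) / rmsecv,
             pls_factors = if (is.null(pls_factors)) NA_integer_ else pls_factors)
}
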