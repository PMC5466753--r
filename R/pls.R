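#' Partial least squares regression (NIPALS)
#'
#' Latent-variable regression of one or more responses on a highly collinear
#' predictor matrix, computed by the NIPALS algorithm with mean centering of
#' X and Y (no variance scaling of X — spectra share a unit, so autoscaling
#' would inflate noise channels). For a single response the component
#' weights have the closed form w = X'y and no iteration is needed; for
#' multiple responses the score pair is iterated to convergence. The
#' deflated weights are folded into regression coefficients
#' B = W (P'W)^-1 Q' so that prediction is a single affine map.
#'
#' There is no randomness anywhere in the fit path: the NIPALS start vector
#' is the largest-variance response column.
#'
#' @param X numeric predictor matrix, samples x variables.
#' @param y response vector or matrix, row-aligned with `X`.
#' @param ncomp number of latent components, between 1 and
#'   `min(nrow(X) - 1, ncol(X))`. If the predictor residual runs out of rank
#'   earlier, the achieved number of components is kept and reported.
#' @param tol convergence tolerance for the multi-response score iteration.
#' @param max_iter iteration cap per component; exceeding it is an error
#'   naming the component.
#' @return a `pls_model` with elements `n_components`, `x_mean`, `y_mean`,
#'   `x_weights`, `x_loadings`, `y_loadings`, `coefficients`
#'   (variables x responses), `fitted_values`, `scores`.
#' @seealso [day_segmented_cv()] for component selection,
#'   [predict.pls_model()].
#' @export
pls_fit <- function(X, y, ncomp, tol = 1e-12, max_iter = 500) {
  X <- as.matrix(X)
  Y <- as.matrix(y)
  storage.mode(X) <- storage.mode(Y) <- "double"
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != n) stop("X and y are not row-aligned")
  max_rank <- min(n - 1, p)
  if (ncomp < 1 || ncomp > max_rank) {
    stop("ncomp must lie in 1..", max_rank, " (min(n - 1, p))")
  }
  y_sd <- apply(Y, 2, stats::sd)
  if (any(y_sd == 0)) stop("degenerate response: zero variance in column ",
                           paste(which(y_sd == 0), collapse = ", "))
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean); Yc <- sweep(Y, 2, y_mean)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); Q <- matrix(0, q, ncomp)
  Tm <- matrix(0, n, ncomp)
  a <- 0
  for (comp in seq_len(ncomp)) {
    if (q == 1) {
      w <- crossprod(Xc, Yc)[, 1]
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14 * max(1, sqrt(sum(Xc^2)))) break  # no covariance left
      w <- w / nw
      tt <- Xc %*% w
    } else {
      u <- Yc[, which.max(apply(Yc, 2, stats::var)), drop = FALSE]
      tt_old <- NULL
      for (it in seq_len(max_iter)) {
        w <- crossprod(Xc, u)[, 1]
        nw <- sqrt(sum(w^2))
        if (nw < 1e-14) break
        w <- w / nw
        tt <- Xc %*% w
        qq <- crossprod(Yc, tt) / sum(tt^2)
        u <- Yc %*% qq / sum(qq^2)
        if (!is.null(tt_old) && sum((tt - tt_old)^2) < tol * sum(tt^2)) break
        tt_old <- tt
        if (it == max_iter) {
          stop("NIPALS failed to converge in component ", comp)
        }
      }
      if (nw < 1e-14) break
    }
    tsq <- sum(tt^2)
    if (tsq < 1e-28) break
    pp <- crossprod(Xc, tt)[, 1] / tsq
    qq <- crossprod(Yc, tt)[, 1] / tsq
    W[, comp] <- w; P[, comp] <- pp; Q[, comp] <- qq; Tm[, comp] <- tt
    Xc <- Xc - tcrossprod(tt, pp)
    Yc <- Yc - tcrossprod(tt, qq)
    a <- comp
  }
  if (a == 0) {
    # response orthogonal to X (no covariance to model): null model that
    # predicts the response mean everywhere
    W <- matrix(0, p, 0); P <- matrix(0, p, 0); Q <- matrix(0, q, 0)
    Tm <- matrix(0, n, 0)
    B <- matrix(0, p, q)
  } else {
    W <- W[, 1:a, drop = FALSE]; P <- P[, 1:a, drop = FALSE]
    Q <- Q[, 1:a, drop = FALSE]; Tm <- Tm[, 1:a, drop = FALSE]
    B <- W %*% solve(crossprod(P, W), t(Q))
  }
  fitted <- sweep(sweep(X, 2, x_mean) %*% B, 2, y_mean, `+`)
  dimnames(B) <- list(colnames(X), colnames(Y))
  structure(list(n_components = a, requested_components = ncomp,
                 x_mean = x_mean, y_mean = y_mean,
                 x_weights = W, x_loadings = P, y_loadings = Q,
                 coefficients = B, scores = Tm,
                 fitted_values = fitted),
            class = "pls_model")
}

#' Predict from a PLS model
#'
#' \eqn{\hat{y} = (X_{new} - \bar{x}) B + \bar{y}}; prediction is affine in
#' the new spectra.
#'
#' @param object a `pls_model`.
#' @param newdata numeric matrix with the training number of variables.
#' @param ncomp optional smaller number of components to predict with
#'   (coefficients are rebuilt from the stored weight/loading sequence).
#' @param ... unused.
#' @return matrix of predictions (vector drop for a single response).
#' @export
predict.pls_model <- function(object, newdata, ncomp = NULL, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean)) {
    stop("newdata has ", ncol(newdata), " variables; the model was trained on ",
         length(object$x_mean))
  }
  B <- if (is.null(ncomp)) object$coefficients else .pls_coef_at(object, ncomp)
  out <- sweep(sweep(newdata, 2, object$x_mean) %*% B, 2, object$y_mean, `+`)
  if (ncol(out) == 1) as.numeric(out) else out
}

# coefficients truncated to the first `ncomp` components
.pls_coef_at <- function(object, ncomp) {
  a <- min(ncomp, object$n_components)
  if (a == 0) return(object$coefficients * 0)
  W <- object$x_weights[, 1:a, drop = FALSE]
  P <- object$x_loadings[, 1:a, drop = FALSE]
  Q <- object$y_loadings[, 1:a, drop = FALSE]
  W %*% solve(crossprod(P, W), t(Q))
}

#' @export
coef.pls_model <- function(object, ncomp = NULL, ...) {
  if (is.null(ncomp)) object$coefficients else .pls_coef_at(object, ncomp)
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", x$n_components, " components, ", length(x$x_mean),
      " predictors, ", nrow(x$y_loadings), " response(s)\n", sep = "")
  invisible(x)
}
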