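#' Preprocessing configuration
#'
#' Collects the tunable parameters of the spectral preprocessing chain:
#' Savitzky-Golay (SG) differentiation followed by extended multiplicative
#' signal correction (EMSC) on the combined fingerprint + CH-stretch region.
#' Defaults are the settings used throughout the package: SG window 9
#' points, second-degree polynomial, second derivative; EMSC with linear and
#' quadratic baseline terms on 3100-2800 and 1800-500 cm^-1.
#'
#' @param sg_window odd SG window length in grid points.
#' @param sg_polyorder SG polynomial degree.
#' @param sg_deriv derivative order (<= `sg_polyorder`).
#' @param sg_scale logical; include the 1/h^m grid-spacing factor so a
#'   second derivative is in absorbance * cm^2. Disable for cosmetic parity
#'   with vendor software that reports unscaled filter output.
#' @param emsc_regions list of regions `c(high, low)` in cm^-1 forming the
#'   combined EMSC/regression range.
#' @param emsc_poly_order polynomial order of the EMSC baseline model
#'   (0 = classic MSC, 2 = linear + quadratic extension).
#' @param reference optional fixed EMSC reference spectrum (numeric vector on
#'   the combined-region grid); default is the mean of the set being
#'   corrected.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(sg_window = 9, sg_polyorder = 2, sg_deriv = 2,
                              sg_scale = TRUE,
                              emsc_regions = list(c(3100, 2800), c(1800, 500)),
                              emsc_poly_order = 2, reference = NULL) {
  if (sg_window %% 2 != 1 || sg_window <= sg_polyorder) {
    stop("sg_window must be odd and greater than sg_polyorder")
  }
  if (sg_deriv > sg_polyorder) stop("sg_deriv must not exceed sg_polyorder")
  if (!emsc_poly_order %in% 0:2) stop("emsc_poly_order must be 0, 1 or 2")
  structure(list(sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 sg_deriv = as.integer(sg_deriv),
                 sg_scale = isTRUE(sg_scale),
                 emsc_regions = .normalize_regions(emsc_regions),
                 emsc_poly_order = as.integer(emsc_poly_order),
                 reference = reference),
            class = "preprocess_config")
}

#' Savitzky-Golay derivative of a spectrum set
#'
#' Replaces every spectrum by its SG derivative with respect to wavenumber.
#' The filter coefficients come from [signal::sgolay()]; with `scale = TRUE`
#' the grid-spacing factor 1/h^m is included so a second derivative carries
#' units of absorbance * cm^2. Edge points where the full window does not
#' fit are dropped: the grid is trimmed by half a window at each end rather
#' than extended by edge polynomials, so no edge artifact enters the
#' downstream EMSC fit.
#'
#' @param x a `spectrum_set` on a uniform grid (spacing uniform within 1%).
#' @param window,polyorder,deriv,scale see [preprocess_config()].
#' @return a `spectrum_set` on the trimmed grid.
#' @export
sg_derivative <- function(x, window = 9, polyorder = 2, deriv = 2,
                          scale = TRUE) {
  stopifnot(inherits(x, "spectrum_set"))
  wn <- x$wavenumbers
  p <- length(wn)
  if (p < window) stop("SG window (", window, ") larger than the grid (", p, " points)")
  d <- diff(wn)
  h <- abs(stats::median(d))
  if (any(abs(abs(d) - h) > 0.01 * h)) {
    stop("SG derivative requires a uniform wavenumber grid (spacing varies by more than 1%)")
  }
  ts <- if (scale) h else 1
  F <- signal::sgolay(p = polyorder, n = window, m = deriv, ts = ts)
  cc <- F[(window + 1) / 2, ]  # central (steady-state) filter row
  # stored axis is descending; odd derivatives w.r.t. wavenumber change sign
  if (deriv %% 2 == 1 && d[1] < 0) cc <- -cc
  hw <- (window - 1) / 2
  out <- matrix(0, nrow(x$absorbance), p - 2 * hw)
  for (k in seq_len(window)) {
    out <- out + cc[k] * x$absorbance[, k:(p - window + k), drop = FALSE]
  }
  spectrum_set(wn[(hw + 1):(p - hw)], out, x$meta)
}

#' Extended multiplicative signal correction
#'
#' Fits, per sample, the least-squares model
#' \deqn{z = a 1 + c p_1 + d p_2 + b r}
#' where \eqn{r} is the reference spectrum and \eqn{p_1, p_2} are the
#' wavenumber axis mapped affinely onto \eqn{[-1, 1]} and its square
#' (raw wavenumbers squared are numerically hostile, so the polynomial basis
#' is reported in the scaled coordinate). The corrected spectrum is
#' \eqn{(z - a 1 - c p_1 - d p_2) / b}. With `poly_order = 0` the model
#' reduces to classic MSC (offset + scale), with `poly_order = 1` the
#' quadratic term is dropped.
#'
#' The fit runs on the full (combined) grid of `x` as one least-squares
#' problem; restrict `x` with [select_region()] first if correction over a
#' combined sub-range is wanted.
#'
#' @param x a `spectrum_set`.
#' @param reference reference spectrum (numeric, same grid); defaults to the
#'   mean spectrum of `x`.
#' @param poly_order 0, 1 or 2.
#' @param tol samples whose multiplicative coefficient `b` has absolute
#'   value below `tol` are reported as degenerate.
#' @return a list with `spectra` (corrected `spectrum_set`),
#'   `coefficients` (`data.frame` of per-sample `a`, `b`, `c`, `d`;
#'   coefficients not in the model are `NA`) and `reference`.
#' @export
emsc <- function(x, reference = NULL, poly_order = 2, tol = 1e-8) {
  stopifnot(inherits(x, "spectrum_set"))
  if (!poly_order %in% 0:2) stop("poly_order must be 0, 1 or 2")
  wn <- x$wavenumbers
  if (is.null(reference)) reference <- colMeans(x$absorbance)
  reference <- as.numeric(reference)
  if (length(reference) != length(wn)) {
    stop("reference length (", length(reference), ") does not match the grid (",
         length(wn), ")")
  }
  p1 <- (wn - (max(wn) + min(wn)) / 2) / ((max(wn) - min(wn)) / 2)
  D <- cbind(intercept = rep(1, length(wn)))
  if (poly_order >= 1) D <- cbind(D, p1 = p1)
  if (poly_order >= 2) D <- cbind(D, p2 = p1^2)
  D <- cbind(D, reference = reference)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    stop("EMSC design matrix is rank deficient (is the reference a polynomial baseline?)")
  }
  B <- qr.coef(qrD, t(x$absorbance))       # (poly terms + b) x n
  b <- B[nrow(B), ]
  bad <- !is.finite(b) | abs(b) < tol
  if (any(bad)) {
    stop("degenerate EMSC fit (|b| < ", tol, ") for sample(s): ",
         paste(x$meta$sample_id[bad], collapse = ", "))
  }
  baseline <- D[, -ncol(D), drop = FALSE] %*% B[-nrow(B), , drop = FALSE]
  corrected <- t((t(x$absorbance) - baseline) / rep(b, each = length(wn)))
  coefs <- data.frame(sample_id = x$meta$sample_id,
                      a = B["intercept", ],
                      b = b,
                      c = if (poly_order >= 1) B["p1", ] else NA_real_,
                      d = if (poly_order >= 2) B["p2", ] else NA_real_,
                      row.names = NULL)
  list(spectra = spectrum_set(wn, corrected, x$meta),
       coefficients = coefs,
       reference = reference)
}

#' Full spectral preprocessing pipeline
#'
#' Applies, in this order: (1) averaging of technical replicates (skipped
#' when every `tech_rep` is already the averaged marker `NA`), (2) SG
#' derivative, (3) restriction to the combined EMSC regions, (4) EMSC. The
#' output grid is therefore the combined-region subset of the SG-trimmed
#' grid.
#'
#' @param x a raw `spectrum_set` (technical replicates or already averaged).
#' @param config a [preprocess_config()].
#' @return a list with `spectra` (preprocessed `spectrum_set`),
#'   `emsc_coefficients`, and `reference` (the EMSC reference actually used;
#'   pass it back via `config$reference` to correct new samples against a
#'   training set).
#' @export
preprocess_spectra <- function(x, config = preprocess_config()) {
  stopifnot(inherits(x, "spectrum_set"), inherits(config, "preprocess_config"))
  if (any(!is.na(x$meta$tech_rep))) {
    x <- average_technical_replicates(x)
  }
  x <- sg_derivative(x, window = config$sg_window,
                     polyorder = config$sg_polyorder,
                     deriv = config$sg_deriv, scale = config$sg_scale)
  x <- select_region(x, config$emsc_regions)
  res <- emsc(x, reference = config$reference,
              poly_order = config$emsc_poly_order)
  list(spectra = res$spectra, emsc_coefficients = res$coefficients,
       reference = res$reference)
}
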