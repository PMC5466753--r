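#' Assemble aligned spectra / reference data for calibration
#'
#' Joins a spectrum set to a GC fatty-acid table on
#' (species, temperature, day): one GC composition row (a per-condition
#' average) serves as the reference value for every biological replicate
#' spectrum of that condition-day. Optionally removes excluded
#' condition-days (all their biological replicates) before the join —
#' e.g. early-growth samples whose biomass is not yet representative.
#'
#' @param spectra a `spectrum_set` of averaged spectra (technical
#'   replicates are averaged here if still present).
#' @param gc a [fatty_acid_table()] keyed by `species`, `temperature`,
#'   `day`.
#' @param exclude optional `data.frame` with columns `species`,
#'   `temperature`, `day`: condition-days to drop.
#' @param catalogue fatty acid descriptor catalogue.
#' @return list with `spectra` (the retained, averaged `spectrum_set`),
#'   `Y` (`data.frame` of per-spectrum reference parameters from
#'   [fatty_acid_parameters()]), `n_before` / `n_after` (spectrum counts
#'   around the exclusion filter).
#' @export
assemble_calibration_data <- function(spectra, gc, exclude = NULL,
                                      catalogue = fatty_acid_catalogue()) {
  stopifnot(inherits(spectra, "spectrum_set"), inherits(gc, "fatty_acid_table"))
  if (any(!is.na(spectra$meta$tech_rep))) {
    spectra <- average_technical_replicates(spectra)
  }
  n_before <- n_samples(spectra)
  if (!is.null(exclude) && nrow(exclude <- as.data.frame(exclude))) {
    need <- c("species", "temperature", "day")
    if (!all(need %in% names(exclude))) {
      stop("exclude needs columns species, temperature, day")
    }
    ex_key <- do.call(paste, c(exclude[need], sep = "|"))
    sp_key <- do.call(paste, c(spectra$meta[need], sep = "|"))
    spectra <- spectra[!(sp_key %in% ex_key)]
    message("exclusion filter: ", n_before, " -> ", n_samples(spectra),
            " spectra")
  }
  params <- fatty_acid_parameters(gc, catalogue)
  gc_key <- do.call(paste, c(gc$meta[c("species", "temperature", "day")], sep = "|"))
  sp_key <- do.call(paste,
                    c(spectra$meta[c("species", "temperature", "day")], sep = "|"))
  j <- match(sp_key, gc_key)
  if (anyNA(j)) {
    stop("spectra without a matching GC reference row: ",
         paste(utils::head(spectra$meta$sample_id[is.na(j)], 8), collapse = ", "))
  }
  list(spectra = spectra, Y = params[j, , drop = FALSE],
       n_before = n_before, n_after = n_samples(spectra))
}

#' Calibrate fatty acid parameters against FTIR spectra
#'
#' The central fitting function: builds one PLS1 calibration per response
#' linking preprocessed biomass spectra (X) to GC fatty-acid reference
#' values (Y), with leave-one-day-out cross-validation for component
#' selection and honest error estimation.
#'
#' The chain is: average technical replicates, Savitzky-Golay second
#' derivative, restriction to the combined 3100-2800 + 1800-500 cm^-1
#' range, EMSC, mean-centered NIPALS PLS. During cross-validation the EMSC
#' reference and all centering are recomputed from the training days only
#' and applied to the held-out day, so the reported RMSECV is leak-free.
#' The final per-response models are refitted on all retained samples, at
#' the component count chosen by the one-standard-error rule, with the
#' full-data EMSC reference stored for predicting new spectra.
#'
#' One PLS1 model per response (rather than one PLS2 model for all) is the
#' default because different responses genuinely need different model
#' complexity.
#'
#' @param spectra raw `spectrum_set` (technical replicates welcome).
#' @param gc [fatty_acid_table()] keyed by (species, temperature, day).
#' @param responses character vector of response names: fatty acid ids
#'   present in `gc` and/or the derived parameters `"SAT"`, `"MUFA"`,
#'   `"PUFA"`, `"unsaturation_index"`, `"total_lipid"`.
#' @param exclude optional condition-day exclusion table, see
#'   [assemble_calibration_data()].
#' @param max_ncomp largest PLS component count scanned (default 25).
#' @param config a [preprocess_config()].
#' @param emsc_refit per-fold EMSC reference (default) or one global
#'   correction before cross-validation.
#' @param catalogue fatty acid descriptor catalogue.
#' @return an object of class `ftir_calibration`: `report` (one
#'   [calibration_metrics()] row per response), `cv` (named list of
#'   `cv_result`), `models` (final `pls_model` per response), `reference`
#'   (full-data EMSC reference), `X`, `wavenumbers`, `Y`, `meta`,
#'   `config`, `call`.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_experiment(seed = 1)
#' cal <- ftir_calibration(sim$spectra, sim$gc,
#'                         responses = c("unsaturation_index", "PUFA"))
#' print(cal)
#' }
ftir_calibration <- function(spectra, gc, responses,
                             exclude = NULL, max_ncomp = 25,
                             config = preprocess_config(),
                             emsc_refit = TRUE,
                             catalogue = fatty_acid_catalogue()) {
  cl <- match.call()
  dat <- assemble_calibration_data(spectra, gc, exclude = exclude,
                                   catalogue = catalogue)
  missing_resp <- setdiff(responses, names(dat$Y))
  if (length(missing_resp)) {
    stop("response(s) not available in the GC table: ",
         paste(missing_resp, collapse = ", "))
  }
  s <- dat$spectra
  s <- sg_derivative(s, window = config$sg_window,
                     polyorder = config$sg_polyorder,
                     deriv = config$sg_deriv, scale = config$sg_scale)
  s <- select_region(s, config$emsc_regions)
  X <- s$absorbance
  wn <- s$wavenumbers
  day <- s$meta$day
  cv_list <- list()
  rows <- list()
  models <- list()
  full <- emsc(s, reference = config$reference,
               poly_order = config$emsc_poly_order)
  for (r in responses) {
    y <- dat$Y[[r]]
    cv <- day_segmented_cv(X, y, day, max_ncomp = max_ncomp,
                           wavenumbers = wn, emsc_refit = emsc_refit,
                           emsc_poly_order = config$emsc_poly_order,
                           response = r)
    cv_list[[r]] <- cv
    rows[[r]] <- calibration_metrics(cv)
    models[[r]] <- pls_fit(full$spectra$absorbance, y,
                           ncomp = cv$chosen_ncomp)
  }
  structure(list(report = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 cv = cv_list, models = models,
                 reference = full$reference,
                 emsc_coefficients = full$emsc_coefficients,
                 X = X, wavenumbers = wn,
                 Y = dat$Y, meta = s$meta,
                 n_before = dat$n_before, n_after = dat$n_after,
                 config = config, emsc_refit = emsc_refit,
                 responses = responses, call = cl),
            class = "ftir_calibration")
}

# Table-style rounding: SD/RMSECV/RPD to 1 decimal, R^2 to 2, but keep
# enough digits for small-magnitude responses like the unsaturation index
.round_report <- function(report) {
  fmt <- function(v) {
    ifelse(abs(v) < 5, signif(v, 3), round(v, 1))
  }
  data.frame(response = report$response,
             n = report$n,
             range = paste0(fmt(report$range_min), "-", fmt(report$range_max)),
             mean = fmt(report$mean),
             sd = fmt(report$sd),
             r2 = round(report$r2_cv, 2),
             rmsecv = fmt(report$rmsecv),
             rpd_cv = round(report$rpd_cv, 1),
             factors = report$pls_factors)
}

#' @export
print.ftir_calibration <- function(x, ...) {
  cat("FTIR / GC fatty-acid PLS calibration\n")
  cat("  spectra used: ", x$n_after,
      if (x$n_after != x$n_before) paste0(" (of ", x$n_before, " before exclusion)"),
      "; predictors: ", ncol(x$X), " wavenumbers; CV segments: ",
      length(unique(x$meta$day)), " days\n\n", sep = "")
  print(.round_report(x$report), row.names = FALSE)
  invisible(x)
}

#' @export
summary.ftir_calibration <- function(object, ...) {
  structure(list(report = object$report,
                 n_before = object$n_before, n_after = object$n_after,
                 n_vars = ncol(object$X),
                 days = sort(unique(object$meta$day)),
                 emsc_refit = object$emsc_refit,
                 config = object$config, call = object$call),
            class = "summary.ftir_calibration")
}

#' @export
print.summary.ftir_calibration <- function(x, ...) {
  cat("Call: "); print(x$call)
  cat("Samples:", x$n_after, "of", x$n_before, "spectra retained\n")
  cat("Predictors:", x$n_vars, "wavenumbers on the combined region\n")
  cat("CV: leave-one-day-out over days",
      paste(range(x$days), collapse = "-"),
      if (x$emsc_refit) "(EMSC reference refitted per fold)\n" else
        "(global EMSC reference)\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ftir_calibration <- function(object, ...) {
  B <- vapply(object$models, function(m) m$coefficients[, 1],
              numeric(ncol(object$X)))
  rownames(B) <- format(object$wavenumbers, trim = TRUE)
  B
}

#' Predict fatty acid parameters for new spectra
#'
#' New raw spectra are pushed through the training preprocessing chain —
#' replicate averaging, SG derivative, region selection, EMSC against the
#' *training* reference — and each stored PLS model is applied.
#'
#' @param object an `ftir_calibration`.
#' @param newdata a raw (or equally averaged) `spectrum_set` on the training
#'   grid.
#' @param ... unused.
#' @return matrix samples x responses.
#' @export
predict.ftir_calibration <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "spectrum_set"))
  cfg <- object$config
  if (any(!is.na(newdata$meta$tech_rep))) {
    newdata <- average_technical_replicates(newdata)
  }
  s <- sg_derivative(newdata, window = cfg$sg_window,
                     polyorder = cfg$sg_polyorder,
                     deriv = cfg$sg_deriv, scale = cfg$sg_scale)
  s <- select_region(s, cfg$emsc_regions)
  if (!isTRUE(all.equal(s$wavenumbers, object$wavenumbers))) {
    stop("newdata grid does not match the training grid")
  }
  corr <- emsc(s, reference = object$reference,
               poly_order = cfg$emsc_poly_order)
  out <- vapply(object$models,
                function(m) as.numeric(predict(m, corr$spectra$absorbance)),
                numeric(n_samples(s)))
  if (!is.matrix(out)) out <- matrix(out, nrow = 1,
                                     dimnames = list(NULL, names(object$models)))
  rownames(out) <- s$meta$sample_id
  out
}

#' @export
fitted.ftir_calibration <- function(object, ...) {
  vapply(object$models, function(m) m$fitted_values[, 1],
         numeric(nrow(object$X)))
}

#' Residuals of an FTIR calibration
#'
#' @param object an `ftir_calibration`.
#' @param type `"cv"` (reference minus cross-validated prediction; the
#'   honest residuals) or `"training"` (final-model fit).
#' @param ... unused.
#' @return matrix samples x responses.
#' @export
residuals.ftir_calibration <- function(object, type = c("cv", "training"), ...) {
  type <- match.arg(type)
  if (type == "training") {
    y <- as.matrix(object$Y[object$responses])
    return(y - fitted(object))
  }
  vapply(object$cv,
         function(cv) cv$cv_predictions$observed - cv$cv_predictions$predicted,
         numeric(nrow(object$X)))
}

#' Plot an FTIR calibration
#'
#' `type = "rmse"` draws the cross-validated RMSE against the number of PLS
#' components with the chosen count marked; `type = "prediction"` draws
#' cross-validated predictions against the GC reference values with the 1:1
#' line.
#'
#' @param x an `ftir_calibration`.
#' @param type `"rmse"` or `"prediction"`.
#' @param responses subset of responses to draw (default: all).
#' @param ... passed to the underlying plot calls.
#' @export
plot.ftir_calibration <- function(x, type = c("rmse", "prediction"),
                                  responses = NULL, ...) {
  type <- match.arg(type)
  responses <- if (is.null(responses)) names(x$cv) else responses
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(responses)))
  on.exit(graphics::par(old))
  for (r in responses) {
    cv <- x$cv[[r]]
    if (type == "rmse") {
      graphics::plot(seq_along(cv$rmse_by_ncomp), cv$rmse_by_ncomp,
                     type = "b", xlab = "PLS components", ylab = "RMSECV",
                     main = r, ...)
      graphics::abline(v = cv$chosen_ncomp, lty = 2)
    } else {
      p <- cv$cv_predictions
      graphics::plot(p$observed, p$predicted, xlab = "GC reference",
                     ylab = "CV prediction", main = r, ...)
      graphics::abline(0, 1, lty = 2)
    }
  }
  invisible(x)
}
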