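#' Run a pipeline stage from a configuration
#'
#' Reproducible orchestration of the analysis stages over plain-text
#' artifacts. `config` is a YAML file (or an equivalent named list) holding
#' input paths, the metadata dialect, preprocessing settings, band
#' definitions, the response list, exclusions and the output directory.
#' Every stage writes CSV outputs plus a JSON run manifest (configuration
#' digest, package and R versions, seed, row counts) into `outdir`, logs
#' every filter with before/after counts, and never mutates its inputs.
#'
#' Commands:
#' \describe{
#'   \item{simulate}{draw a synthetic experiment; write `spectra.csv`,
#'     `spectra_meta.csv`, `gc.csv`, `glucose.csv`, `truth.csv`.}
#'   \item{preprocess}{read spectra, run the preprocessing chain; write
#'     `preprocessed.csv` and `emsc_coefficients.csv`.}
#'   \item{bands}{write ester-carbonyl trend curves (`lipid_trend.csv`) and
#'     olefinic peak positions (`peak_positions.csv`) from preprocessed
#'     spectra.}
#'   \item{calibrate}{join spectra and GC table, fit [ftir_calibration()];
#'     write `calibration_report.csv` and `cv_predictions.csv`.}
#'   \item{report}{`calibrate` plus a formatted text table
#'     (`calibration_report.txt`).}
#' }
#'
#' @param config path to a YAML file or a named list. Recognised keys:
#'   `spectra`, `spectra_meta`, `gc`, `glucose` (input paths), `id_pattern`,
#'   `responses`, `exclude` (list of species/temperature/day records),
#'   `max_ncomp`, `outdir`, `seed`, `sg` (`window`, `polyorder`, `deriv`),
#'   `emsc` (`regions`, `poly_order`), `simulate` (generator overrides:
#'   `noise`, `additive_sd`).
#' @param command one of `"simulate"`, `"preprocess"`, `"bands"`,
#'   `"calibrate"`, `"report"`.
#' @param outdir overrides `config$outdir`.
#' @param seed overrides `config$seed`.
#' @return invisibly, a list of the artifact paths written.
#' @export
run_pipeline <- function(config,
                         command = c("simulate", "preprocess", "bands",
                                     "calibrate", "report"),
                         outdir = NULL, seed = NULL) {
  command <- match.arg(command)
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else as.list(config)
  outdir <- outdir %||% cfg$outdir %||% "."
  seed <- seed %||% cfg$seed %||% 1
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  counts <- list()
  emit <- function(df, name, writer = utils::write.csv) {
    path <- file.path(outdir, name)
    writer(df, path)
    artifacts <<- c(artifacts, path)
    path
  }
  pcfg <- .pipeline_preprocess_config(cfg)
  if (command == "simulate") {
    sim_over <- cfg$simulate %||% list()
    scfg_args <- sim_over[intersect(names(sim_over),
                                    names(formals(synthetic_config)))]
    scfg <- do.call(synthetic_config, scfg_args)
    sim <- simulate_experiment(scfg, seed = seed,
                               noise = !isFALSE(sim_over$noise))
    message("INFO simulate: ", n_samples(sim$spectra), " technical spectra, ",
            nrow(sim$gc$composition), " GC condition-days")
    write_spectra(sim$spectra, file.path(outdir, "spectra.csv"),
                  meta_path = file.path(outdir, "spectra_meta.csv"))
    artifacts <- c(artifacts, file.path(outdir, c("spectra.csv", "spectra_meta.csv")))
    write_fatty_acid_table(sim$gc, file.path(outdir, "gc.csv"))
    artifacts <- c(artifacts, file.path(outdir, "gc.csv"))
    emit(sim$glucose, "glucose.csv", function(d, p) utils::write.csv(d, p, row.names = FALSE))
    emit(sim$truth, "truth.csv", function(d, p) utils::write.csv(d, p, row.names = FALSE))
    counts <- list(technical_spectra = n_samples(sim$spectra),
                   gc_rows = nrow(sim$gc$composition))
  } else {
    spectra <- .pipeline_read_spectra(cfg)
    if (command %in% c("preprocess", "bands")) {
      pre <- preprocess_spectra(spectra, pcfg)
      message("INFO preprocess: ", n_samples(spectra), " -> ",
              n_samples(pre$spectra), " spectra on ",
              length(pre$spectra$wavenumbers), " grid points")
      counts <- list(spectra_in = n_samples(spectra),
                     spectra_out = n_samples(pre$spectra))
      if (command == "preprocess") {
        write_spectra(pre$spectra, file.path(outdir, "preprocessed.csv"),
                      meta_path = file.path(outdir, "preprocessed_meta.csv"))
        artifacts <- c(artifacts,
                       file.path(outdir, c("preprocessed.csv", "preprocessed_meta.csv")))
        emit(pre$emsc_coefficients, "emsc_coefficients.csv",
             function(d, p) utils::write.csv(d, p, row.names = FALSE))
      } else {
        trend <- lipid_trend(pre$spectra)
        emit(trend, "lipid_trend.csv",
             function(d, p) utils::write.csv(d, p, row.names = FALSE))
        pos <- peak_position(pre$spectra, lipid_bands()$olefinic)
        emit(data.frame(sample_id = names(pos), olefinic_position = pos),
             "peak_positions.csv",
             function(d, p) utils::write.csv(d, p, row.names = FALSE))
      }
    } else {
      if (is.null(cfg$gc)) stop("calibrate needs a gc input path")
      if (!file.exists(cfg$gc)) stop("GC table not found: ", cfg$gc)
      gc <- read_fatty_acid_table(cfg$gc)
      responses <- unlist(cfg$responses)
      if (!length(responses)) stop("calibrate needs a non-empty response list")
      exclude <- if (!is.null(cfg$exclude)) {
        do.call(rbind, lapply(cfg$exclude, as.data.frame))
      }
      cal <- ftir_calibration(spectra, gc, responses = responses,
                              exclude = exclude,
                              max_ncomp = cfg$max_ncomp %||% 25,
                              config = pcfg)
      message("INFO calibrate: ", cal$n_before, " -> ", cal$n_after,
              " spectra used for regression")
      counts <- list(spectra_before = cal$n_before, spectra_after = cal$n_after)
      emit(cal$report, "calibration_report.csv",
           function(d, p) utils::write.csv(d, p, row.names = FALSE))
      cvp <- do.call(rbind, lapply(names(cal$cv), function(r) {
        cbind(response = r, cal$cv[[r]]$cv_predictions)
      }))
      emit(cvp, "cv_predictions.csv",
           function(d, p) utils::write.csv(d, p, row.names = FALSE))
      if (command == "report") {
        path <- file.path(outdir, "calibration_report.txt")
        writeLines(c("FTIR / GC fatty-acid PLS calibration",
                     utils::capture.output(print(.round_report(cal$report),
                                                 row.names = FALSE))),
                   path)
        artifacts <- c(artifacts, path)
      }
    }
  }
  manifest <- list(command = command,
                   seed = seed,
                   config_digest = .config_digest(cfg),
                   package_version = as.character(utils::packageVersion("ftirlipids")),
                   r_version = R.version.string,
                   counts = counts,
                   artifacts = basename(artifacts))
  manifest_path <- file.path(outdir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(artifacts, manifest_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.pipeline_preprocess_config <- function(cfg) {
  sg <- cfg$sg %||% list()
  em <- cfg$emsc %||% list()
  regions <- if (!is.null(em$regions)) {
    lapply(em$regions, as.numeric)
  } else list(c(3100, 2800), c(1800, 500))
  preprocess_config(sg_window = sg$window %||% 9,
                    sg_polyorder = sg$polyorder %||% 2,
                    sg_deriv = sg$deriv %||% 2,
                    emsc_regions = regions,
                    emsc_poly_order = em$poly_order %||% 2)
}

.pipeline_read_spectra <- function(cfg) {
  if (is.null(cfg$spectra)) stop("config is missing the spectra input path")
  if (!file.exists(cfg$spectra)) stop("spectra file not found: ", cfg$spectra)
  read_spectra(cfg$spectra,
               meta = cfg$spectra_meta,
               id_pattern = cfg$id_pattern %||%
                 if (is.null(cfg$spectra_meta)) .default_id_pattern)
}

# order-independent digest of the configuration actually used
.config_digest <- function(cfg) {
  cfg <- cfg[order(names(cfg))]
  txt <- paste(utils::capture.output(utils::str(cfg, give.attr = FALSE)),
               collapse = "\n")
  f <- tempfile(); on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}
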