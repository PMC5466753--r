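#' Spectrum set: absorbance matrix on a shared wavenumber grid
#'
#' A `spectrum_set` bundles an absorbance matrix (samples in rows) with the
#' common wavenumber grid and per-sample metadata. The grid is stored in
#' descending order (4000 -> 500 cm^-1, the spectrometer convention); all
#' downstream selection is by wavenumber value, never by raw index. An
#' ascending grid is accepted and flipped (absorbance columns reordered
#' consistently).
#'
#' @param wavenumbers numeric vector of wavenumbers in cm^-1, strictly
#'   monotone, no missing values.
#' @param absorbance numeric matrix, one row per sample, one column per
#'   wavenumber (a single spectrum may be given as a vector).
#' @param meta optional `data.frame` of per-sample metadata. Recognised
#'   columns: `sample_id`, `species`, `temperature` (degrees C), `day`
#'   (cultivation day), `bio_rep`, `tech_rep`. Missing columns are filled
#'   with `NA`; a missing `sample_id` is generated. `tech_rep = NA` marks
#'   spectra that are averages over technical replicates.
#'
#' @return An object of class `spectrum_set` with elements `wavenumbers`,
#'   `absorbance` and `meta`.
#' @export
spectrum_set <- function(wavenumbers, absorbance, meta = NULL) {
  wavenumbers <- as.numeric(wavenumbers)
  if (is.null(dim(absorbance))) {
    absorbance <- matrix(as.numeric(absorbance), nrow = 1)
  }
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (anyNA(wavenumbers)) {
    stop("wavenumbers contain missing values")
  }
  d <- diff(wavenumbers)
  if (length(wavenumbers) > 1 && !(all(d > 0) || all(d < 0))) {
    stop("wavenumber grid must be strictly monotone")
  }
  if (length(wavenumbers) > 1 && all(d > 0)) {
    wavenumbers <- rev(wavenumbers)
    absorbance <- absorbance[, rev(seq_len(ncol(absorbance))), drop = FALSE]
  }
  if (ncol(absorbance) != length(wavenumbers)) {
    stop("absorbance has ", ncol(absorbance), " columns but the grid has ",
         length(wavenumbers), " wavenumbers")
  }
  if (anyNA(absorbance)) {
    stop("absorbance matrix contains missing values")
  }
  meta <- .complete_meta(meta, nrow(absorbance))
  rownames(absorbance) <- meta$sample_id
  colnames(absorbance) <- NULL
  x <- structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                      meta = meta),
                 class = "spectrum_set")
  .validate_meta_keys(x)
  x
}

.meta_columns <- c("sample_id", "species", "temperature", "day",
                   "bio_rep", "tech_rep")

.complete_meta <- function(meta, n) {
  if (is.null(meta)) {
    meta <- data.frame(sample_id = if (n) paste0("S", seq_len(n)) else character(0))
  }
  meta <- as.data.frame(meta)
  if (nrow(meta) != n) {
    stop("metadata has ", nrow(meta), " rows but the matrix has ", n, " samples")
  }
  if (is.null(meta$sample_id)) meta$sample_id <- paste0("S", seq_len(n))
  meta$sample_id <- as.character(meta$sample_id)
  for (col in setdiff(.meta_columns, "sample_id")) {
    if (is.null(meta[[col]])) meta[[col]] <- rep(NA, n)
  }
  for (col in c("temperature", "day", "bio_rep", "tech_rep")) {
    meta[[col]] <- suppressWarnings(as.numeric(meta[[col]]))
  }
  ok_day <- is.na(meta$day) | meta$day >= 1
  ok_rep <- is.na(meta$bio_rep) | meta$bio_rep >= 1
  if (!all(ok_day)) stop("cultivation day must be >= 1")
  if (!all(ok_rep)) stop("bio_rep must be >= 1")
  rownames(meta) <- NULL
  meta[union(.meta_columns, names(meta))]
}

.validate_meta_keys <- function(x) {
  m <- x$meta
  if (anyDuplicated(m$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(m$sample_id[duplicated(m$sample_id)]), collapse = ", "))
  }
  key_cols <- c("species", "temperature", "day", "bio_rep", "tech_rep")
  complete <- stats::complete.cases(m[key_cols])
  if (any(complete)) {
    key <- do.call(paste, c(m[complete, key_cols, drop = FALSE], sep = "|"))
    if (anyDuplicated(key)) {
      stop("duplicate (species, temperature, day, bio_rep, tech_rep) keys: ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
    }
  }
  invisible(x)
}

#' @export
print.spectrum_set <- function(x, ...) {
  wn <- x$wavenumbers
  cat("<spectrum_set> ", nrow(x$absorbance), " spectra x ", length(wn),
      " wavenumbers (", format(max(wn)), "-", format(min(wn)), " cm^-1)\n",
      sep = "")
  shown <- x$meta[, c("sample_id", "species", "temperature", "day",
                      "bio_rep", "tech_rep")]
  print(utils::head(shown, 6))
  if (nrow(shown) > 6) cat("... and", nrow(shown) - 6, "more samples\n")
  invisible(x)
}

#' @export
`[.spectrum_set` <- function(x, i, ...) {
  spectrum_set(x$wavenumbers, x$absorbance[i, , drop = FALSE],
               x$meta[i, , drop = FALSE])
}

#' Number of samples in a spectrum set
#' @param x a `spectrum_set`.
#' @return integer sample count.
#' @export
n_samples <- function(x) nrow(x$absorbance)

#' Parse sample identifiers into metadata fields
#'
#' Applies a Perl regular expression with named capture groups (any of
#' `species`, `temperature`, `day`, `bio_rep`, `tech_rep`) to a vector of
#' sample ids. This is the configurable "dialect" used when a spectra table
#' carries its design information in the id string, e.g.
#' `"Mc_T20_d01_b1_t2"`.
#'
#' @param ids character vector of sample ids.
#' @param pattern Perl regex with named capture groups.
#' @return `data.frame` with `sample_id` plus one column per capture group.
#' @export
#' @examples
#' parse_sample_ids("Mc_T20_d01_b1_t2",
#'   "^(?<species>[^_]+)_T(?<temperature>\\d+)_d(?<day>\\d+)_b(?<bio_rep>\\d+)_t(?<tech_rep>\\d+)$")
parse_sample_ids <- function(ids, pattern) {
  m <- regexpr(pattern, ids, perl = TRUE)
  if (any(m == -1)) {
    stop("sample ids do not match the id pattern: ",
         paste(utils::head(ids[m == -1], 3), collapse = ", "))
  }
  st <- attr(m, "capture.start")
  len <- attr(m, "capture.length")
  if (is.null(st)) stop("id pattern has no named capture groups")
  out <- data.frame(sample_id = as.character(ids))
  for (g in colnames(st)) {
    if (!nzchar(g)) next
    out[[g]] <- substr(ids, st[, g], st[, g] + len[, g] - 1)
  }
  out
}

# default id dialect used by the synthetic generator
.default_id_pattern <- paste0("^(?<species>[^_]+)_T(?<temperature>[0-9.]+)",
                              "_d(?<day>\\d+)_b(?<bio_rep>\\d+)",
                              "(?:_t(?<tech_rep>\\d+))?$")

#' Read a spectra table
#'
#' Reads FTIR spectra from a plain-text table. Two layouts are supported:
#' `"wide"` (first column `sample_id`, remaining columns one per wavenumber
#' with numeric headers in cm^-1) and `"long"` (columns `sample_id`,
#' `wavenumber`, `absorbance`). Metadata may come from a sidecar CSV keyed by
#' `sample_id`, or be parsed out of the ids with `id_pattern`.
#'
#' @param path path to a CSV/TSV file.
#' @param format `"wide"` or `"long"`.
#' @param sep field separator (default `","`).
#' @param meta optional metadata: a `data.frame` or the path of a CSV keyed
#'   by `sample_id`.
#' @param id_pattern optional Perl regex with named groups, see
#'   [parse_sample_ids()].
#' @return a [spectrum_set()]; the grid is coerced to descending order.
#' @export
read_spectra <- function(path, format = c("wide", "long"), sep = ",",
                         meta = NULL, id_pattern = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("spectra file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      fill = FALSE, stringsAsFactors = FALSE,
                      comment.char = ""),
    error = function(e) stop("malformed spectra table (", conditionMessage(e),
                             ")", call. = FALSE))
  if (format == "wide") {
    if (ncol(df) < 2) stop("wide spectra table needs sample_id plus wavenumber columns")
    wn <- suppressWarnings(as.numeric(names(df)[-1]))
    if (anyNA(wn)) {
      bad <- names(df)[-1][is.na(wn)]
      stop("non-numeric wavenumber header: ", paste(utils::head(bad, 5), collapse = ", "))
    }
    ids <- as.character(df[[1]])
    a <- as.matrix(df[, -1, drop = FALSE])
    if (nrow(a) == 0) storage.mode(a) <- "double"
    if (!is.numeric(a)) stop("non-numeric absorbance values in spectra table")
  } else {
    need <- c("sample_id", "wavenumber", "absorbance")
    if (!all(need %in% names(df))) {
      stop("long spectra table needs columns: ", paste(need, collapse = ", "))
    }
    ids <- unique(as.character(df$sample_id))
    wn <- sort(unique(as.numeric(df$wavenumber)), decreasing = TRUE)
    a <- matrix(NA_real_, length(ids), length(wn))
    ri <- match(as.character(df$sample_id), ids)
    ci <- match(as.numeric(df$wavenumber), wn)
    a[cbind(ri, ci)] <- as.numeric(df$absorbance)
    if (anyNA(a)) stop("long spectra table does not cover a complete grid for every sample")
  }
  md <- data.frame(sample_id = ids)
  if (!is.null(id_pattern)) md <- parse_sample_ids(ids, id_pattern)
  if (!is.null(meta)) {
    mdf <- if (is.character(meta)) utils::read.csv(meta, stringsAsFactors = FALSE) else as.data.frame(meta)
    if (is.null(mdf$sample_id)) stop("metadata must contain a sample_id column")
    j <- match(ids, as.character(mdf$sample_id))
    if (anyNA(j)) {
      stop("metadata missing for samples: ",
           paste(utils::head(ids[is.na(j)], 5), collapse = ", "))
    }
    md <- cbind(md["sample_id"], mdf[j, setdiff(names(mdf), "sample_id"), drop = FALSE])
  }
  spectrum_set(wn, a, md)
}

#' Write a spectra table
#'
#' Writes the wide CSV layout read by [read_spectra()] (first column
#' `sample_id`, numeric wavenumber headers) at full double precision, so a
#' read/write round trip reproduces the matrix to better than 1e-10.
#' Metadata beyond the sample id goes in a sidecar file if `meta_path` is
#' given.
#'
#' @param x a `spectrum_set`.
#' @param path destination CSV path.
#' @param meta_path optional path for a metadata CSV keyed by `sample_id`.
#' @return `x`, invisibly.
#' @export
write_spectra <- function(x, path, meta_path = NULL) {
  stopifnot(inherits(x, "spectrum_set"))
  a <- x$absorbance
  df <- data.frame(sample_id = x$meta$sample_id, a, check.names = FALSE)
  names(df) <- c("sample_id", format(x$wavenumbers, digits = 15, trim = TRUE))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write spectra table to ", path)
  if (!is.null(meta_path)) {
    utils::write.csv(x$meta, meta_path, row.names = FALSE, quote = FALSE)
  }
  invisible(x)
}

#' Select wavenumber regions
#'
#' Keeps exactly the grid points falling inside one of the given regions,
#' bounds inclusive (the field writes closed ranges such as 3100-2800
#' cm^-1). The descending grid order is preserved across concatenated
#' regions; sample metadata is untouched.
#'
#' @param x a `spectrum_set`.
#' @param regions a single region `c(high, low)` in cm^-1, or a list of
#'   such regions. Regions must not overlap.
#' @return a `spectrum_set` restricted to the selected grid points.
#' @export
select_region <- function(x, regions) {
  stopifnot(inherits(x, "spectrum_set"))
  regions <- .normalize_regions(regions)
  wn <- x$wavenumbers
  keep <- rep(FALSE, length(wn))
  for (r in regions) {
    inside <- wn >= r[2] & wn <= r[1]
    if (!any(inside)) {
      stop("region ", r[1], "-", r[2], " cm^-1 selects no grid points")
    }
    keep <- keep | inside
  }
  spectrum_set(wn[keep], x$absorbance[, keep, drop = FALSE], x$meta)
}

.normalize_regions <- function(regions) {
  if (is.numeric(regions) && length(regions) == 2) regions <- list(regions)
  regions <- lapply(regions, function(r) {
    r <- as.numeric(r)
    if (length(r) != 2 || anyNA(r)) stop("a region must be two wavenumbers c(high, low)")
    sort(r, decreasing = TRUE)
  })
  if (length(regions) > 1) {
    ord <- order(vapply(regions, `[`, numeric(1), 1), decreasing = TRUE)
    sorted <- regions[ord]
    for (i in seq_len(length(sorted) - 1)) {
      if (sorted[[i]][2] <= sorted[[i + 1]][1]) {
        stop("regions overlap: ", paste(sorted[[i]], collapse = "-"), " and ",
             paste(sorted[[i + 1]], collapse = "-"))
      }
    }
  }
  regions
}

#' Average technical replicates
#'
#' Collapses each (species, temperature, day, bio_rep) group to the
#' arithmetic mean of its member spectra. The result carries one row per
#' group with `tech_rep = NA` marking the averaged status; output row order
#' follows the first appearance of each group. The operation is invariant to
#' row order within groups.
#'
#' @param x a `spectrum_set` whose metadata defines the grouping.
#' @return a `spectrum_set` of group-mean spectra.
#' @export
average_technical_replicates <- function(x) {
  stopifnot(inherits(x, "spectrum_set"))
  m <- x$meta
  key_cols <- c("species", "temperature", "day", "bio_rep")
  if (anyNA(m[key_cols])) {
    stop("averaging requires complete (species, temperature, day, bio_rep) metadata")
  }
  key <- do.call(paste, c(m[key_cols], sep = "|"))
  ukey <- unique(key)
  g <- match(key, ukey)
  summed <- rowsum(x$absorbance, g, reorder = TRUE)
  counts <- as.vector(table(g))
  avg <- summed / counts
  first <- match(ukey, key)
  meta <- m[first, , drop = FALSE]
  meta$tech_rep <- NA_real_
  meta$sample_id <- sub("_t\\d+$", "", meta$sample_id)
  fallback <- do.call(paste, c(meta[key_cols], sep = "_"))
  dup <- duplicated(meta$sample_id) | meta$sample_id %in% m$sample_id[-first]
  meta$sample_id[dup] <- fallback[dup]
  spectrum_set(x$wavenumbers, avg, meta)
}

#' Read a single-spectrum JCAMP-DX file
#'
#' Convenience importer for the plain AFFN `XYDATA=(X++(Y..Y))` dialect:
#' each data line starts with an X value followed by consecutive Y values on
#' an even grid. `XFACTOR`/`YFACTOR` scaling is applied.
#'
#' @param path path to a `.jdx`/`.dx` file.
#' @param sample_id id given to the imported spectrum.
#' @return a one-sample `spectrum_set`.
#' @export
read_jcamp <- function(path, sample_id = basename(path)) {
  if (!file.exists(path)) stop("JCAMP file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  getnum <- function(label, default = NA_real_) {
    i <- grep(paste0("^##", label, "="), lines)
    if (!length(i)) return(default)
    as.numeric(sub(paste0("^##", label, "="), "", lines[i[1]]))
  }
  xf <- getnum("XFACTOR", 1); yf <- getnum("YFACTOR", 1)
  npt <- getnum("NPOINTS"); fx <- getnum("FIRSTX"); lx <- getnum("LASTX")
  start <- grep("^##XYDATA=\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", lines)
  if (!length(start)) stop("unsupported JCAMP file: no XYDATA=(X++(Y..Y)) block")
  end <- grep("^##END", lines)
  end <- if (length(end)) min(end[end > start[1]]) else length(lines) + 1
  body <- lines[(start[1] + 1):(end - 1)]
  y <- unlist(lapply(body, function(l) {
    v <- as.numeric(strsplit(trimws(l), "[ \t]+")[[1]])
    v[-1]
  }))
  if (is.na(npt)) npt <- length(y)
  if (length(y) != npt) stop("JCAMP NPOINTS mismatch: header ", npt, ", data ", length(y))
  wn <- seq(fx, lx, length.out = npt) * xf
  spectrum_set(wn, matrix(y * yf, nrow = 1),
               data.frame(sample_id = sample_id))
}
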