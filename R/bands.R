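#' Define a spectral band
#'
#' A band is a named search window on the wavenumber axis plus the rule used
#' to read it out. On second-derivative spectra an absorbance maximum
#' appears as a minimum, so the default mode locates the window minimum and
#' negates it to a nonnegative intensity.
#'
#' @param name band name.
#' @param center nominal band center, cm^-1 (must lie inside the window).
#' @param window search window `c(high, low)` in cm^-1.
#' @param mode `"second_derivative_min"` (negated window minimum, for
#'   preprocessed spectra) or `"absorbance_max"` (window maximum, for raw
#'   spectra).
#' @return a `band_definition`.
#' @export
band_definition <- function(name, center, window,
                            mode = c("second_derivative_min", "absorbance_max")) {
  mode <- match.arg(mode)
  window <- sort(as.numeric(window), decreasing = TRUE)
  if (length(window) != 2) stop("window must be c(high, low)")
  if (center > window[1] || center < window[2]) {
    stop("band center ", center, " lies outside the window ",
         window[1], "-", window[2], " cm^-1")
  }
  structure(list(name = name, center = center, window = window, mode = mode),
            class = "band_definition")
}

#' Default lipid band definitions
#'
#' The two read-outs used to follow lipogenesis: the triacylglycerol ester
#' carbonyl C=O stretch near 1745 cm^-1 (intensity tracks total lipid) and
#' the olefinic =C-H stretch near 3008 cm^-1 (position tracks fatty-acid
#' unsaturation). Windows bracket the band centers with margin: 1760-1730
#' and 3020-2995 cm^-1.
#'
#' @return named list of [band_definition()] objects
#'   (`ester_carbonyl`, `olefinic`).
#' @export
lipid_bands <- function() {
  list(ester_carbonyl = band_definition("ester_carbonyl", 1745, c(1760, 1730)),
       olefinic = band_definition("olefinic", 3008, c(3020, 2995)))
}

.band_window_idx <- function(wn, band) {
  idx <- which(wn <= band$window[1] & wn >= band$window[2])
  if (!length(idx)) {
    stop("band '", band$name, "' window ", band$window[1], "-", band$window[2],
         " cm^-1 does not overlap the grid")
  }
  idx
}

#' Band peak height
#'
#' Band intensity per sample: for `second_derivative_min` bands, the negated
#' minimum of the (preprocessed, second-derivative) spectrum inside the
#' search window; for `absorbance_max` bands, the window maximum. The
#' extremum is taken over grid points.
#'
#' @param x a `spectrum_set` (preprocessed for the default mode).
#' @param band a [band_definition()].
#' @return named numeric vector of band intensities, one per sample.
#' @export
peak_height <- function(x, band) {
  stopifnot(inherits(x, "spectrum_set"), inherits(band, "band_definition"))
  idx <- .band_window_idx(x$wavenumbers, band)
  v <- x$absorbance[, idx, drop = FALSE]
  out <- if (band$mode == "second_derivative_min") -apply(v, 1, min) else apply(v, 1, max)
  names(out) <- x$meta$sample_id
  out
}

#' Band peak position
#'
#' Locates the discrete extremum inside the window, then refines it by a
#' three-point parabola through the extremum and its two neighbours, which
#' recovers sub-grid positions to a fraction of the 6 cm^-1 spacing. If the
#' extremum sits on the window boundary the grid value is returned with a
#' warning (no neighbours to interpolate with).
#'
#' @inheritParams peak_height
#' @return named numeric vector of peak positions in cm^-1.
#' @export
peak_position <- function(x, band) {
  stopifnot(inherits(x, "spectrum_set"), inherits(band, "band_definition"))
  idx <- .band_window_idx(x$wavenumbers, band)
  wn <- x$wavenumbers[idx]
  v <- x$absorbance[, idx, drop = FALSE]
  if (band$mode == "second_derivative_min") v <- -v
  out <- vapply(seq_len(nrow(v)), function(i) {
    y <- v[i, ]
    k <- which.max(y)
    if (k == 1 || k == length(y)) {
      warning("band '", band$name, "' extremum on window boundary for sample ",
              x$meta$sample_id[i], "; returning the grid value")
      return(wn[k])
    }
    denom <- y[k - 1] - 2 * y[k] + y[k + 1]
    delta <- if (denom == 0) 0 else (y[k - 1] - y[k + 1]) / (2 * denom)
    wn[k] + delta * (wn[k + 1] - wn[k - 1]) / 2
  }, numeric(1))
  names(out) <- x$meta$sample_id
  out
}

#' Lipid accumulation trend curves
#'
#' Mean and standard deviation of a band intensity over biological
#' replicates, per (species, temperature) group and cultivation day — the
#' at-line lipid accumulation read-out. The SD of a single replicate is
#' reported as 0.
#'
#' @param x a preprocessed `spectrum_set` with complete
#'   (species, temperature, day) metadata.
#' @param band a [band_definition()]; default the ester carbonyl band.
#' @return tidy `data.frame` with columns `species`, `temperature`, `day`,
#'   `n`, `mean`, `sd`, ordered by group and day.
#' @export
lipid_trend <- function(x, band = lipid_bands()$ester_carbonyl) {
  stopifnot(inherits(x, "spectrum_set"))
  m <- x$meta
  if (anyNA(m[c("species", "temperature", "day")])) {
    stop("lipid_trend requires complete (species, temperature, day) metadata")
  }
  h <- peak_height(x, band)
  key <- interaction(m$species, m$temperature, m$day, drop = TRUE, lex.order = TRUE)
  agg <- do.call(rbind, lapply(split(seq_along(h), key), function(i) {
    data.frame(species = m$species[i[1]], temperature = m$temperature[i[1]],
               day = m$day[i[1]], n = length(i), mean = mean(h[i]),
               sd = if (length(i) > 1) stats::sd(h[i]) else 0)
  }))
  agg <- agg[order(agg$species, agg$temperature, agg$day), ]
  rownames(agg) <- NULL
  agg
}

#' Replicate similarity by Pearson correlation
#'
#' Quantifies cultivation / measurement reproducibility as the average
#' pairwise Pearson correlation between replicate spectra, summarised over
#' groups. At the `"technical"` level, groups are
#' (species, temperature, day, bio_rep); at the `"biological"` level,
#' technical replicates are averaged first and groups are
#' (species, temperature, day). Singleton groups are dropped.
#'
#' @param x a `spectrum_set` (raw or preprocessed, caller's choice; the
#'   correlation is computed on the spectra as given).
#' @param level `"technical"` or `"biological"`.
#' @param region optional region `c(high, low)` (or list of regions) to
#'   restrict the correlation to.
#' @return list with `mean` (grand mean over groups), `min`, and `groups`
#'   (per-group `data.frame` of `n` and `mean_cor`).
#' @export
replicate_correlation <- function(x, level = c("technical", "biological"),
                                  region = NULL) {
  stopifnot(inherits(x, "spectrum_set"))
  level <- match.arg(level)
  if (!is.null(region)) x <- select_region(x, region)
  if (level == "biological" && any(!is.na(x$meta$tech_rep))) {
    x <- average_technical_replicates(x)
  }
  key_cols <- if (level == "technical") {
    c("species", "temperature", "day", "bio_rep")
  } else {
    c("species", "temperature", "day")
  }
  if (anyNA(x$meta[key_cols])) {
    stop("replicate_correlation requires complete ",
         paste(key_cols, collapse = ", "), " metadata")
  }
  key <- do.call(paste, c(x$meta[key_cols], sep = "|"))
  groups <- split(seq_len(n_samples(x)), key)
  groups <- groups[lengths(groups) >= 2]
  if (!length(groups)) {
    stop("no group has >= 2 replicates at the ", level, " level")
  }
  tbl <- do.call(rbind, lapply(names(groups), function(k) {
    i <- groups[[k]]
    cm <- stats::cor(t(x$absorbance[i, , drop = FALSE]))
    data.frame(group = k, n = length(i),
               mean_cor = mean(cm[upper.tri(cm)]))
  }))
  rownames(tbl) <- NULL
  list(mean = mean(tbl$mean_cor), min = min(tbl$mean_cor), groups = tbl)
}
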