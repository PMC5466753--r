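#' Built-in fatty acid descriptor catalogue
#'
#' Chain length, double-bond count and omega class for the fatty acids
#' relevant to oleaginous fungi: the common saturates C12:0-C24:0,
#' palmitoleic and oleic acid, linoleic acid, and both trienoic C18 isomers
#' (basal fungi make the n-6 isomer, gamma-linolenic acid; higher fungi the
#' n-3 isomer, alpha-linolenic acid), plus arachidonic acid. Extend by
#' `rbind`-ing rows with the same columns.
#'
#' @return `data.frame` with columns `id`, `chain_length`,
#'   `n_double_bonds`, `omega_class`.
#' @export
fatty_acid_catalogue <- function() {
  data.frame(
    id = c("C12:0", "C13:0", "C14:0", "C15:0", "C16:0", "C17:0", "C18:0",
           "C20:0", "C22:0", "C24:0",
           "C16:1n7", "C18:1n9", "C20:1n9",
           "C18:2n6", "C20:2n6",
           "C18:3n6", "C18:3n3", "C20:3n6",
           "C20:4n6"),
    chain_length = c(12, 13, 14, 15, 16, 17, 18, 20, 22, 24,
                     16, 18, 20, 18, 20, 18, 18, 20, 20),
    n_double_bonds = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
                       1, 1, 1, 2, 2, 3, 3, 3, 4),
    omega_class = c(rep("none", 10), "n7", "n9", "n9", "n6", "n6",
                    "n6", "n3", "n6", "n6"),
    stringsAsFactors = FALSE)
}

.lookup_double_bonds <- function(ids, catalogue) {
  j <- match(ids, catalogue$id)
  if (anyNA(j)) {
    stop("fatty acid(s) not in the descriptor catalogue: ",
         paste(ids[is.na(j)], collapse = ", "))
  }
  catalogue$n_double_bonds[j]
}

#' Fatty acid reference table
#'
#' Container for GC-FID reference data: per-sample fatty acid composition
#' (% of total fatty acids), optional total lipid content (% of cell dry
#' weight), and the (species, temperature, day) key linking each row to its
#' spectra. Compositions are expected to sum to 100 within +/- 0.5
#' percentage points (published tables round minor acids); larger deviations
#' warn, and `renormalize = TRUE` rescales rows to exactly 100.
#'
#' @param composition numeric matrix or data.frame, samples x fatty acids,
#'   columns named by catalogue ids, values in % of total fatty acids.
#' @param total_lipid optional numeric vector, % of cell dry weight.
#' @param meta optional `data.frame` with `species`, `temperature`, `day`.
#' @param renormalize rescale each row to sum exactly 100.
#' @return a `fatty_acid_table`.
#' @export
fatty_acid_table <- function(composition, total_lipid = NULL, meta = NULL,
                             renormalize = FALSE) {
  composition <- as.matrix(composition)
  storage.mode(composition) <- "double"
  if (is.null(colnames(composition))) stop("composition columns must be named by fatty acid id")
  if (any(composition < 0)) stop("composition values must be nonnegative")
  sums <- rowSums(composition)
  off <- abs(sums - 100) > 0.5
  if (any(off)) {
    warning(sum(off), " composition row(s) deviate from 100% by more than 0.5 points")
  }
  if (renormalize) composition <- 100 * composition / sums
  n <- nrow(composition)
  if (!is.null(total_lipid)) {
    total_lipid <- as.numeric(total_lipid)
    if (length(total_lipid) != n) stop("total_lipid length does not match composition rows")
    if (any(!is.na(total_lipid) & (total_lipid < 0 | total_lipid > 100))) {
      stop("total_lipid must lie in [0, 100] % of CDW")
    }
  }
  if (is.null(meta)) meta <- data.frame(row = seq_len(n))
  meta <- as.data.frame(meta)
  if (nrow(meta) != n) stop("meta rows do not match composition rows")
  structure(list(composition = composition, total_lipid = total_lipid,
                 meta = meta),
            class = "fatty_acid_table")
}

#' @export
print.fatty_acid_table <- function(x, ...) {
  cat("<fatty_acid_table> ", nrow(x$composition), " samples x ",
      ncol(x$composition), " fatty acids",
      if (!is.null(x$total_lipid)) " (+ total lipid)", "\n", sep = "")
  print(utils::head(cbind(x$meta, round(x$composition, 2)), 6))
  invisible(x)
}

#' Quantify FAMEs against an internal standard
#'
#' Converts GC-FID peak areas to masses via the internal standard (IS) and
#' per-acid relative response factors (RRF):
#' \deqn{m_i = (A_i / A_{IS}) \times RRF_i \times m_{IS}}
#' Composition is each mass as % of the total FAME mass; total lipid is the
#' total FAME mass as % of the dry biomass.
#'
#' @param areas numeric matrix samples x fatty acids (columns named by acid
#'   id), integrated peak areas; the internal standard must not be a column.
#' @param is_area internal standard peak area per sample (> 0).
#' @param is_mass internal standard mass added, mg (scalar or per sample).
#' @param rrf named numeric vector of relative response factors (from
#'   multi-point calibration of the FAME standard mix) covering every
#'   column of `areas`.
#' @param biomass_mass dry biomass per sample, mg (> 0).
#' @param meta optional sample metadata passed through to the result.
#' @return a [fatty_acid_table()] with `total_lipid` filled in.
#' @export
quantify_fames <- function(areas, is_area, is_mass, rrf, biomass_mass,
                           meta = NULL) {
  areas <- as.matrix(areas)
  storage.mode(areas) <- "double"
  if (is.null(colnames(areas))) stop("area columns must be named by fatty acid id")
  if (any(areas < 0)) stop("peak areas must be nonnegative")
  if (any(is_area <= 0)) stop("internal standard area must be positive")
  if (any(biomass_mass <= 0)) stop("biomass mass must be positive")
  miss <- setdiff(colnames(areas), names(rrf))
  if (length(miss)) stop("no RRF for: ", paste(miss, collapse = ", "))
  n <- nrow(areas)
  is_area <- rep_len(is_area, n)
  is_mass <- rep_len(is_mass, n)
  biomass_mass <- rep_len(biomass_mass, n)
  mass <- sweep(areas / is_area, 2, rrf[colnames(areas)], `*`) * is_mass
  tot <- rowSums(mass)
  if (any(tot == 0)) {
    stop("sample(s) without any fatty acid signal: ",
         paste(which(tot == 0), collapse = ", "))
  }
  fatty_acid_table(100 * mass / tot,
                   total_lipid = 100 * tot / biomass_mass,
                   meta = meta)
}

#' Unsaturation index
#'
#' Average number of double bonds per fatty-acyl chain:
#' \deqn{UI = [\Sigma(\% \times n_{double bonds})] / 100}
#' i.e. monoenes count once, dienes twice, trienes three times; saturated
#' acids contribute nothing. For a composition summing to 100% with at most
#' three double bonds per acid, UI lies in [0, 3].
#'
#' @param composition named numeric vector (single sample) or matrix /
#'   `fatty_acid_table` (values in % of total fatty acids).
#' @param catalogue descriptor catalogue, see [fatty_acid_catalogue()].
#' @return numeric UI, one value per sample.
#' @export
unsaturation_index <- function(composition, catalogue = fatty_acid_catalogue()) {
  if (inherits(composition, "fatty_acid_table")) composition <- composition$composition
  if (is.null(dim(composition))) {
    composition <- matrix(composition, nrow = 1,
                          dimnames = list(NULL, names(composition)))
  }
  if (any(composition < 0)) stop("composition values must be nonnegative")
  ndb <- .lookup_double_bonds(colnames(composition), catalogue)
  as.numeric(composition %*% ndb) / 100
}

#' Summed fatty acid parameters
#'
#' Per-sample SAT (no double bonds), MUFA (one), PUFA (two or more), the
#' unsaturation index, and total lipid content where available. By
#' construction SAT + MUFA + PUFA equals the total composition sum.
#'
#' @param x a [fatty_acid_table()].
#' @param catalogue descriptor catalogue covering every acid in `x`.
#' @return `data.frame`: the table's metadata, each fatty acid, then
#'   `SAT`, `MUFA`, `PUFA`, `unsaturation_index` and (if present)
#'   `total_lipid`.
#' @export
fatty_acid_parameters <- function(x, catalogue = fatty_acid_catalogue()) {
  stopifnot(inherits(x, "fatty_acid_table"))
  comp <- x$composition
  ndb <- .lookup_double_bonds(colnames(comp), catalogue)
  out <- data.frame(x$meta,
                    comp,
                    SAT = rowSums(comp[, ndb == 0, drop = FALSE]),
                    MUFA = rowSums(comp[, ndb == 1, drop = FALSE]),
                    PUFA = rowSums(comp[, ndb >= 2, drop = FALSE]),
                    unsaturation_index = unsaturation_index(comp, catalogue),
                    check.names = FALSE)
  if (!is.null(x$total_lipid)) out$total_lipid <- x$total_lipid
  rownames(out) <- NULL
  out
}

#' Autoscale a data matrix
#'
#' Centers every column to mean 0 and scales it to unit standard deviation
#' (n - 1 denominator) — the conventional scaling for PCA of compositional
#' GC data. The means and SDs are returned for the inverse transform.
#'
#' @param x numeric matrix or data.frame, samples x variables.
#' @return list with `scaled` (matrix), `means`, `sds`.
#' @export
autoscale <- function(x) {
  x <- as.matrix(x)
  means <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero)) {
    nm <- colnames(x)[zero]
    if (is.null(nm)) nm <- which(zero)
    stop("zero-variance column(s): ", paste(nm, collapse = ", "))
  }
  scaled <- sweep(sweep(x, 2, means), 2, sds, `/`)
  list(scaled = scaled, means = means, sds = sds)
}

#' Pooled standard deviation of replicate groups
#'
#' \deqn{s_p = \sqrt{\Sigma_i (n_i - 1) s_i^2 / \Sigma_i (n_i - 1)}}
#' with per-group sample SDs — the reproducibility statistic used for
#' replicate cultivations (e.g. glucose consumption triples).
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return scalar pooled SD.
#' @export
pooled_sd <- function(groups) {
  if (!is.list(groups)) stop("groups must be a list of replicate value vectors")
  n <- lengths(groups)
  if (any(n < 2)) stop("every replicate group needs at least 2 values")
  s2 <- vapply(groups, stats::var, numeric(1))
  sqrt(sum((n - 1) * s2) / sum(n - 1))
}

#' Read / write fatty acid tables as CSV
#'
#' Wide CSV layout: metadata columns (`species`, `temperature`, `day`, and
#' any others present), one column per fatty acid id, and optionally
#' `total_lipid`. This is the shape used for GC composition tables.
#'
#' @param path CSV path.
#' @param catalogue catalogue used to recognise fatty-acid columns.
#' @param renormalize passed to [fatty_acid_table()].
#' @return a [fatty_acid_table()].
#' @export
read_fatty_acid_table <- function(path, catalogue = fatty_acid_catalogue(),
                                  renormalize = FALSE) {
  if (!file.exists(path)) stop("fatty acid table not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  acid_cols <- intersect(names(df), catalogue$id)
  if (!length(acid_cols)) stop("no fatty-acid columns recognised in ", path)
  meta_cols <- setdiff(names(df), c(acid_cols, "total_lipid"))
  fatty_acid_table(df[acid_cols],
                   total_lipid = df$total_lipid,
                   meta = df[meta_cols],
                   renormalize = renormalize)
}

#' @rdname read_fatty_acid_table
#' @param x a `fatty_acid_table` to write.
#' @export
write_fatty_acid_table <- function(x, path) {
  stopifnot(inherits(x, "fatty_acid_table"))
  df <- cbind(x$meta, as.data.frame(x$composition, check.names = FALSE))
  if (!is.null(x$total_lipid)) df$total_lipid <- x$total_lipid
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(x)
}
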