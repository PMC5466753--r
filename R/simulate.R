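#' Olefinic band position as a function of unsaturation index
#'
#' The =C-H stretching band shifts to higher wavenumbers with increasing
#' fatty-acid unsaturation. The generator links the two linearly through the
#' anchor points (UI 0.93, 3006 cm^-1) and (UI 1.43, 3012 cm^-1); the slope
#' is configurable because only the direction of the association, not its
#' functional form, is established.
#'
#' @param ui unsaturation index (double bonds per acyl chain).
#' @param anchor_low,anchor_high `c(ui, wavenumber)` anchor points.
#' @return olefinic band center, cm^-1.
#' @export
olefinic_position <- function(ui, anchor_low = c(0.93, 3006),
                              anchor_high = c(1.43, 3012)) {
  slope <- (anchor_high[2] - anchor_low[2]) / (anchor_high[1] - anchor_low[1])
  anchor_low[2] + slope * (ui - anchor_low[1])
}

.gauss <- function(wn, center, sigma) exp(-(wn - center)^2 / (2 * sigma^2))

#' Pure-component spectra for the generator
#'
#' Builds unit-normalized, nonnegative component spectra as sums of
#' Gaussian bands at the positions characteristic of fungal biomass:
#' lipid (acyl CH stretches 2955/2925/2850, olefinic =C-H whose position
#' follows the unsaturation index, ester carbonyl 1745, CH bend 1465,
#' chain rock 725 cm^-1), protein (amide I 1650, amide II 1540),
#' carbohydrate (1150, 1080, 1033) and polyphosphate (1260, 880). Gaussian
#' (rather than Voigt) shapes are used because their second derivatives
#' have closed forms, which keeps every downstream operation analytically
#' testable.
#'
#' Band amplitudes follow Beer-Lambert proportionality to functional-group
#' densities per acyl chain: the olefinic =C-H stretch and the cis-CH wag
#' near 725 cm^-1 scale with the double-bond density (the unsaturation
#' index; zero double bonds means no olefinic band), while the CH2 stretch
#' and bend bands scale with the methylene count per chain, which drops by
#' two for every cis double bond. The olefinic position additionally
#' follows the unsaturation-dependent shift of [olefinic_position()].
#'
#' @param wavenumbers grid in cm^-1; must cover 3020-725.
#' @param ui unsaturation index (double bonds per acyl chain).
#' @param chain_length mean acyl chain length of the fatty-acid pool.
#' @param bis_allylic mean bis-allylic methylene count per chain (one CH2
#'   bridges each pair of cis double bonds: 0 for monoenes, 1 for dienes,
#'   2 for trienes) — the spectral marker specific to polyunsaturation.
#' @return matrix with rows `lipid`, `protein`, `carbohydrate`,
#'   `polyphosphate`, each with maximum 1.
#' @export
pure_component_spectra <- function(wavenumbers, ui = 1.1, chain_length = 17.5,
                                   bis_allylic = max(ui - 0.7, 0)) {
  wn <- as.numeric(wavenumbers)
  if (max(wn) < 3020 || min(wn) > 725) {
    stop("grid must cover the 3020-725 cm^-1 band positions")
  }
  bands <- function(centers, amps, sigmas) {
    v <- rep(0, length(wn))
    for (i in seq_along(centers)) v <- v + amps[i] * .gauss(wn, centers[i], sigmas[i])
    v / max(v)
  }
  ch2 <- (chain_length - 2 - 2 * ui) / 13  # methylenes per chain, ~1 at C18:1
  lipid <- bands(c(olefinic_position(ui), 2955, 2940, 2925, 2850, 1745, 1465, 725),
                 c(0.22 * ui, 0.55, 0.30 * bis_allylic, 0.85 * ch2, 0.60 * ch2,
                   1.00, 0.35 * ch2, 0.05 + 0.06 * ui),
                 c(8, 10, 10, 11, 9, 11, 13, 9))
  protein <- bands(c(1650, 1540), c(1.00, 0.70), c(15, 13))
  carbohydrate <- bands(c(1150, 1080, 1033), c(0.50, 0.80, 1.00), c(12, 13, 11))
  polyphosphate <- bands(c(1260, 880), c(0.80, 0.50), c(14, 11))
  rbind(lipid = lipid, protein = protein, carbohydrate = carbohydrate,
        polyphosphate = polyphosphate)
}

.default_lipid_kinetics <- function() {
  data.frame(
    species = rep(c("Mc", "Ui", "Pg"), each = 2),
    temperature = rep(c(20, 30), 3),
    start = c(8, 8, 8, 8, 8, 8),
    plateau = c(31, 37, 33, 35, 26, 28),
    onset = c(3, 2.5, 3, 2.5, 3.5, 3),
    rate = c(1.2, 1.4, 1.2, 1.4, 1.1, 1.2))
}

.fa_cols <- c("C16:0", "C18:0", "C18:1n9", "C18:2n6", "C18:3n6", "C18:3n3")

.fa_chain_lengths <- function() {
  cat <- fatty_acid_catalogue()
  stats::setNames(cat$chain_length, cat$id)
}

.default_composition_kinetics <- function() {
  vec <- function(p16, p18, oleic, la, triene, which_triene) {
    v <- stats::setNames(rep(0, length(.fa_cols)), .fa_cols)
    v[c("C16:0", "C18:0", "C18:1n9", "C18:2n6")] <- c(p16, p18, oleic, la)
    v[which_triene] <- triene
    v
  }
  list(
    Mc = list(start = vec(22, 6, 26, 28, 18, "C18:3n6"),
              end = vec(25, 8, 43, 16, 8, "C18:3n6")),
    Ui = list(start = vec(20, 4, 30, 26, 20, "C18:3n6"),
              end = vec(22, 6, 46, 18, 8, "C18:3n6")),
    Pg = list(start = vec(24, 6, 24, 28, 18, "C18:3n3"),
              end = vec(26, 9, 40, 19, 6, "C18:3n3")),
    transition_day = 4, rate = 1.5)
}

.default_glucose_kinetics <- function() {
  data.frame(
    species = rep(c("Mc", "Ui", "Pg"), each = 2),
    temperature = rep(c(20, 30), 3),
    start = 80,
    final = c(45, 1, 2, 1, 5, 2),
    mid = c(6, 5, 6, 5, 7, 6),
    rate = c(0.8, 0.9, 0.8, 0.9, 0.7, 0.8))
}

#' Configuration of the synthetic microcultivation experiment
#'
#' Defines the study design the generator emulates: 3 fungal species
#' (two gamma-linolenic producers `Mc`, `Ui` and one alpha-linolenic
#' producer `Pg`) at 2 temperatures over 12 cultivation days, 3 biological
#' x 3 technical replicates. Lipid content follows a per-condition logistic
#' (onset day, rate, plateau in % of cell dry weight, plateau capped at the
#' 70% biological ceiling); fatty-acid composition interpolates from a
#' PUFA-rich growth-phase vector to a MUFA-rich stationary-phase vector
#' around the growth transition; glucose declines along a logistic with
#' replicate noise. Spectra are mixtures of the pure components scaled by
#' the lipid weight fraction, wrapped in multiplicative scatter
#' (`b`), additive offset (`a`), polynomial baseline (`c`, `d` on the
#' [-1, 1]-mapped axis) and white noise.
#'
#' @param species species codes (must have kinetics rows/entries).
#' @param temperatures cultivation temperatures, degrees C.
#' @param days sampling days.
#' @param bio_reps,tech_reps replicate counts.
#' @param grid wavenumber grid, cm^-1.
#' @param noise list of artifact ranges: `additive_sd` (absorbance units),
#'   `b_range`, `a_range`, `c_range`, `d_range`.
#' @param lipid_kinetics per species x temperature `data.frame`
#'   (`start`, `plateau`, `onset`, `rate`).
#' @param composition_kinetics per-species `start`/`end` composition
#'   vectors (% of total fatty acids, summing to 100) plus
#'   `transition_day` and `rate`.
#' @param glucose_kinetics per species x temperature logistic parameters.
#' @param gc_noise_rel relative SD of GC measurement noise (main fatty
#'   acids reproduce to a coefficient of variation of ~1-2%).
#' @param day_jitter Dirichlet concentration of the condition-day kinetic
#'   fluctuation of the composition: real cultivations do not follow their
#'   mean kinetics exactly, and the day-to-day wobble is shared by the GC
#'   reference and all replicate spectra of that condition-day (it is
#'   signal, not noise).
#' @param lipid_day_cv relative SD of the same condition-day fluctuation on
#'   lipid content (lipid accumulation curves visibly fluctuate between
#'   sampling days).
#' @param bio_jitter Dirichlet concentration for biological composition
#'   jitter (larger = tighter replicates).
#' @param lipid_bio_cv relative SD of biological lipid-content jitter.
#' @param glucose_rep_sd replicate SD of glucose, g/L.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(species = c("Mc", "Ui", "Pg"),
                             temperatures = c(20, 30),
                             days = 1:12,
                             bio_reps = 3, tech_reps = 3,
                             grid = seq(4000, 500, by = -6),
                             noise = list(additive_sd = 0.001,
                                          b_range = c(0.7, 1.3),
                                          a_range = c(-0.05, 0.05),
                                          c_range = c(-0.02, 0.02),
                                          d_range = c(-0.01, 0.01)),
                             lipid_kinetics = .default_lipid_kinetics(),
                             composition_kinetics = .default_composition_kinetics(),
                             glucose_kinetics = .default_glucose_kinetics(),
                             gc_noise_rel = 0.01,
                             day_jitter = 600,
                             lipid_day_cv = 0.06,
                             bio_jitter = 15000,
                             lipid_bio_cv = 0.02,
                             glucose_rep_sd = 1.1) {
  for (s in species) {
    ck <- composition_kinetics[[s]]
    if (is.null(ck)) stop("no composition kinetics for species ", s)
    for (w in c("start", "end")) {
      if (abs(sum(ck[[w]]) - 100) > 1e-8) {
        stop("composition ", w, " vector for ", s, " must sum to 100")
      }
    }
  }
  if (any(lipid_kinetics$plateau > 70)) {
    stop("lipid plateau above the 70% of CDW biological ceiling")
  }
  structure(list(species = species, temperatures = temperatures, days = days,
                 bio_reps = bio_reps, tech_reps = tech_reps, grid = grid,
                 noise = noise, lipid_kinetics = lipid_kinetics,
                 composition_kinetics = composition_kinetics,
                 glucose_kinetics = glucose_kinetics,
                 gc_noise_rel = gc_noise_rel,
                 day_jitter = day_jitter, lipid_day_cv = lipid_day_cv,
                 bio_jitter = bio_jitter,
                 lipid_bio_cv = lipid_bio_cv,
                 glucose_rep_sd = glucose_rep_sd),
            class = "synthetic_config")
}

.logistic <- function(x) 1 / (1 + exp(-x))

.kinetics_row <- function(tab, sp, temp) {
  i <- which(tab$species == sp & tab$temperature == temp)
  if (!length(i)) stop("no kinetics for ", sp, " at ", temp, " degrees C")
  tab[i[1], ]
}

.condition_composition <- function(cfg, sp, temp, day) {
  ck <- cfg$composition_kinetics[[sp]]
  frac <- .logistic(cfg$composition_kinetics$rate *
                      (day - cfg$composition_kinetics$transition_day))
  comp <- ck$start + (ck$end - ck$start) * frac
  # cooler cultivation retains more triene at the expense of linoleic acid
  if (temp <= min(cfg$temperatures)) {
    triene <- if (comp["C18:3n6"] > 0) "C18:3n6" else "C18:3n3"
    shift <- 3 * frac
    comp[triene] <- comp[triene] + shift
    comp["C18:2n6"] <- max(comp["C18:2n6"] - 4 * frac, 0)
    comp["C18:1n9"] <- comp["C18:1n9"] + 1 * frac
  }
  100 * comp / sum(comp)
}

.rdirichlet_scaled <- function(mean_pct, concentration) {
  alpha <- pmax(mean_pct, 1e-6) / 100 * concentration
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  stats::setNames(100 * g / sum(g), names(mean_pct))
}

#' Generate a synthetic microcultivation experiment
#'
#' Draws a complete experiment from a [synthetic_config()]: raw technical
#' replicate FTIR spectra with planted scatter artifacts, a per-condition
#' GC fatty-acid table (the reference side), per-replicate glucose
#' concentrations, and the full ground truth needed for parameter-recovery
#' tests. All randomness flows through the single `seed`; the same seed
#' reproduces the output bitwise. With `noise = FALSE` every artifact and
#' jitter is switched off (b = 1, baselines 0, no additive noise, exact
#' kinetics), which is the mode used for ordering/recovery oracles.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @param noise logical master switch for all stochastic components.
#' @param drop optional `data.frame(species, temperature, day)` of
#'   condition-days to remove from every output table (emulates incomplete
#'   sampling designs).
#' @return a `synthetic_experiment` list: `spectra` (`spectrum_set` of
#'   technical replicates), `gc` ([fatty_acid_table()] per condition-day),
#'   `glucose` (`data.frame` per biological replicate), `truth`
#'   (biological-sample ground truth incl. lipid %, composition, UI,
#'   olefinic center, glucose), `scatter` (per technical replicate planted
#'   `a`, `b`, `c`, `d`), `config`, `seed`.
#' @export
simulate_experiment <- function(config = synthetic_config(), seed = 1,
                                noise = TRUE, drop = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  wn <- config$grid
  p <- length(wn)
  p1 <- (wn - (max(wn) + min(wn)) / 2) / ((max(wn) - min(wn)) / 2)
  p2 <- p1^2
  nonlipid_w <- c(protein = 0.55, carbohydrate = 0.35, polyphosphate = 0.10)
  spec_rows <- list(); spec_meta <- list()
  gc_rows <- list(); gc_meta <- list(); gc_lipid <- c()
  glucose_rows <- list(); truth_rows <- list(); scatter_rows <- list()
  for (sp in config$species) {
    for (temp in config$temperatures) {
      lk <- .kinetics_row(config$lipid_kinetics, sp, temp)
      gk <- .kinetics_row(config$glucose_kinetics, sp, temp)
      for (day in config$days) {
        L <- lk$start + (lk$plateau - lk$start) *
          .logistic(lk$rate * (day - lk$onset))
        comp_mean <- .condition_composition(config, sp, temp, day)
        if (noise) {
          # condition-day kinetic fluctuation: shared by the GC reference
          # and every replicate spectrum of this condition-day
          L <- L * (1 + stats::rnorm(1, 0, config$lipid_day_cv))
          comp_mean <- .rdirichlet_scaled(comp_mean, config$day_jitter)
        }
        g_mean <- gk$final + (gk$start - gk$final) /
          (1 + exp(gk$rate * (day - gk$mid)))
        # GC reference: condition-level measurement with analytical noise
        comp_gc <- comp_mean
        lipid_gc <- L
        if (noise) {
          comp_gc <- comp_mean * (1 + stats::rnorm(length(comp_mean), 0,
                                                   config$gc_noise_rel))
          comp_gc <- 100 * pmax(comp_gc, 0) / sum(pmax(comp_gc, 0))
          lipid_gc <- L * (1 + stats::rnorm(1, 0, config$gc_noise_rel))
        }
        gc_rows[[length(gc_rows) + 1]] <- comp_gc
        gc_meta[[length(gc_meta) + 1]] <-
          data.frame(species = sp, temperature = temp, day = day)
        gc_lipid <- c(gc_lipid, lipid_gc)
        for (b_rep in seq_len(config$bio_reps)) {
          comp_b <- if (noise) {
            .rdirichlet_scaled(comp_mean, config$bio_jitter)
          } else comp_mean
          L_b <- if (noise) L * (1 + stats::rnorm(1, 0, config$lipid_bio_cv)) else L
          ui_b <- unsaturation_index(comp_b)
          gl_b <- if (noise) {
            max(g_mean + stats::rnorm(1, 0, config$glucose_rep_sd), 0)
          } else g_mean
          chain_b <- sum(comp_b * .fa_chain_lengths()[names(comp_b)]) / 100
          ndb_b <- .lookup_double_bonds(names(comp_b), fatty_acid_catalogue())
          bis_b <- sum(comp_b * pmax(ndb_b - 1, 0)) / 100
          comps <- pure_component_spectra(wn, ui = ui_b, chain_length = chain_b,
                                          bis_allylic = bis_b)
          nonlipid <- colSums(comps[names(nonlipid_w), ] * nonlipid_w)
          signal <- (L_b / 100) * comps["lipid", ] + (1 - L_b / 100) * nonlipid
          base_id <- sprintf("%s_T%g_d%02d_b%d", sp, temp, day, b_rep)
          glucose_rows[[length(glucose_rows) + 1]] <-
            data.frame(species = sp, temperature = temp, day = day,
                       bio_rep = b_rep, glucose = gl_b)
          truth_rows[[length(truth_rows) + 1]] <- data.frame(
            species = sp, temperature = temp, day = day, bio_rep = b_rep,
            lipid_pct = L_b, unsaturation_index = ui_b,
            olefinic_center = olefinic_position(ui_b),
            glucose = gl_b, t(comp_b), check.names = FALSE)
          for (t_rep in seq_len(config$tech_reps)) {
            if (noise) {
              a <- stats::runif(1, config$noise$a_range[1], config$noise$a_range[2])
              b <- stats::runif(1, config$noise$b_range[1], config$noise$b_range[2])
              cc <- stats::runif(1, config$noise$c_range[1], config$noise$c_range[2])
              dd <- stats::runif(1, config$noise$d_range[1], config$noise$d_range[2])
              eps <- stats::rnorm(p, 0, config$noise$additive_sd)
            } else {
              a <- 0; b <- 1; cc <- 0; dd <- 0; eps <- 0
            }
            z <- b * signal + a + cc * p1 + dd * p2 + eps
            id <- paste0(base_id, "_t", t_rep)
            spec_rows[[length(spec_rows) + 1]] <- z
            spec_meta[[length(spec_meta) + 1]] <- data.frame(
              sample_id = id, species = sp, temperature = temp, day = day,
              bio_rep = b_rep, tech_rep = t_rep)
            scatter_rows[[length(scatter_rows) + 1]] <- data.frame(
              sample_id = id, a = a, b = b, c = cc, d = dd)
          }
        }
      }
    }
  }
  spectra <- spectrum_set(wn, do.call(rbind, spec_rows),
                          do.call(rbind, spec_meta))
  gc <- fatty_acid_table(do.call(rbind, gc_rows), total_lipid = gc_lipid,
                         meta = do.call(rbind, gc_meta))
  glucose <- do.call(rbind, glucose_rows)
  truth <- do.call(rbind, truth_rows)
  scatter <- do.call(rbind, scatter_rows)
  rownames(glucose) <- rownames(truth) <- rownames(scatter) <- NULL
  out <- list(spectra = spectra, gc = gc, glucose = glucose, truth = truth,
              scatter = scatter, config = config, seed = seed)
  if (!is.null(drop)) out <- .drop_condition_days(out, drop)
  structure(out, class = "synthetic_experiment")
}

.drop_condition_days <- function(x, drop) {
  drop <- as.data.frame(drop)
  need <- c("species", "temperature", "day")
  if (!all(need %in% names(drop))) {
    stop("drop needs columns species, temperature, day")
  }
  key <- function(df) do.call(paste, c(df[need], sep = "|"))
  dk <- key(drop)
  x$spectra <- x$spectra[!(key(x$spectra$meta) %in% dk)]
  keep_gc <- !(key(x$gc$meta) %in% dk)
  x$gc <- fatty_acid_table(x$gc$composition[keep_gc, , drop = FALSE],
                           total_lipid = x$gc$total_lipid[keep_gc],
                           meta = x$gc$meta[keep_gc, , drop = FALSE])
  x$glucose <- x$glucose[!(key(x$glucose) %in% dk), , drop = FALSE]
  x$truth <- x$truth[!(key(x$truth) %in% dk), , drop = FALSE]
  x$scatter <- x$scatter[x$scatter$sample_id %in% x$spectra$meta$sample_id, ,
                         drop = FALSE]
  rownames(x$glucose) <- rownames(x$truth) <- rownames(x$scatter) <- NULL
  x
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("<synthetic_experiment> seed ", x$seed, ": ",
      n_samples(x$spectra), " technical spectra, ",
      nrow(x$truth), " biological samples, ",
      nrow(x$gc$composition), " GC condition-days\n", sep = "")
  invisible(x)
}

#' Small regression fixtures with known coefficients
#'
#' Draws X with standard-normal entries and y = X beta + noise — the
#' minimal planted linear model used to check PLS and cross-validation
#' behaviour against known truth.
#'
#' @param n_samples,n_vars dimensions (`n_samples > n_vars >= 1`).
#' @param beta coefficient vector (recycled to `n_vars`).
#' @param noise_sd SD of the additive noise.
#' @param seed integer seed.
#' @return list with `X`, `y`, `beta`, `noise_sd`.
#' @export
simulate_regression <- function(n_samples, n_vars, beta = 1, noise_sd = 0,
                                seed = 1) {
  if (n_samples <= n_vars || n_vars < 1) stop("need n_samples > n_vars >= 1")
  set.seed(seed)
  X <- matrix(stats::rnorm(n_samples * n_vars), n_samples, n_vars)
  beta <- rep_len(beta, n_vars)
  y <- as.numeric(X %*% beta) + stats::rnorm(n_samples, 0, noise_sd)
  list(X = X, y = y, beta = beta, noise_sd = noise_sd)
}
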