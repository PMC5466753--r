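# Shared fixtures, all built in code.

# instrument grid: 4000 -> 500 cm^-1 at 6 cm^-1 spacing
instrument_grid <- function() seq(4000, 500, by = -6)

# a small spectrum_set of Gaussian bands on an arbitrary grid
gaussian_set <- function(centers, amps = 1, sigmas = 15,
                         grid = instrument_grid(), meta = NULL) {
  amps <- rep_len(amps, length(centers))
  sigmas <- rep_len(sigmas, length(centers))
  a <- t(vapply(seq_along(centers), function(i) {
    amps[i] * exp(-(grid - centers[i])^2 / (2 * sigmas[i]^2))
  }, numeric(length(grid))))
  spectrum_set(grid, a, meta)
}

# metadata for a factorial replicate design
design_meta <- function(species = "Sp", temperature = 30, day = 1,
                        bio_rep = 1, tech_rep = 1:3) {
  g <- expand.grid(species = species, temperature = temperature, day = day,
                   bio_rep = bio_rep, tech_rep = tech_rep,
                   stringsAsFactors = FALSE)
  g$sample_id <- sprintf("%s_T%g_d%02d_b%d_t%d", g$species, g$temperature,
                         g$day, g$bio_rep, g$tech_rep)
  g
}

# memoised default synthetic experiment (seed 1) shared across test files
sim_default <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_experiment(seed = 1)
    cache
  }
})

# the two condition-days missing from the deposited 210-sample design are
# not identified in the study text; this stand-in drop list emulates a
# 630-spectrum / 210-average design
synthetic_drop_cells <- function() {
  data.frame(species = c("Ui", "Mc"), temperature = c(20, 30), day = c(12, 11))
}

# the study's early-growth exclusion triple (3 bio reps each)
study_exclusion <- function() {
  data.frame(species = c("Mc", "Pg", "Pg"), temperature = c(20, 20, 30),
             day = c(1, 2, 1))
}
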