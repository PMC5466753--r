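test_that("peak height is zero on flat input and linear in amplitude", {
  grid <- instrument_grid()
  band <- lipid_bands()$ester_carbonyl
  flat <- spectrum_set(grid, matrix(0, 1, length(grid)))
  expect_identical(unname(peak_height(flat, band)), 0)

  s <- gaussian_set(c(1745, 1745), amps = c(1, 2), sigmas = 12)
  d <- sg_derivative(s)
  h <- peak_height(d, band)
  expect_gt(h[1], 0)
  expect_equal(unname(h[2]), 2 * unname(h[1]), tolerance = 1e-8)
  # adding a constant to the raw spectrum does not change the height
  shifted <- spectrum_set(grid, s$absorbance + 0.7)
  expect_equal(unname(peak_height(sg_derivative(shifted), band)),
               unname(h), tolerance = 1e-10)
})

test_that("ester peak height follows the planted lipid kinetics", {
  sim <- simulate_experiment(seed = 5, noise = FALSE)
  pre <- preprocess_spectra(sim$spectra)
  h <- peak_height(pre$spectra, lipid_bands()$ester_carbonyl)
  m <- pre$spectra$meta
  truth <- sim$truth
  for (grp in split(seq_len(nrow(m)),
                    paste(m$species, m$temperature, m$bio_rep))) {
    o <- grp[order(m$day[grp])]
    expect_true(all(diff(h[o]) > 0))  # nondecreasing lipid -> increasing band
    tl <- truth$lipid_pct[match(m$sample_id[o],
                                sprintf("%s_T%g_d%02d_b%d", truth$species,
                                        truth$temperature, truth$day,
                                        truth$bio_rep))]
    expect_identical(order(h[o]), order(tl))  # same ranking as the truth
  }
})

test_that("parabolic refinement locates band centers to sub-grid accuracy", {
  band <- band_definition("olefinic", 3008, c(3020, 2995))
  s <- gaussian_set(3008, sigmas = 8)
  d <- sg_derivative(s)
  expect_lt(abs(peak_position(d, band) - 3008), 0.6)
  # a symmetric triple with equal neighbours sits exactly on the grid point
  grid <- seq(3020, 2996, by = -6)
  y <- c(0, 1, 2, 1, 0)
  s2 <- spectrum_set(grid, matrix(y, 1))
  pos <- peak_position(s2, band_definition("x", 3008, c(3020, 2996),
                                           mode = "absorbance_max"))
  expect_identical(unname(pos), 3008)
  # a shifted copy of the band shifts the estimate by the same amount
  s3 <- gaussian_set(c(3008, 3005), sigmas = 8)
  d3 <- sg_derivative(s3)
  p3 <- peak_position(d3, band)
  expect_equal(unname(p3[1] - p3[2]), 3, tolerance = 0.6)
  # extremum on the window boundary falls back to the grid value, warning
  sMono <- spectrum_set(seq(3020, 2996, by = -6), matrix(seq(5, 1), 1))
  expect_warning(
    pb <- peak_position(sMono, band_definition("m", 3008, c(3020, 2996),
                                               mode = "absorbance_max")),
    "boundary")
  expect_identical(unname(pb), 3020)
})

test_that("low-unsaturation samples sit at lower olefinic positions", {
  sim <- simulate_experiment(seed = 5, noise = FALSE)
  pre <- preprocess_spectra(sim$spectra)
  pos <- peak_position(pre$spectra, lipid_bands()$olefinic)
  ui <- sim$truth$unsaturation_index
  expect_gt(cor(pos, ui), 0.9)
  lo <- ui <= quantile(ui, 0.25); hi <- ui >= quantile(ui, 0.75)
  expect_lt(mean(pos[lo]), mean(pos[hi]))
})

test_that("lipid trends aggregate replicates per condition and day", {
  m <- design_meta(bio_rep = 1:3, tech_rep = NA)
  m$sample_id <- paste0("s", 1:3)
  grid <- seq(1760, 1730, by = -6)
  idx <- which.min(abs(grid - 1745))
  a <- matrix(0, 3, length(grid))
  a[, idx] <- -c(1, 2, 3)  # second-derivative minima of known depth
  s <- spectrum_set(grid, a, m)
  tr <- lipid_trend(s, band_definition("ester", 1745, c(1760, 1730)))
  expect_identical(nrow(tr), 1L)
  expect_equal(tr$mean, 2)
  expect_equal(tr$sd, 1)
  expect_identical(tr$n, 3L)
  # single replicate: SD reported as 0
  tr1 <- lipid_trend(s[1], band_definition("ester", 1745, c(1760, 1730)))
  expect_identical(tr1$sd, 0)
  expect_equal(tr1$mean, 1)
  # full design: 3 species x 2 temperatures x 12 days
  sim <- sim_default()
  pre <- preprocess_spectra(sim$spectra)
  tr_full <- lipid_trend(pre$spectra)
  expect_identical(nrow(tr_full), 72L)
  expect_identical(nrow(unique(tr_full[c("species", "temperature")])), 6L)
  expect_true(all(tr_full$n == 3))
})

test_that("replicate correlation behaves like a similarity statistic", {
  grid <- seq(1800, 1000, by = -6)
  v <- exp(-(grid - 1650)^2 / 500) + 0.3 * sin(grid / 40)
  m <- design_meta(tech_rep = 1:2)
  identical_reps <- spectrum_set(grid, rbind(v, v), m)
  expect_equal(replicate_correlation(identical_reps, "technical")$mean, 1)
  anti <- spectrum_set(grid, rbind(v, -v), m)
  expect_equal(replicate_correlation(anti, "technical")$mean, -1)
  # invariant to global scaling and to replicate order
  set.seed(3)
  noisy <- rbind(v + rnorm(length(v), 0, 0.01), v + rnorm(length(v), 0, 0.01))
  s1 <- spectrum_set(grid, noisy, m)
  s2 <- spectrum_set(grid, 5 * noisy[2:1, ], m)
  expect_equal(replicate_correlation(s1, "technical")$mean,
               replicate_correlation(s2, "technical")$mean)
  expect_error(replicate_correlation(s1[1], "technical"), ">= 2 replicates")
})

test_that("1% additive noise keeps replicate correlation above 0.999", {
  grid <- instrument_grid()
  base <- 0.8 * pure_component_spectra(grid)["lipid", ] +
    0.5 * pure_component_spectra(grid)["protein", ]
  sig <- sd(base)
  set.seed(8)
  m <- do.call(rbind, lapply(1:10, function(b) {
    d <- design_meta(bio_rep = b, tech_rep = 1:3)
    d
  }))
  a <- t(vapply(seq_len(nrow(m)), function(i) {
    base + rnorm(length(grid), 0, 0.01 * sig)
  }, numeric(length(grid))))
  rc <- replicate_correlation(spectrum_set(grid, a, m), "technical")
  expect_gt(rc$mean, 0.999)
})
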