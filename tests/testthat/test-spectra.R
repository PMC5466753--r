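test_that("wide CSV reading recovers the expected grid and rows", {
  grid <- instrument_grid()
  # independent count: floor((4000 - 500) / 6) + 1 grid points
  expect_identical(length(grid), as.integer(floor((4000 - 500) / 6) + 1))
  a <- matrix(rnorm(3 * length(grid)), 3)
  f <- tempfile(fileext = ".csv")
  write_spectra(spectrum_set(grid, a), f)
  s <- read_spectra(f)
  expect_s3_class(s, "spectrum_set")
  expect_identical(dim(s$absorbance), c(3L, 584L))
  expect_equal(s$wavenumbers, grid)
  expect_lt(max(abs(s$absorbance - a)), 1e-10)
})

test_that("an ascending grid is flipped to descending with values preserved", {
  asc <- seq(500, 1000, by = 10)
  a <- matrix(seq_along(asc), 1)
  s <- spectrum_set(asc, a)
  expect_equal(s$wavenumbers, rev(asc))
  expect_equal(s$absorbance[1, ], rev(a[1, ]))
  # reading an ascending file gives the same flip
  f <- tempfile(fileext = ".csv")
  df <- data.frame(sample_id = "x", a, check.names = FALSE)
  names(df) <- c("sample_id", asc)
  write.csv(df, f, row.names = FALSE, quote = FALSE)
  expect_equal(read_spectra(f)$wavenumbers, rev(asc))
})

test_that("malformed spectra tables are rejected", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,1000,994,988", "s1,1,2,3", "s2,1,2"), f)
  expect_error(read_spectra(f), "malformed")
  writeLines(c("sample_id,1000,seven,988", "s1,1,2,3"), f)
  expect_error(read_spectra(f), "non-numeric wavenumber")
  m <- design_meta(tech_rep = c(1, 1))  # duplicate key
  expect_error(spectrum_set(1:4, matrix(0, 2, 4), m), "duplicate")
  expect_error(spectrum_set(c(1000, 994, 994), matrix(0, 1, 3)), "monotone")
  expect_error(spectrum_set(1:3, matrix(c(1, NA, 3), 1)), "missing")
})

test_that("write/read round trip is lossless, including the empty set", {
  s <- gaussian_set(c(1745, 2925, 1650), amps = c(1, 0.5, 0.25))
  f <- tempfile(fileext = ".csv")
  write_spectra(s, f)
  expect_lt(max(abs(read_spectra(f)$absorbance - s$absorbance)), 1e-10)

  empty <- spectrum_set(instrument_grid(), matrix(numeric(0), 0, 584))
  write_spectra(empty, f)
  back <- read_spectra(f)
  expect_identical(nrow(back$absorbance), 0L)
  expect_equal(back$wavenumbers, empty$wavenumbers)
})

test_that("a full synthetic design round-trips with identical metadata keys", {
  sim <- sim_default()
  f <- tempfile(fileext = ".csv")
  fm <- tempfile(fileext = ".csv")
  write_spectra(sim$spectra, f, meta_path = fm)
  back <- read_spectra(f, meta = fm)
  expect_identical(back$meta$sample_id, sim$spectra$meta$sample_id)
  expect_identical(back$meta[c("species", "temperature", "day", "bio_rep",
                               "tech_rep")],
                   sim$spectra$meta[c("species", "temperature", "day",
                                      "bio_rep", "tech_rep")])
  expect_lt(max(abs(back$absorbance - sim$spectra$absorbance)), 1e-10)
})

test_that("metadata can be parsed from sample ids with a named-group regex", {
  md <- parse_sample_ids(
    c("Mc_T20_d01_b1_t2", "Pg_T30_d12_b3_t1"),
    paste0("^(?<species>[^_]+)_T(?<temperature>\\d+)_d(?<day>\\d+)",
           "_b(?<bio_rep>\\d+)_t(?<tech_rep>\\d+)$"))
  expect_identical(md$species, c("Mc", "Pg"))
  expect_identical(md$day, c("01", "12"))
  expect_error(parse_sample_ids("oddball", "^(?<species>[A-Z])$"), "do not match")
})

test_that("select_region keeps exactly the points inside closed regions", {
  grid <- instrument_grid()
  s <- spectrum_set(grid, matrix(seq_along(grid), 1))
  one <- select_region(s, list(c(3100, 2800)))
  expect_true(all(one$wavenumbers <= 3100 & one$wavenumbers >= 2800))
  # brute-force membership scan as the oracle for the combined count
  both <- select_region(s, list(c(3100, 2800), c(1800, 500)))
  manual <- sum(grid >= 2800 & grid <= 3100) + sum(grid >= 500 & grid <= 1800)
  expect_identical(length(both$wavenumbers), manual)
  expect_identical(length(both$wavenumbers),
                   length(one$wavenumbers) +
                     length(select_region(s, list(c(1800, 500)))$wavenumbers))
  # idempotence and order preservation
  again <- select_region(both, list(c(3100, 2800), c(1800, 500)))
  expect_identical(again$wavenumbers, both$wavenumbers)
  expect_true(all(diff(both$wavenumbers) < 0))
  expect_error(select_region(s, c(10000, 9000)), "no grid points")
  expect_error(select_region(s, list(c(3100, 2800), c(2900, 500))), "overlap")
})

test_that("technical replicate averaging collapses groups to their mean", {
  sim2 <- simulate_experiment(seed = 2, drop = synthetic_drop_cells())
  expect_identical(n_samples(sim2$spectra), 630L)
  avg <- average_technical_replicates(sim2$spectra)
  expect_identical(n_samples(avg), 210L)
  expect_true(all(is.na(avg$meta$tech_rep)))

  v <- rnorm(10)
  m <- design_meta(tech_rep = 1:2)
  s <- spectrum_set(1000 - (0:9) * 6, rbind(0 * v, 2 * v), m)
  expect_equal(average_technical_replicates(s)$absorbance[1, ], v)
  # identical members: average equals any member; row order irrelevant
  s3 <- spectrum_set(1000 - (0:9) * 6, rbind(v, v, v), design_meta())
  expect_equal(average_technical_replicates(s3)$absorbance[1, ], v)
  perm <- s3[c(3, 1, 2)]
  expect_equal(average_technical_replicates(perm)$absorbance,
               average_technical_replicates(s3)$absorbance)
})

test_that("the JCAMP-DX importer reads an AFFN X++(Y..Y) block", {
  f <- tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=demo", "##XUNITS=1/CM", "##XFACTOR=1", "##YFACTOR=0.5",
               "##FIRSTX=1000", "##LASTX=970", "##NPOINTS=6",
               "##XYDATA=(X++(Y..Y))",
               "1000 2 4 6", "982 8 10 12", "##END="), f)
  s <- read_jcamp(f)
  expect_equal(s$wavenumbers, seq(1000, 970, by = -6))
  expect_equal(s$absorbance[1, ], c(1, 2, 3, 4, 5, 6))
})
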