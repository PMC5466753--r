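test_that("FAME quantification follows the internal-standard arithmetic", {
  # one analyte with area equal to the IS, RRF 1, 0.5 mg IS, 30 mg biomass
  t1 <- quantify_fames(matrix(100, 1, 1, dimnames = list(NULL, "C16:0")),
                       is_area = 100, is_mass = 0.5, rrf = c("C16:0" = 1),
                       biomass_mass = 30)
  expect_equal(unname(t1$composition[1, 1]), 100)
  expect_equal(t1$total_lipid, 100 * 0.5 / 30, tolerance = 1e-12)

  # doubling all areas leaves composition unchanged, doubles total lipid
  areas <- matrix(c(10, 20, 5, 40), 1,
                  dimnames = list(NULL, c("C16:0", "C18:1n9", "C18:0", "C18:2n6")))
  rrf <- c("C16:0" = 1.1, "C18:1n9" = 0.95, "C18:0" = 1.05, "C18:2n6" = 0.9)
  t2 <- quantify_fames(areas, 50, 0.5, rrf, 30)
  t3 <- quantify_fames(2 * areas, 50, 0.5, rrf, 30)
  expect_equal(t2$composition, t3$composition, tolerance = 1e-12)
  expect_equal(2 * t2$total_lipid, t3$total_lipid, tolerance = 1e-12)

  # random instance vs direct spreadsheet-style arithmetic
  set.seed(4)
  ar <- matrix(runif(4, 10, 200), 1, dimnames = dimnames(areas))
  q <- quantify_fames(ar, 80, 0.4, rrf, 25)
  mass <- ar[1, ] / 80 * rrf[colnames(ar)] * 0.4
  expect_equal(q$composition[1, ], 100 * mass / sum(mass), tolerance = 1e-10)
  expect_equal(q$total_lipid, 100 * sum(mass) / 25, tolerance = 1e-10)
  # composition sums to exactly 100 whatever the response factors
  expect_equal(unname(rowSums(q$composition)), 100, tolerance = 1e-12)

  expect_error(quantify_fames(areas, 0, 0.5, rrf, 30), "positive")
  expect_error(quantify_fames(0 * areas, 50, 0.5, rrf, 30), "signal")
})

test_that("unsaturation index counts double bonds per chain", {
  expect_equal(unsaturation_index(c("C18:1n9" = 100)), 1)
  expect_equal(unsaturation_index(c("C18:3n6" = 100)), 3)
  expect_equal(unsaturation_index(
    c("C18:1n9" = 40, "C18:2n6" = 20, "C18:3n3" = 10, "C16:0" = 30)), 1.1)
  # linear in composition, bounded by [0, 3]
  set.seed(9)
  for (i in 1:10) {
    w <- runif(4); w <- 100 * w / sum(w)
    comp <- setNames(w, c("C16:0", "C18:1n9", "C18:2n6", "C18:3n3"))
    ui <- unsaturation_index(comp)
    expect_gte(ui, 0); expect_lte(ui, 3)
    expect_equal(unsaturation_index(comp / 2) * 2, ui, tolerance = 1e-12)
  }
  expect_error(unsaturation_index(c("C99:9" = 100)), "not in the descriptor")
})

test_that("summed parameters partition the composition", {
  t1 <- fatty_acid_table(matrix(100, 1, 1, dimnames = list(NULL, "C16:0")))
  p1 <- fatty_acid_parameters(t1)
  expect_equal(p1[c("SAT", "MUFA", "PUFA", "unsaturation_index")],
               data.frame(SAT = 100, MUFA = 0, PUFA = 0, unsaturation_index = 0))

  t2 <- fatty_acid_table(matrix(c(50, 50), 1,
                                dimnames = list(NULL, c("C18:1n9", "C18:2n6"))))
  p2 <- fatty_acid_parameters(t2)
  expect_equal(unlist(p2[c("MUFA", "PUFA", "unsaturation_index")]),
               c(MUFA = 50, PUFA = 50, unsaturation_index = 1.5))

  sim <- sim_default()
  pa <- fatty_acid_parameters(sim$gc)
  expect_equal(pa$SAT + pa$MUFA + pa$PUFA,
               unname(rowSums(sim$gc$composition)), tolerance = 1e-10)
})

test_that("autoscaling standardises columns and is invertible", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  sc <- autoscale(m)
  expect_equal(unname(colMeans(sc$scaled)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(sc$scaled, 2, sd)), c(1, 1), tolerance = 1e-12)
  # idempotent on already-standardised data
  expect_equal(autoscale(sc$scaled)$scaled, sc$scaled, tolerance = 1e-12)
  # exact inverse transform
  back <- sweep(sweep(sc$scaled, 2, sc$sds, `*`), 2, sc$means, `+`)
  expect_equal(back, m, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(autoscale(cbind(ok = 1:3, flat = c(2, 2, 2))), "flat")
})

test_that("pooled SD combines replicate groups correctly", {
  expect_equal(pooled_sd(list(c(0, 2), c(10, 10))), 1)
  g <- list(c(1, 2, 3), c(11, 12, 13), c(5, 6, 7))  # identical spread
  expect_equal(pooled_sd(g), 1)
  expect_error(pooled_sd(list(c(1, 2), 3)), "at least 2")
  # sampling distribution: 70 triples at sigma = 1.1 recover sigma within 15%
  set.seed(10)
  groups <- replicate(70, rnorm(3, 50, 1.1), simplify = FALSE)
  expect_lt(abs(pooled_sd(groups) - 1.1) / 1.1, 0.15)
})

test_that("fatty acid tables round-trip through CSV", {
  sim <- sim_default()
  f <- tempfile(fileext = ".csv")
  write_fatty_acid_table(sim$gc, f)
  back <- read_fatty_acid_table(f)
  expect_equal(back$composition, sim$gc$composition, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(back$total_lipid, sim$gc$total_lipid, tolerance = 1e-10)
  expect_identical(back$meta$species, sim$gc$meta$species)
})

test_that("composition ingest warns on rows far from 100%", {
  expect_warning(fatty_acid_table(matrix(c(60, 30), 1,
                                         dimnames = list(NULL, c("C16:0", "C18:0")))),
                 "deviate")
  renorm <- suppressWarnings(
    fatty_acid_table(matrix(c(60, 30), 1,
                            dimnames = list(NULL, c("C16:0", "C18:0"))),
                     renormalize = TRUE))
  expect_equal(unname(rowSums(renorm$composition)), 100)
})
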