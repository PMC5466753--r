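test_that("SG second derivative is exact on polynomials of degree <= 2", {
  grid <- seq(2000, 1500, by = -6)
  s <- spectrum_set(grid, rbind(grid^2, 3 * grid + 7))
  d <- sg_derivative(s, window = 9, polyorder = 2, deriv = 2)
  expect_lt(max(abs(d$absorbance[1, ] - 2)), 1e-8)
  expect_lt(max(abs(d$absorbance[2, ])), 1e-8)
  # grid trimmed by half a window at each end
  expect_identical(length(d$wavenumbers), length(grid) - 8L)
  expect_equal(d$wavenumbers, grid[5:(length(grid) - 4)])
})

test_that("SG second derivative matches the analytic Gaussian derivative", {
  # closed-form oracle: d2/dx2 exp(-x^2 / (2 s^2))
  grid <- seq(2000, 1500, by = -3)
  sgm <- 15
  s <- gaussian_set(1745, sigmas = sgm, grid = grid)
  d <- sg_derivative(s)
  x <- d$wavenumbers - 1745
  analytic <- (x^2 / sgm^4 - 1 / sgm^2) * exp(-x^2 / (2 * sgm^2))
  expect_lt(max(abs(d$absorbance[1, ] - analytic)), 1e-3)
})

test_that("SG differentiation is linear and rejects bad grids", {
  grid <- seq(3000, 2500, by = -6)
  x <- rnorm(length(grid)); y <- rnorm(length(grid))
  s <- spectrum_set(grid, rbind(x, y, 2.5 * x - 4 * y))
  d <- sg_derivative(s)
  expect_lt(max(abs(2.5 * d$absorbance[1, ] - 4 * d$absorbance[2, ] -
                      d$absorbance[3, ])), 1e-10)
  bad <- 3000 - cumsum(c(0, 6, 6, 9, 6, 6, 12, 6, 6, 6))
  expect_error(sg_derivative(spectrum_set(bad, matrix(0, 1, length(bad)))),
               "uniform")
  expect_error(sg_derivative(spectrum_set(grid[1:5], matrix(0, 1, 5)),
                             window = 9), "larger than the grid")
})

test_that("EMSC recovers planted transformations exactly", {
  grid <- seq(1800, 800, by = -6)
  r <- exp(-(grid - 1650)^2 / 450) + 0.6 * exp(-(grid - 1080)^2 / 800)
  # identity: the reference itself fits with (a, b, c, d) = (0, 1, 0, 0)
  s <- spectrum_set(grid, rbind(r, 0.5 + 2 * r))
  out <- emsc(s, reference = r)
  expect_equal(unlist(out$coefficients[1, c("a", "b", "c", "d")]),
               c(a = 0, b = 1, c = 0, d = 0), tolerance = 1e-10)
  expect_equal(unlist(out$coefficients[2, c("a", "b")]), c(a = 0.5, b = 2),
               tolerance = 1e-10)
  expect_lt(max(abs(out$spectra$absorbance[2, ] - r)), 1e-10)

  # random planted coefficients, independent normal-equations oracle
  set.seed(42)
  p1 <- (grid - (max(grid) + min(grid)) / 2) / ((max(grid) - min(grid)) / 2)
  for (i in 1:5) {
    truth <- c(a = rnorm(1), b = runif(1, 0.5, 2), c = rnorm(1, 0, 0.3),
               d = rnorm(1, 0, 0.3))
    z <- truth["a"] + truth["c"] * p1 + truth["d"] * p1^2 + truth["b"] * r
    fit <- emsc(spectrum_set(grid, matrix(z, 1)), reference = r)
    got <- unlist(fit$coefficients[1, c("a", "b", "c", "d")])
    expect_equal(unname(got), unname(truth), tolerance = 1e-8)
    # independent oracle: solve the normal equations directly
    D <- cbind(1, p1, p1^2, r)
    beta <- solve(crossprod(D), crossprod(D, z))
    expect_equal(as.numeric(beta), unname(truth[c("a", "c", "d", "b")]),
                 tolerance = 1e-8)
    # span exactness: corrected spectrum equals the reference, residual-free
    expect_lt(max(abs(fit$spectra$absorbance[1, ] - r)), 1e-8)
  }
})

test_that("EMSC with polynomial order 0 reduces to classic MSC", {
  grid <- seq(1800, 800, by = -6)
  r <- exp(-(grid - 1650)^2 / 450)
  set.seed(7)
  z <- 0.3 + 1.7 * r + rnorm(length(grid), 0, 0.01)
  fit <- emsc(spectrum_set(grid, matrix(z, 1)), reference = r, poly_order = 0)
  ols <- lm(z ~ r)  # two-parameter least-squares oracle
  expect_equal(fit$coefficients$a, unname(coef(ols)[1]), tolerance = 1e-10)
  expect_equal(fit$coefficients$b, unname(coef(ols)[2]), tolerance = 1e-10)
  expect_true(is.na(fit$coefficients$c))
})

test_that("EMSC reports degenerate and rank-deficient fits", {
  grid <- seq(1800, 800, by = -6)
  r <- exp(-(grid - 1650)^2 / 450)
  z <- 0.2 + 0.001 * (grid / 1000)  # no reference contribution
  expect_error(emsc(spectrum_set(grid, rbind(r, z)), reference = r),
               "degenerate")
  p1 <- (grid - (max(grid) + min(grid)) / 2) / ((max(grid) - min(grid)) / 2)
  expect_error(emsc(spectrum_set(grid, matrix(r, 1)), reference = 2 + 3 * p1),
               "rank deficient")
})

test_that("full pipeline: 630 raw spectra become 210 corrected spectra", {
  sim <- simulate_experiment(seed = 2, drop = synthetic_drop_cells())
  pre <- preprocess_spectra(sim$spectra)
  expect_identical(n_samples(pre$spectra), 210L)
  # output grid = combined-region subset of the SG-trimmed grid
  wn <- pre$spectra$wavenumbers
  expect_true(all((wn >= 2800 & wn <= 3100) | (wn >= 500 & wn <= 1800)))
  expect_lt(max(wn), 3976 + 1e-9)
  # deterministic: no hidden randomness anywhere
  pre2 <- preprocess_spectra(sim$spectra)
  expect_identical(pre$spectra$absorbance, pre2$spectra$absorbance)
})

test_that("EMSC against a fixed reference is idempotent", {
  sim <- sim_default()
  sub <- sim$spectra[1:30]
  d <- select_region(sg_derivative(sub), list(c(3100, 2800), c(1800, 500)))
  once <- emsc(d)
  twice <- emsc(once$spectra, reference = once$reference)
  expect_lt(max(abs(twice$spectra$absorbance - once$spectra$absorbance)), 1e-10)
})

test_that("EMSC removes planted scatter from a shared truth spectrum", {
  grid <- instrument_grid()
  truth <- pure_component_spectra(grid)["lipid", ]
  p1 <- (grid - (max(grid) + min(grid)) / 2) / ((max(grid) - min(grid)) / 2)
  set.seed(11)
  n <- 24
  raw <- t(vapply(seq_len(n), function(i) {
    runif(1, 0.7, 1.3) * truth + runif(1, -0.05, 0.05) +
      runif(1, -0.02, 0.02) * p1 + runif(1, -0.01, 0.01) * p1^2
  }, numeric(length(grid))))
  s <- spectrum_set(grid, raw)
  rms_between <- function(m) sqrt(mean(scale(m, scale = FALSE)^2))
  corrected <- emsc(s)$spectra$absorbance
  expect_lt(rms_between(corrected), 1e-6 * rms_between(raw))
})
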