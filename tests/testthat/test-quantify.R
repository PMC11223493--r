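test_that("correction factors: pooled arithmetic and uncertainties", {
  cf <- estimate_correction_factors(data.frame(
    class = "cA6", n_events = 100, duration_s = 100, concentration_uM = 1))
  expect_equal(cf$cf, 1.0)
  expect_equal(cf$cf_sd, sqrt(100) / 100)     # Poisson for a single trace
  # two traces with identical rates: zero between-trace SD
  cf2 <- estimate_correction_factors(data.frame(
    class = "x", n_events = c(50, 100), duration_s = c(50, 100),
    concentration_uM = 1))
  expect_equal(cf2$cf, 1.0)
  expect_equal(cf2$cf_sd, 0)
  expect_error(estimate_correction_factors(data.frame(
    class = "x", n_events = 1, duration_s = 0, concentration_uM = 1)),
    "zero")
})

test_that("composition: rate-corrected fractions and scaling invariance", {
  cfs <- c(cA34 = 0.17, cA5 = 0.62, cA6 = 0.12)
  comp <- estimate_composition(c(cA34 = 17, cA5 = 62, cA6 = 12), 100, cfs)
  expect_equal(unname(comp$fractions), rep(1 / 3, 3))
  expect_equal(comp$r_e, 91 / 100)
  expect_equal(sum(comp$fractions), 1)
  # single nonzero class
  one <- estimate_composition(c(cA34 = 0, cA5 = 40, cA6 = 0), 10, cfs)
  expect_equal(unname(one$fractions), c(0, 1, 0))
  # doubling time with proportional counts changes nothing
  a <- estimate_composition(c(cA34 = 20, cA5 = 30, cA6 = 10), 50, cfs)
  b <- estimate_composition(c(cA34 = 40, cA5 = 60, cA6 = 20), 100, cfs)
  expect_equal(a$fractions, b$fractions)
  expect_error(estimate_composition(c(cA34 = 0, cA5 = 0, cA6 = 0), 10, cfs),
               "zero total")
  expect_error(estimate_composition(c(zz = 5), 10, cfs), "zz")
})

test_that("prediction intervals summarize fold spread correctly", {
  same <- matrix(0.5, 5, 2, dimnames = list(NULL, c("a", "b")))
  pi0 <- prediction_interval(same)
  expect_equal(pi0$lower, pi0$upper)
  expect_equal(pi0$mean, c(0.5, 0.5))
  set.seed(400)
  base <- matrix(rnorm(30, 0.5, 0.01), 10, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  wide <- base + matrix(rnorm(30, 0, 0.05), 10, 3)
  pi1 <- prediction_interval(base)
  pi2 <- prediction_interval(base + (wide - base) * 3)
  expect_true(all(pi1$lower <= pi1$mean & pi1$mean <= pi1$upper))
  expect_true(all(pi2$upper - pi2$lower > pi1$upper - pi1$lower))
  expect_error(prediction_interval(base[1:2, ]), "at least 3")
})

test_that("absolute yield: unit construction and printed worked examples", {
  cfs <- c(x = 0.5)
  y <- absolute_yield(r_e = 0.5, fractions = c(x = 1), cfs = cfs, d = 1,
                      complex_conc_uM = 1)
  expect_equal(y$total, 1)           # r_e/CF = 1 uM; d = 1; complex 1 uM
  expect_equal(y$total_sd, 0)        # zero input uncertainties
})

test_that("absolute yield is homogeneous in its inputs", {
  cfs <- c(cA34 = 0.17, cA5 = 0.62, cA6 = 0.12)
  fr <- c(cA34 = 0.89, cA5 = 0.08, cA6 = 0.03)
  y1 <- absolute_yield(0.47, fr, cfs, d = 21, complex_conc_uM = 0.0625)
  y2 <- absolute_yield(0.94, fr, cfs, d = 21, complex_conc_uM = 0.0625)
  expect_equal(y2$total, 2 * y1$total)
  expect_equal(y2$per_class$molecules_per_complex,
               2 * y1$per_class$molecules_per_complex)
  y3 <- absolute_yield(0.47, fr, cfs * 2, d = 21, complex_conc_uM = 0.0625)
  expect_equal(y3$total, y1$total / 2)
  expect_equal(y1$total, sum(y1$per_class$molecules_per_complex))
})

test_that("yield uncertainty propagation responds to each input error", {
  cfs <- c(a = 0.2, b = 0.4)
  fr <- c(a = 0.7, b = 0.3)
  y0 <- absolute_yield(1, fr, cfs, d = 10, complex_conc_uM = 0.1)
  expect_equal(y0$total_sd, 0)
  yr <- absolute_yield(1, fr, cfs, d = 10, complex_conc_uM = 0.1,
                       r_e_sd = 0.1)
  expect_equal(yr$total_sd, 0.1 * y0$total)   # pure relative r_e error
  ycf <- absolute_yield(1, fr, cfs, d = 10, complex_conc_uM = 0.1,
                        cf_sd = c(0.02, 0))
  # only class a contributes: |d total/d CF_a| * sd = (yield_a/CF_a) * sd
  expect_equal(ycf$total_sd,
               y0$per_class$molecules_per_complex[1] / 0.2 * 0.02)
})

test_that("LC-MS estimators reproduce the equimolar pooling example", {
  mono <- c(cA3 = 4e5, cA4 = 5e5, cA5 = 3e5, cA6 = 2e5)
  conc <- lcms_concentrations(mono, mono / 4)
  expect_equal(conc$concentration_uM, rep(12.5, 4))
  rat <- lcms_ratios(conc)
  expect_equal(rat$ratio_pct, rep(25, 4))
  expect_equal(sum(rat$ratio_pct), 100)
})

test_that("LC-MS handles absent species and rejects zero calibration", {
  mono <- c(a = 1000, b = 2000)
  conc <- lcms_concentrations(mono, c(a = 0, b = 1000))
  expect_equal(conc$concentration_uM, c(0, 25))
  rat <- lcms_ratios(conc)
  expect_equal(rat$ratio_pct, c(0, 100))
  expect_equal(sum(rat$ratio_pct), 100)
  expect_error(lcms_concentrations(c(a = 0, b = 1), c(a = 1, b = 1)),
               "zero monodisperse.*a")
})

test_that("LC-MS ratios always sum to 100% on random inputs", {
  set.seed(401)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    conc <- setNames(runif(k, 0.1, 60), paste0("s", 1:k))
    expect_equal(sum(lcms_ratios(conc)$ratio_pct), 100, tolerance = 1e-10)
  }
})
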