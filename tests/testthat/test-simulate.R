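test_that("zero concentration gives pure baseline and no annotations", {
  cfg <- simulation_config(duration = 0.2,
                           classes = default_classes(c(0, 0, 0)), seed = 1)
  sim <- simulate_trace(cfg)
  expect_equal(nrow(sim$annotations), 0L)
  expect_equal(mean(sim$trace$samples), 1000,
               tolerance = 3 * 15 / sqrt(length(sim$trace$samples)) / 1000)
  expect_equal(length(sim$trace$samples), 0.2 * 5e5)
})

test_that("event counts follow the Poisson rate cf x concentration", {
  # 10 uM at cf = 0.12 over 100 s -> expect 120 events (within 3 sqrt(120));
  # simulated at a low sampling rate (rate statistics are rate-independent)
  cfg <- simulation_config(duration = 100, sampling_rate = 2e4,
    filter_cutoff = NA,
    classes = list(cA6 = list(concentration = 10, cf = 0.12,
                              dwell_mean = 315e-6, dwell_sd = 26e-6,
                              blockade_mean = 400, blockade_sd = 30)),
    seed = 2024)
  sim <- simulate_trace(cfg)
  expect_lt(abs(nrow(sim$annotations) - 120), 3 * sqrt(120))
})

test_that("identical seeds give bit-identical traces and annotations", {
  cfg <- simulation_config(duration = 0.3, seed = 77)
  a <- simulate_trace(cfg)
  b <- simulate_trace(cfg)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$annotations, b$annotations)
})

test_that("annotated events are sorted, non-overlapping and in range", {
  cfg <- simulation_config(duration = 1, seed = 5,
                           classes = default_classes(c(60, 30, 60)))
  sim <- simulate_trace(cfg)
  ann <- sim$annotations
  expect_gt(nrow(ann), 10)
  expect_true(all(diff(ann$start) > 0))
  expect_true(all(ann$start[-1] >= ann$end[-nrow(ann)]))
  expect_true(all(ann$end <= length(sim$trace$samples)))
  expect_true(all(ann$class %in% c("cA34", "cA5", "cA6")))
})

test_that("annotation dwell moments match the configured log-normal", {
  cfg <- simulation_config(duration = 40, sampling_rate = 5e4,
    filter_cutoff = NA,
    classes = list(cA6 = list(concentration = 10, cf = 12,
                              dwell_mean = 315e-6, dwell_sd = 26e-6,
                              blockade_mean = 400, blockade_sd = 30)),
    seed = 9)
  ann <- simulate_trace(cfg)$annotations
  n <- nrow(ann)
  expect_gt(n, 3000)
  expect_equal(mean(ann$duration_s), 315e-6,
               tolerance = 4 * 26e-6 / sqrt(n) / 315e-6)
  expect_equal(sd(ann$duration_s), 26e-6, tolerance = 0.1)
  expect_equal(mean(ann$depth_pA), 400, tolerance = 4 * 30 / sqrt(n) / 400)
})

test_that("infeasible occupancy is rejected", {
  cfg <- simulation_config(duration = 0.5, sampling_rate = 5e4,
    filter_cutoff = NA,
    classes = list(a = list(concentration = 1000, cf = 10,
                            dwell_mean = 5e-3, dwell_sd = 1e-3,
                            blockade_mean = 400, blockade_sd = 30)),
    seed = 1)
  expect_error(simulate_trace(cfg), "occupancy")
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(classes = list(
    a = list(concentration = -1, cf = 1, dwell_mean = 1e-4, dwell_sd = 1e-5,
             blockade_mean = 400, blockade_sd = 30))), ">= 0")
  expect_error(simulation_config(classes = list(
    a = list(concentration = 1, cf = 1, dwell_mean = 1e-4, dwell_sd = 1e-5,
             blockade_mean = 1200, blockade_sd = 30))), "open-pore")
  expect_error(simulation_config(classes = list(
    a = list(concentration = 1, cf = 1, dwell_mean = 1e-4,
             blockade_mean = 400))), "missing fields")
})

test_that("EIC peak simulation is linear with exact dilution behaviour", {
  # zero concentration and exact linearity, noise-free
  tab <- simulate_eic_peaks(c(cA3 = 0, cA4 = 50), response_factors = 1000)
  expect_equal(tab$area, c(0, 50000))
  # equal-volume 4-way pooling of 50 uM stocks: areas are 1/4 of mono
  mono <- simulate_eic_peaks(setNames(rep(50, 4), paste0("cA", 3:6)),
                             response_factors = c(800, 1000, 600, 400))
  mix <- simulate_eic_peaks(setNames(rep(50 / 4, 4), paste0("cA", 3:6)),
                            response_factors = c(800, 1000, 600, 400))
  expect_equal(mix$area, mono$area / 4)
})

test_that("negative simulated areas are clipped with a warning", {
  expect_warning(
    tab <- simulate_eic_peaks(c(a = 1), response_factors = 1,
                              noise_rel_sd = 10, seed = 1),
    "clipped")
  expect_true(all(tab$area >= 0))
})
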