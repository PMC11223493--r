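test_that("zero-phase low-pass has unit DC gain on a constant trace", {
  tr <- current_trace(rep(1000, 5000), sampling_rate = 5e5)
  fl <- lowpass_filter(tr, 8e4)
  expect_equal(fl$samples, rep(1000, 5000), tolerance = 1e-9)
  expect_equal(fl$sampling_rate, 5e5)
})

test_that("sinusoid attenuation matches the filter's frequency response", {
  # oracle: direct evaluation of the digital transfer function; filtfilt
  # applies |H|^2
  fs <- 5e5; fc <- 8e4; f0 <- 2 * fc
  ba <- coapore:::bessel_lowpass(fc, fs, net = TRUE)
  z <- exp(-1i * 2 * pi * f0 / fs)
  H <- sum(ba$b * z^(0:4)) / sum(ba$a * z^(0:4))
  expected_gain <- Mod(H)^2
  tt <- (0:49999) / fs
  tr <- current_trace(1000 + 100 * sin(2 * pi * f0 * tt), fs)
  fl <- lowpass_filter(tr, fc)
  core <- 5000:45000   # avoid startup transients at the edges
  measured <- sqrt(mean((fl$samples[core] - 1000)^2)) / (100 / sqrt(2))
  expect_equal(measured, expected_gain, tolerance = 0.02)
  expect_lt(expected_gain, 0.2)   # stop-band: strong attenuation at 2 fc
})

test_that("filtering removes energy from white noise", {
  set.seed(1)
  tr <- current_trace(rnorm(1e5, 1000, 20), sampling_rate = 5e5)
  fl <- lowpass_filter(tr, 8e4)
  expect_lt(var(fl$samples), var(tr$samples))
})

test_that("cutoff at or above Nyquist is rejected", {
  tr <- current_trace(rep(1000, 1000), sampling_rate = 1e5)
  expect_error(lowpass_filter(tr, 5e4), "Nyquist")
  expect_error(lowpass_filter(tr, 6e4), "Nyquist")
})

test_that("median decimation follows the [6,6,6,7] pattern for 500->80 kHz", {
  expect_identical(coapore:::decimation_pattern(5e5, 8e4),
                   c(6L, 6L, 6L, 7L))
  n <- 10000
  tr <- current_trace(seq_len(n), sampling_rate = 5e5)
  dec <- decimate_median(tr, 8e4)
  expect_equal(length(dec$samples), floor(n / 6.25))
  expect_equal(dec$sampling_rate, 8e4)
})

test_that("decimation matches a brute-force per-window median", {
  set.seed(7)
  x <- rnorm(1000, 1000, 50)
  tr <- current_trace(x, sampling_rate = 5e5)
  dec <- decimate_median(tr, 8e4)
  # oracle: explicit window walk
  pattern <- rep_len(c(6, 6, 6, 7), 1000)
  pos <- 1; expected <- c()
  for (w in pattern) {
    if (pos + w - 1 > length(x)) break
    expected <- c(expected, median(x[pos:(pos + w - 1)]))
    pos <- pos + w
  }
  expect_equal(dec$samples, expected)
})

test_that("decimation preserves constants and suppresses outliers", {
  tr <- current_trace(rep(1000, 625), sampling_rate = 5e5)
  expect_true(all(decimate_median(tr, 8e4)$samples == 1000))
  x <- rep(1000, 625); x[100] <- -5000      # single spike inside a window
  tr2 <- current_trace(x, sampling_rate = 5e5)
  expect_true(all(decimate_median(tr2, 8e4)$samples == 1000))
  expect_error(decimate_median(tr, 5e5), "below")
  expect_error(decimate_median(tr, -1), "positive")
})

test_that("open-pore estimation is robust to event content", {
  set.seed(3)
  tr <- current_trace(rnorm(5000, 1000, 10), sampling_rate = 8e4)
  expect_equal(estimate_open_pore(tr), 1000, tolerance = 1e-2)
  # 1% of samples blocked at 600 pA: oracle = median of constructed
  # baseline-only samples
  x <- rnorm(10000, 1000, 10)
  blocked <- sample(10000, 100)
  x[blocked] <- 600
  tr2 <- current_trace(x, sampling_rate = 8e4)
  oracle <- median(x[x > 0.8 * median(x)])
  expect_equal(estimate_open_pore(tr2), oracle)
  expect_equal(estimate_open_pore(tr2), 1000, tolerance = 1e-2)
})

test_that("degenerate traces are rejected by open-pore estimation", {
  expect_error(estimate_open_pore(current_trace(rep(0, 1000), 8e4)),
               "non-positive")
  x <- c(rep(100, 600), rep(1000, 400))   # blockades dominate
  expect_error(estimate_open_pore(current_trace(x, 8e4)), "dominated")
})
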