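#' Distribution fits for event durations and blockades
#'
#' `fit_duration_lognormal()` fits a log-normal to event dwell times by
#' maximum likelihood (closed form on log durations) and reports both the
#' (meanlog, sdlog) parameters and the implied arithmetic mean and SD.
#' `fit_blockade_normal()` fits a normal distribution to blockade depths.
#'
#' @param durations event durations in seconds (> 0), at least 10 values.
#' @param blockades blockade depths in pA, at least 10 values.
#' @return `fit_duration_lognormal()`: a list of class `duration_fit` with
#'   `meanlog`, `sdlog`, `mean`, `sd`, `n`, `loglik`.
#'   `fit_blockade_normal()`: a list of class `blockade_fit` with `mean`,
#'   `sd`, `n`, `loglik`.
#' @examples
#' d <- rlnorm(1000, log(3e-4), 0.1)
#' fit_duration_lognormal(d)$mean
#' @export
fit_duration_lognormal <- function(durations) {
  durations <- as.numeric(durations)
  if (length(durations) < 10) stop("need at least 10 durations", call. = FALSE)
  if (any(durations <= 0)) stop("durations must be > 0", call. = FALSE)
  lg <- log(durations)
  if (var(lg) == 0)
    stop("degenerate input: all durations equal (zero variance)", call. = FALSE)
  meanlog <- mean(lg)
  sdlog <- sqrt(mean((lg - meanlog)^2))     # MLE (n denominator)
  m <- exp(meanlog + sdlog^2 / 2)
  s <- m * sqrt(expm1(sdlog^2))
  ll <- sum(stats::dlnorm(durations, meanlog, sdlog, log = TRUE))
  structure(list(meanlog = meanlog, sdlog = sdlog, mean = m, sd = s,
                 n = length(durations), loglik = ll),
            class = "duration_fit")
}

#' @rdname fit_duration_lognormal
#' @export
fit_blockade_normal <- function(blockades) {
  blockades <- as.numeric(blockades)
  if (length(blockades) < 10) stop("need at least 10 blockades", call. = FALSE)
  if (var(blockades) == 0)
    stop("degenerate input: all blockades equal (zero variance)", call. = FALSE)
  m <- mean(blockades)
  s <- sqrt(mean((blockades - m)^2))        # MLE
  ll <- sum(stats::dnorm(blockades, m, s, log = TRUE))
  structure(list(mean = m, sd = s, n = length(blockades), loglik = ll),
            class = "blockade_fit")
}

#' Bootstrap time constant of the dwell-time survival curve
#'
#' Resamples the durations with replacement `n_resamples` times and fits
#' each resample with a single-exponential survival model with free offset,
#' `S(t) = exp(-(t - t0)/tau)` for `t >= t0`. The fit is the closed-form
#' maximum-likelihood solution of the shifted exponential
#' (`t0 = min(t)`, `tau = mean(t) - min(t)`). The reported time constant is
#' the mean of the bootstrapped `tau` values and its uncertainty their
#' standard deviation. Degenerate resamples (zero spread) are dropped and
#' counted; more than 10% dropped is an error.
#'
#' @param durations event durations in seconds, at least 20 values.
#' @param n_resamples number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return A list of class `bootstrap_result` with `tau`, `uncertainty`,
#'   `t0`, `n_resamples`, `n_dropped`.
#' @examples
#' d <- 5e-5 + rexp(500, 1 / 3e-4)
#' bootstrap_duration(d, n_resamples = 200, seed = 1)$tau
#' @export
bootstrap_duration <- function(durations, n_resamples = 1000L, seed = NULL) {
  durations <- as.numeric(durations)
  if (length(durations) < 20) stop("need at least 20 durations", call. = FALSE)
  stop_if_not_scalar_pos(n_resamples, "n_resamples")
  n <- length(durations)
  with_seed(seed, {
    taus <- numeric(n_resamples); t0s <- numeric(n_resamples)
    ok <- logical(n_resamples)
    for (b in seq_len(n_resamples)) {
      res <- durations[sample.int(n, n, replace = TRUE)]
      t0 <- min(res); tau <- mean(res) - t0
      if (tau > 0) { taus[b] <- tau; t0s[b] <- t0; ok[b] <- TRUE }
    }
    n_drop <- sum(!ok)
    if (n_drop > 0.1 * n_resamples)
      stop(sprintf("%d of %d bootstrap fits degenerate (>10%%)",
                   n_drop, n_resamples), call. = FALSE)
    structure(list(tau = mean(taus[ok]), uncertainty = sd(taus[ok]),
                   t0 = mean(t0s[ok]), n_resamples = as.integer(n_resamples),
                   n_dropped = n_drop),
              class = "bootstrap_result")
  })
}
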