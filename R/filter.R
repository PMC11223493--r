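# Low-pass filtering, median-conserving decimation and open-pore estimation.

# 4th-order Bessel low-pass prototype, -3 dB frequency normalized to 1 rad/s
# (standard Bessel-Thomson pole table).
BESSEL4_POLES <- c(-0.9952087643502788 + 1.2571057394546700i,
                   -0.9952087643502788 - 1.2571057394546700i,
                   -1.3700678305514334 + 0.4102497174937433i,
                   -1.3700678305514334 - 0.4102497174937433i)

# Frequency scale at which the single-pass magnitude is -1.5 dB, so that a
# forward-backward (zero-phase) application is -3 dB at the nominal cutoff.
BESSEL4_NET_SCALE <- 0.7225991870

# Digital 4-pole Bessel low-pass via bilinear transform with frequency
# prewarping. `net = TRUE` places the -3 dB point of the squared
# (forward-backward) response at `cutoff`; `net = FALSE` designs a plain
# single-pass -3 dB filter. Returns list(b, a) polynomial coefficients.
bessel_lowpass <- function(cutoff, sampling_rate, net = FALSE) {
  stop_if_not_scalar_pos(cutoff, "cutoff")
  stop_if_not_scalar_pos(sampling_rate, "sampling_rate")
  if (net) cutoff <- cutoff / BESSEL4_NET_SCALE
  if (cutoff >= sampling_rate / 2)
    stop("`cutoff` must be below the Nyquist frequency", call. = FALSE)
  fs2 <- 2 * sampling_rate
  wa <- fs2 * tan(pi * cutoff / sampling_rate)  # prewarped analog cutoff
  p <- BESSEL4_POLES * wa
  k <- Re(prod(-p))                             # unit DC gain
  # bilinear transform s = fs2 (1 - z^-1)/(1 + z^-1); all-pole prototype:
  # 4 zeros land at z = -1.
  pd <- (1 + p / fs2) / (1 - p / fs2)
  kd <- k / Re(prod(fs2 - p))
  b <- kd * c(1, 4, 6, 4, 1)                    # (1 + z^-1)^4
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

# Monic polynomial coefficients from roots (descending powers).
poly_from_roots <- function(r) {
  cf <- 1
  for (ri in r) cf <- c(cf, 0) - c(0, cf * ri)
  cf
}

#' Zero-phase low-pass filtering of a current trace
#'
#' Applies a digital 4-pole Bessel low-pass filter forward and backward
#' ([signal::filtfilt()]), so the filter is zero phase and event boundaries
#' are not shifted. DC gain is 1. Because the forward-backward pass squares
#' the magnitude response, the filter is designed so that the *net*
#' zero-phase response is -3 dB at `cutoff` (each pass has its corner at
#' `cutoff / 0.723`).
#'
#' @param trace a [current_trace()].
#' @param cutoff net -3 dB cutoff frequency in Hz; `cutoff / 0.723` must be
#'   below Nyquist.
#' @return A filtered [current_trace()] of the same length and sampling rate;
#'   `metadata$filter_hz` records the cutoff.
#' @examples
#' tr <- current_trace(rnorm(5000, 1000, 20), sampling_rate = 5e5)
#' fl <- lowpass_filter(tr, 8e4)
#' var(fl$samples) < var(tr$samples)
#' @export
lowpass_filter <- function(trace, cutoff) {
  stopifnot(inherits(trace, "current_trace"))
  ba <- bessel_lowpass(cutoff, trace$sampling_rate, net = TRUE)
  x <- trace$samples
  n <- length(x)
  # reflection padding absorbs the zero-state startup transient at the ends
  np <- min(n - 1L, 30L * ceiling(trace$sampling_rate / cutoff))
  xp <- c(x[(np + 1L):2L], x, x[(n - 1L):(n - np)])
  y <- signal::filtfilt(signal::Arma(b = ba$b, a = ba$a), xp)
  y <- y[(np + 1L):(np + n)]
  meta <- trace$metadata
  meta$filter_hz <- cutoff
  current_trace(y, trace$sampling_rate, trace$voltage, meta)
}

#' Median-conserving decimation
#'
#' Reduces the sampling rate by replacing consecutive sample windows with
#' their medians. Window lengths follow the shortest repeating integer
#' pattern whose mean equals `sampling_rate / target_rate` (e.g. `[6,6,6,7]`
#' for 500 kHz to 80 kHz, mean 6.25), so the output rate is exact and the
#' median suppresses isolated outlier samples.
#'
#' @param trace a [current_trace()].
#' @param target_rate output sampling rate in Hz, below the input rate.
#' @return A decimated [current_trace()] with `sampling_rate = target_rate`.
#' @examples
#' tr <- current_trace(rep(1000, 1000), sampling_rate = 5e5)
#' dec <- decimate_median(tr, 8e4)
#' dec$sampling_rate
#' @export
decimate_median <- function(trace, target_rate) {
  stopifnot(inherits(trace, "current_trace"))
  stop_if_not_scalar_pos(target_rate, "target_rate")
  if (target_rate >= trace$sampling_rate)
    stop("`target_rate` must be below the trace sampling rate", call. = FALSE)
  pattern <- decimation_pattern(trace$sampling_rate, target_rate)
  y <- decimate_median_cpp(trace$samples, pattern)
  current_trace(y, target_rate, trace$voltage, trace$metadata)
}

# Repeating integer window-length pattern with mean = sampling_rate/target.
# The ratio is approximated as a fraction num/den in lowest terms; the
# pattern spreads `num` samples over `den` windows (e.g. 25/4 -> 6,6,6,7).
decimation_pattern <- function(sampling_rate, target_rate) {
  ratio <- sampling_rate / target_rate
  den <- which(abs(ratio * seq_len(64) - round(ratio * seq_len(64))) < 1e-9)[1]
  if (is.na(den)) { # irrational-ish ratio: round per-window boundaries
    den <- 64L
  }
  num <- round(ratio * den)
  bounds <- floor(seq_len(den) * num / den)
  pattern <- as.integer(diff(c(0L, bounds)))
  if (any(pattern < 1L))
    stop("`target_rate` too close to the sampling rate for integer windows",
         call. = FALSE)
  pattern
}

#' Estimate the open-pore (baseline) current of a trace
#'
#' The unblocked current level is estimated as the median of all samples
#' above 80% of the trace's global median. This is robust to event content
#' as long as blockades do not dominate the recording.
#'
#' @param trace a [current_trace()].
#' @param min_baseline_frac error if fewer than this fraction of samples are
#'   attributable to baseline (default 0.5).
#' @return The open-pore current in pA.
#' @examples
#' tr <- current_trace(rnorm(5000, 1000, 10), sampling_rate = 5e5)
#' estimate_open_pore(tr)
#' @export
estimate_open_pore <- function(trace, min_baseline_frac = 0.5) {
  stopifnot(inherits(trace, "current_trace"))
  x <- trace$samples
  if (length(x) < 100)
    stop("trace too short for open-pore estimation", call. = FALSE)
  med <- median(x)
  if (!is.finite(med) || med <= 0)
    stop("trace has non-positive median current; cannot locate baseline",
         call. = FALSE)
  # if the median sits well below the upper current level, blockades occupy
  # more than half the trace and the baseline is not identifiable
  if (med < 0.8 * quantile(x, 0.95))
    stop("trace dominated by blockades (median below 80% of the open-pore ",
         "level); open-pore current is not identifiable", call. = FALSE)
  keep <- x > 0.8 * med
  if (mean(keep) < min_baseline_frac)
    stop("trace dominated by blockades; open-pore current is not ",
         "identifiable", call. = FALSE)
  median(x[keep])
}
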