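#' Threshold-based translocation event detection
#'
#' An event is every maximal run of samples strictly below
#' `threshold_frac * open_pore` (the resistive-pulse criterion; samples at
#' exactly the threshold count as baseline). Runs shorter than
#' `min_event_samples` are discarded as single-sample noise spikes.
#'
#' For each event the duration is the run length divided by the sampling
#' rate, the mean blockade `deltaI_pA` is the open-pore current minus the
#' mean in-event current, and `rel_blockade = deltaI_pA / open_pore`.
#'
#' @param trace a [current_trace()], normally filtered and decimated first.
#' @param open_pore open-pore current in pA (see [estimate_open_pore()]).
#' @param threshold_frac detection threshold as a fraction of the open-pore
#'   current (default 0.65).
#' @param min_event_samples minimum run length in samples (default 2).
#' @return A data frame of class `translocation_events` with columns
#'   `trace_id`, `event_id`, `start`, `end` (0-based, half-open, in samples
#'   of `trace`), `duration_s`, `deltaI_pA`, `rel_blockade`.
#' @examples
#' x <- rep(1000, 2000); x[500:520] <- 600
#' tr <- current_trace(x, sampling_rate = 8e4)
#' detect_events(tr, open_pore = 1000)
#' @export
detect_events <- function(trace, open_pore, threshold_frac = 0.65,
                          min_event_samples = 2L) {
  stopifnot(inherits(trace, "current_trace"))
  stop_if_not_scalar_pos(open_pore, "open_pore")
  if (!is.numeric(threshold_frac) || threshold_frac <= 0 || threshold_frac >= 1)
    stop("`threshold_frac` must be in (0, 1)", call. = FALSE)
  thr <- threshold_frac * open_pore
  below <- trace$samples < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & r$lengths >= min_event_samples
  starts <- starts[sel]; ends <- ends[sel]
  trace_id <- trace$metadata$trace_id %||% NA_character_
  if (!length(starts)) {
    out <- data.frame(trace_id = character(), event_id = integer(),
                      start = integer(), end = integer(),
                      duration_s = numeric(), deltaI_pA = numeric(),
                      rel_blockade = numeric())
  } else {
    mean_in <- vapply(seq_along(starts), function(i)
      mean(trace$samples[starts[i]:ends[i]]), 0)
    out <- data.frame(
      trace_id = rep(as.character(trace_id), length(starts)),
      event_id = seq_along(starts),
      start = starts - 1L,              # 0-based, half-open
      end = ends,
      duration_s = (ends - starts + 1L) / trace$sampling_rate,
      deltaI_pA = open_pore - mean_in,
      rel_blockade = (open_pore - mean_in) / open_pore)
  }
  attr(out, "open_pore") <- open_pore
  attr(out, "sampling_rate") <- trace$sampling_rate
  attr(out, "trace_duration_s") <- length(trace$samples) / trace$sampling_rate
  class(out) <- c("translocation_events", "data.frame")
  out
}

#' Run the standard event-extraction pipeline on a raw trace
#'
#' Convenience wrapper chaining [lowpass_filter()], [decimate_median()],
#' [estimate_open_pore()] and [detect_events()] with the acquisition-style
#' defaults (80 kHz digital low-pass, median decimation to 80 kHz, threshold
#' at 65% of the open-pore current).
#'
#' @inheritParams detect_events
#' @param filter_cutoff digital low-pass cutoff in Hz.
#' @param target_rate decimation target rate in Hz.
#' @param open_pore open-pore current in pA, or `NULL` to estimate it from
#'   the decimated trace.
#' @return A list with elements `events` (see [detect_events()]),
#'   `trace` (the filtered, decimated [current_trace()]) and `open_pore`.
#' @export
extract_events <- function(trace, filter_cutoff = 8e4, target_rate = 8e4,
                           open_pore = NULL, threshold_frac = 0.65,
                           min_event_samples = 2L) {
  fl <- lowpass_filter(trace, filter_cutoff)
  dec <- decimate_median(fl, target_rate)
  if (is.null(open_pore)) open_pore <- estimate_open_pore(dec)
  ev <- detect_events(dec, open_pore, threshold_frac, min_event_samples)
  list(events = ev, trace = dec, open_pore = open_pore)
}
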