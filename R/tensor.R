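#' Fixed-length classifier input tensors for detected events
#'
#' Converts detected events into the fixed-length representation the
#' per-event classifier consumes: the event plus `flank` baseline samples on
#' either side, individually normalized (flank mean subtracted, divided by
#' the segment standard deviation), right-zero-padded to `width` points,
#' with the event duration appended as one final feature (log10 seconds,
#' z-scored by training-set statistics), for a total length of `width + 1`.
#'
#' Events too close to a trace edge for full flanks, or longer than
#' `width - 2 * flank` samples, are skipped with a warning and reported in
#' the `skipped` attribute.
#'
#' @param trace the (decimated) [current_trace()] the events were detected
#'   on.
#' @param events a `translocation_events` data frame from [detect_events()].
#' @param flank number of baseline samples kept on each side (default 47).
#' @param width padded signal width in samples (default 250).
#' @param dur_stats list with `mean` and `sd` of log10 duration over the
#'   training set (see [duration_feature_stats()]); defaults to the events
#'   at hand.
#' @return A numeric matrix with one row per kept event and `width + 1`
#'   columns, with attributes `kept` (row indices into `events`) and
#'   `skipped` (named counts: `edge`, `too_long`).
#' @examples
#' x <- rep(1000, 4000); x[2000:2024] <- 600
#' tr <- current_trace(x + rnorm(4000, 0, 5), sampling_rate = 8e4)
#' ev <- detect_events(tr, 1000)
#' tens <- event_tensors(tr, ev)
#' dim(tens)
#' @export
event_tensors <- function(trace, events, flank = 47L, width = 250L,
                          dur_stats = NULL) {
  stopifnot(inherits(trace, "current_trace"), nrow(events) >= 1L)
  flank <- as.integer(flank); width <- as.integer(width)
  if (2L * flank >= width)
    stop("`width` must exceed twice the flank length", call. = FALSE)
  if (is.null(dur_stats)) dur_stats <- duration_feature_stats(events$duration_s)
  n <- length(trace$samples)
  max_len <- width - 2L * flank
  out <- matrix(NA_real_, nrow(events), width + 1L)
  kept <- logical(nrow(events))
  n_edge <- 0L; n_long <- 0L
  for (i in seq_len(nrow(events))) {
    s <- events$start[i] + 1L        # back to 1-based
    e <- events$end[i]               # inclusive last sample
    len <- e - s + 1L
    if (s - flank < 1L || e + flank > n) { n_edge <- n_edge + 1L; next }
    if (len > max_len) { n_long <- n_long + 1L; next }
    seg <- trace$samples[(s - flank):(e + flank)]
    flank_idx <- c(seq_len(flank), flank + len + seq_len(flank))
    seg <- seg - mean(seg[flank_idx])
    ssd <- sd(seg)
    if (ssd <= 0) { n_edge <- n_edge + 1L; next }   # flat segment: unusable
    seg <- seg / ssd
    out[i, seq_along(seg)] <- seg
    if (length(seg) < width) out[i, (length(seg) + 1L):width] <- 0
    out[i, width + 1L] <-
      (log10(events$duration_s[i]) - dur_stats$mean) / dur_stats$sd
    kept[i] <- TRUE
  }
  if (n_edge + n_long > 0L)
    warning(sprintf("skipped %d event(s): %d at trace edge, %d longer than %d samples",
                    n_edge + n_long, n_edge, n_long, max_len), call. = FALSE)
  res <- out[kept, , drop = FALSE]
  attr(res, "kept") <- which(kept)
  attr(res, "skipped") <- c(edge = n_edge, too_long = n_long)
  attr(res, "dur_stats") <- dur_stats
  res
}

#' @rdname event_tensors
#' @param durations event durations in seconds.
#' @export
duration_feature_stats <- function(durations) {
  stopifnot(all(durations > 0))
  lg <- log10(durations)
  s <- sd(lg)
  if (!is.finite(s) || s <= 0) s <- 1  # degenerate single-duration set
  list(mean = mean(lg), sd = s)
}
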