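#' Ionic-current trace objects
#'
#' A `current_trace` holds a sampled ionic-current recording (in pA) together
#' with its acquisition metadata. It is the input of the whole event-detection
#' pipeline and the output of [simulate_trace()].
#'
#' @param samples numeric vector of current samples, in pA.
#' @param sampling_rate sampling rate in Hz.
#' @param voltage applied bias in mV (metadata only).
#' @param metadata named list of free-form metadata (analyte, concentration
#'   in uM, acquisition filter in Hz, trace id, ...).
#'
#' @return An object of class `current_trace`: a list with elements
#'   `samples`, `sampling_rate`, `voltage` and `metadata`.
#' @examples
#' tr <- current_trace(rnorm(5000, 1000, 10), sampling_rate = 5e5)
#' print(tr)
#' @export
current_trace <- function(samples, sampling_rate, voltage = NA_real_,
                          metadata = list()) {
  stop_if_not_scalar_pos(sampling_rate, "sampling_rate")
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("`samples` must be finite", call. = FALSE)
  structure(list(samples = samples,
                 sampling_rate = as.numeric(sampling_rate),
                 voltage = as.numeric(voltage),
                 metadata = metadata),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  dur <- length(x$samples) / x$sampling_rate
  cat(sprintf("<current_trace> %d samples @ %g kHz (%.4g s)\n",
              length(x$samples), x$sampling_rate / 1e3, dur))
  if (!is.na(x$voltage)) cat(sprintf("  voltage: %g mV\n", x$voltage))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata),
                             vapply(x$metadata, format, ""),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.current_trace <- function(x) length(x$samples)

#' Read and write current traces as plain CSV
#'
#' The on-disk dialect is a two-column CSV (`time_s,current_pA`) preceded by
#' `#key=value` header lines carrying the metadata. `sampling_rate_hz` is
#' required; unknown keys are preserved in `metadata`. Samples round-trip
#' bit-identically (written with 17 significant digits).
#'
#' @param path file path.
#' @param trace a [current_trace()].
#' @return `read_trace()` returns a [current_trace()]; `write_trace()`
#'   returns `path` invisibly.
#' @examples
#' tr <- current_trace(rnorm(100, 1000, 10), 5e5, voltage = 120)
#' f <- tempfile(fileext = ".csv")
#' write_trace(tr, f)
#' tr2 <- read_trace(f)
#' stopifnot(identical(tr$samples, tr2$samples))
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "r"); on.exit(close(con))
  meta <- list()
  n_head <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("file ", path, " has no data rows", call. = FALSE)
    if (!startsWith(line, "#")) break
    n_head <- n_head + 1L
    kv <- sub("^#", "", line)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- substr(kv, 1L, eq - 1L)
      val <- substr(kv, eq + 1L, nchar(kv))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (is.na(num)) val else num
    }
  }
  if (is.null(meta$sampling_rate_hz))
    stop(sprintf("file %s: required header field `sampling_rate_hz` missing",
                 path), call. = FALSE)
  dat <- read.csv(path, skip = n_head, header = TRUE)
  if (!("current_pA" %in% names(dat)))
    stop(sprintf("file %s: malformed header, `current_pA` column missing",
                 path), call. = FALSE)
  sr <- meta$sampling_rate_hz
  volt <- meta$voltage_mv %||% NA_real_
  keep <- meta[setdiff(names(meta), c("sampling_rate_hz", "voltage_mv"))]
  current_trace(dat$current_pA, sampling_rate = sr, voltage = volt,
                metadata = keep)
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("#sampling_rate_hz=%.17g", trace$sampling_rate), con)
  if (!is.na(trace$voltage))
    writeLines(sprintf("#voltage_mv=%.17g", trace$voltage), con)
  for (key in names(trace$metadata)) {
    val <- trace$metadata[[key]]
    val <- if (is.numeric(val)) sprintf("%.17g", val) else as.character(val)
    writeLines(paste0("#", key, "=", val), con)
  }
  writeLines("time_s,current_pA", con)
  tt <- (seq_along(trace$samples) - 1) / trace$sampling_rate
  writeLines(sprintf("%.9g,%.17g", tt, trace$samples), con)
  invisible(path)
}

#' Read and write translocation event tables
#'
#' Event tables are TSV files with one row per detected event
#' (`trace_id, event_id, start, end, duration_s, deltaI_pA, rel_blockade`).
#'
#' @param events a `translocation_events` data frame from [detect_events()].
#' @param path file path.
#' @return `read_events()` returns the event data frame; `write_events()`
#'   returns `path` invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path)
  class(ev) <- c("translocation_events", "data.frame")
  ev
}
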