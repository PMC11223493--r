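# Fixtures built in code: constructed traces, brute-force oracles and
# directly synthesized event-tensor sets (fast alternatives to full trace
# simulation for classifier tests).

# Baseline trace with rectangular dips at given (start, len, level) rows.
make_square_trace <- function(n, baseline = 1000, dips = NULL,
                              noise_sd = 0, sampling_rate = 8e4,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- rep(baseline, n)
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  if (!is.null(dips)) {
    for (i in seq_len(nrow(dips))) {
      idx <- dips$start[i]:(dips$start[i] + dips$len[i] - 1L)
      x[idx] <- dips$level[i] + if (noise_sd > 0) rnorm(length(idx), 0, noise_sd) else 0
    }
  }
  current_trace(x, sampling_rate)
}

# Independent oracle: naive per-sample threshold scan.
brute_force_detect <- function(x, thr, min_len = 2L) {
  runs <- list()
  in_run <- FALSE
  start <- 0L
  for (i in seq_along(x)) {
    if (x[i] < thr && !in_run) { in_run <- TRUE; start <- i }
    if (x[i] >= thr && in_run) {
      in_run <- FALSE
      if (i - start >= min_len) runs[[length(runs) + 1L]] <- c(start, i - 1L)
    }
  }
  if (in_run && length(x) - start + 1L >= min_len)
    runs[[length(runs) + 1L]] <- c(start, length(x))
  if (!length(runs)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, runs)
  data.frame(start = m[, 1] - 1L, end = m[, 2])   # 0-based half-open
}

# Directly synthesized 251-point event tensors for two or three classes
# whose separability is controlled: class-specific "event" length (duration
# feature and padding extent) and optional in-event oscillation amplitude.
make_tensor_set <- function(n_per_class, spec, seed = 1) {
  # spec: list of lists with ev_len (samples), wiggle (amplitude of
  # alternating in-event fluctuation), jitter (sd of ev_len in samples)
  set.seed(seed)
  flank <- 47L; width <- 250L
  xs <- list(); labs <- character(0)
  all_len <- list()
  for (cl in names(spec)) {
    sp <- spec[[cl]]
    lens <- pmax(4L, round(rnorm(n_per_class, sp$ev_len, sp$jitter %||% 0)))
    lens <- pmin(lens, width - 2L * flank)
    all_len[[cl]] <- lens
  }
  dur_all <- log10(unlist(all_len) / 8e4)
  dmu <- mean(dur_all); dsd <- max(sd(dur_all), 1e-6)
  for (cl in names(spec)) {
    sp <- spec[[cl]]
    rows <- matrix(0, n_per_class, width + 1L)
    for (i in seq_len(n_per_class)) {
      len <- all_len[[cl]][i]
      seg <- c(rnorm(flank, 0, 0.05),
               rnorm(len, -1, 0.05) +
                 (sp$wiggle %||% 0) * rep_len(c(1, -1), len),
               rnorm(flank, 0, 0.05))
      seg <- seg - mean(seg[c(1:flank, flank + len + 1:flank)])
      seg <- seg / sd(seg)
      rows[i, seq_along(seg)] <- seg
      rows[i, width + 1L] <- (log10(len / 8e4) - dmu) / dsd
    }
    xs[[cl]] <- rows
    labs <- c(labs, rep(cl, n_per_class))
  }
  list(x = do.call(rbind, xs), labels = labs,
       dur_stats = list(mean = dmu, sd = dsd))
}

# Monodisperse simulated trace batch for one class; returns pooled events
# and the decimated traces (used by the heavier end-to-end tests).
sim_class_batch <- function(class_name, cf, conc, dwell_mean, dwell_sd,
                            n_traces, duration, seed0,
                            blockade_mean = 400, blockade_sd = 30,
                            intra_sd = 0, osc_amp = 0) {
  out <- list()
  for (i in seq_len(n_traces)) {
    cls <- list(list(concentration = conc, cf = cf, dwell_mean = dwell_mean,
                     dwell_sd = dwell_sd, blockade_mean = blockade_mean,
                     blockade_sd = blockade_sd, intra_sd = intra_sd,
                     osc_amp = osc_amp))
    names(cls) <- class_name
    cfg <- simulation_config(classes = cls, duration = duration,
                             seed = seed0 + i)
    sim <- simulate_trace(cfg)
    ex <- extract_events(sim$trace)
    id <- paste0(class_name, "_", i)
    ex$events$trace_id <- id
    out[[id]] <- list(trace = ex$trace, events = ex$events,
                      n_true = nrow(sim$annotations))
  }
  out
}
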