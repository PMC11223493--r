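#' Configuration for the synthetic nanopore trace simulator
#'
#' Describes everything needed to generate a synthetic resistive-pulse
#' recording with known ground truth: acquisition constants, baseline noise
#' and, per cOA class, the event-rate constant (events per second per uM of
#' analyte), the dwell-time distribution (log-normal, parameterized by its
#' arithmetic mean and SD) and the blockade-depth distribution (normal).
#'
#' Defaults follow the study conditions of the alpha-hemolysin cOA assay:
#' 500 kHz sampling, 100 kHz acquisition low-pass, open-pore current 1000 pA
#' and rate constants 0.17, 0.62, 0.12 events/s/uM for cA3/4, cA5 and cA6.
#' The cA6 dwell (315 +/- 26 us) and blockade (400 +/- 30 pA) statistics are
#' the measured calibration values; dwell defaults for the other classes are
#' chosen to reproduce the qualitative duration ordering (cA3/4 < cA5 < cA6)
#' with adjacent-class overlap whose misclassifications run mainly toward
#' *lower* stoichiometries (short-duration tails), and are configuration,
#' not measurement. Classes also differ mildly in within-event fluctuation
#' amplitude (`intra_sd`), emulating the shape/fluctuation differences that
#' let a convolutional classifier outperform duration-and-blockade features
#' alone.
#'
#' @param classes named list of per-class parameter lists, each with
#'   `concentration` (uM), `cf` (events/s/uM), `dwell_mean`, `dwell_sd`
#'   (seconds), `blockade_mean`, `blockade_sd` (pA) and optionally
#'   `intra_sd` (pA of extra white in-event current noise, default 0),
#'   `osc_amp` / `osc_freq` (amplitude in pA and frequency in Hz of a
#'   mean-free in-event current oscillation, defaults 0 and 20 kHz; models
#'   bound-state current wander below the acquisition bandwidth).
#' @param sampling_rate sampling rate in Hz.
#' @param duration trace duration in seconds.
#' @param open_pore_current open-pore current in pA.
#' @param baseline_noise_sd Gaussian baseline noise SD in pA (pre-filter).
#' @param voltage applied bias in mV (metadata only).
#' @param filter_cutoff acquisition low-pass cutoff in Hz (`NA` disables
#'   filtering).
#' @param seed integer seed; identical seeds give bit-identical traces.
#' @return A `simulation_config` list.
#' @examples
#' cfg <- simulation_config(duration = 1, seed = 1)
#' names(cfg$classes)
#' @export
simulation_config <- function(classes = default_classes(),
                              sampling_rate = 5e5,
                              duration = 10,
                              open_pore_current = 1000,
                              baseline_noise_sd = 15,
                              voltage = 120,
                              filter_cutoff = 1e5,
                              seed = NULL) {
  stop_if_not_scalar_pos(sampling_rate, "sampling_rate")
  stop_if_not_scalar_pos(duration, "duration")
  stop_if_not_scalar_pos(open_pore_current, "open_pore_current")
  if (baseline_noise_sd < 0) stop("`baseline_noise_sd` must be >= 0")
  if (!length(classes) || is.null(names(classes)) || any(names(classes) == ""))
    stop("`classes` must be a named list", call. = FALSE)
  for (nm in names(classes)) {
    cl <- classes[[nm]]
    need <- c("concentration", "cf", "dwell_mean", "dwell_sd",
              "blockade_mean", "blockade_sd")
    if (!all(need %in% names(cl)))
      stop("class `", nm, "` missing fields: ",
           paste(setdiff(need, names(cl)), collapse = ", "), call. = FALSE)
    if (cl$concentration < 0) stop("concentrations must be >= 0")
    if (cl$cf <= 0) stop("correction factors must be > 0")
    if (cl$dwell_mean <= 0) stop("dwell means must be > 0")
    if (cl$blockade_mean >= open_pore_current)
      stop("blockade mean must be below the open-pore current")
    classes[[nm]]$intra_sd <- cl$intra_sd %||% 0
  }
  structure(list(classes = classes, sampling_rate = sampling_rate,
                 duration = duration, open_pore_current = open_pore_current,
                 baseline_noise_sd = baseline_noise_sd, voltage = voltage,
                 filter_cutoff = filter_cutoff, seed = seed),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @param concentrations per-class analyte concentrations in uM, recycled
#'   over the three default classes (cA3/4, cA5, cA6).
#' @export
default_classes <- function(concentrations = c(10, 10, 10)) {
  concentrations <- rep_len(concentrations, 3L)
  list(
    cA34 = list(concentration = concentrations[1], cf = 0.17,
                dwell_mean = 120e-6, dwell_sd = 35e-6,
                blockade_mean = 400, blockade_sd = 30, intra_sd = 8),
    cA5  = list(concentration = concentrations[2], cf = 0.62,
                dwell_mean = 175e-6, dwell_sd = 30e-6,
                blockade_mean = 400, blockade_sd = 30, intra_sd = 4),
    cA6  = list(concentration = concentrations[3], cf = 0.12,
                dwell_mean = 315e-6, dwell_sd = 26e-6,
                blockade_mean = 400, blockade_sd = 30, intra_sd = 0)
  )
}

#' Simulate a nanopore recording with ground-truth annotations
#'
#' Event arrivals per class are Poisson with rate `cf * concentration`
#' (events per second); dwell times are log-normal and blockade depths
#' normal with the configured per-class moments. Events are ideal square
#' pulses subtracted from the Gaussian open-pore baseline; the whole trace
#' is then shaped by the acquisition low-pass (4-pole Bessel, zero phase),
#' so short events show bandwidth-attenuated depths as in real recordings.
#' Overlapping arrivals are resolved by rejection-resampling of start times;
#' the simulator refuses configurations with more than 50% expected pore
#' occupancy.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `trace` (a [current_trace()]) and
#'   `annotations`, a data frame with one row per injected event:
#'   `event_id`, `class`, `start`, `end` (0-based, half-open, at the
#'   simulation sampling rate), `duration_s`, `depth_pA`.
#' @examples
#' cfg <- simulation_config(duration = 0.5,
#'                          classes = default_classes(c(0, 0, 50)),
#'                          seed = 42)
#' sim <- simulate_trace(cfg)
#' nrow(sim$annotations)
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    fs <- config$sampling_rate
    n <- round(config$duration * fs)
    rates <- vapply(config$classes, function(cl) cl$cf * cl$concentration, 0)
    # draw per-class event sets
    cls <- character(0); dur <- numeric(0); depth <- numeric(0)
    intra <- numeric(0)
    for (nm in names(config$classes)) {
      cl <- config$classes[[nm]]
      k <- rpois(1L, rates[[nm]] * config$duration)
      if (k == 0L) next
      lp <- lognormal_params(cl$dwell_mean, cl$dwell_sd)
      cls <- c(cls, rep(nm, k))
      dur <- c(dur, rlnorm(k, lp$meanlog, lp$sdlog))
      depth <- c(depth, rnorm(k, cl$blockade_mean, cl$blockade_sd))
      intra <- c(intra, rep(cl$intra_sd, k))
    }
    len <- pmax(1L, as.integer(round(dur * fs)))
    if (sum(len) > 0.5 * n)
      stop("configured rates imply >50% pore occupancy; ",
           "rejection placement is infeasible", call. = FALSE)
    starts <- place_events(len, n)
    ord <- order(starts)
    cls <- cls[ord]; dur <- dur[ord]; depth <- depth[ord]
    len <- len[ord]; starts <- starts[ord]; intra <- intra[ord]

    osc_amp <- vapply(config$classes, function(cl) cl$osc_amp %||% 0, 0)
    osc_freq <- vapply(config$classes, function(cl) cl$osc_freq %||% 2e4, 0)
    x <- rnorm(n, config$open_pore_current, config$baseline_noise_sd)
    for (i in seq_along(starts)) {
      idx <- starts[i]:(starts[i] + len[i] - 1L)
      x[idx] <- x[idx] - depth[i]
      if (intra[i] > 0) x[idx] <- x[idx] + rnorm(len[i], 0, intra[i])
      amp <- osc_amp[[cls[i]]]
      if (amp > 0) {
        # mean-free in-event oscillation (e.g. bound-state current wander);
        # frequency below the acquisition cutoff so it survives filtering
        phase <- runif(1, 0, 2 * pi)
        x[idx] <- x[idx] +
          amp * sin(2 * pi * osc_freq[[cls[i]]] * seq_along(idx) / fs + phase)
      }
    }
    meta <- list(analyte = paste(names(config$classes), collapse = "+"),
                 concentration_um = sum(vapply(config$classes,
                                               `[[`, 0, "concentration")))
    tr <- current_trace(x, fs, config$voltage, meta)
    if (is.finite(config$filter_cutoff) && config$filter_cutoff > 0 &&
        config$filter_cutoff < fs / 2)
      tr <- lowpass_filter(tr, config$filter_cutoff)
    ann <- data.frame(event_id = seq_along(starts),
                      class = cls,
                      start = starts - 1L,      # 0-based, half-open
                      end = starts - 1L + len,
                      duration_s = dur,
                      depth_pA = depth)
    list(trace = tr, annotations = ann)
  })
}

# Draw non-overlapping start positions (1-based) for events of length `len`
# in a trace of `n` samples, by rejection-resampling colliding events.
place_events <- function(len, n) {
  k <- length(len)
  if (!k) return(integer(0))
  if (any(len >= n)) stop("event longer than trace", call. = FALSE)
  starts <- as.integer(floor(runif(k, 1, n - len + 1)))
  for (iter in seq_len(1000L)) {
    ord <- order(starts)
    s <- starts[ord]; l <- len[ord]
    # overlap (with a 1-sample guard) between consecutive events
    clash <- which(s[-1] <= s[-k] + l[-k])
    if (!length(clash)) return(starts)
    bad <- unique(ord[c(clash, clash + 1L)])
    starts[bad] <- as.integer(floor(runif(length(bad), 1, n - len[bad] + 1)))
  }
  stop("could not place events without overlap after 1000 rounds; ",
       "reduce rates or durations", call. = FALSE)
}

#' Simulate LC-MS extracted-ion-chromatogram peak areas
#'
#' Generates the peak-area table the LC-MS estimators consume: each species'
#' area is `response_factor * concentration`, perturbed by multiplicative
#' Gaussian noise. Negative simulated areas are clipped to zero with a
#' warning.
#'
#' @param concentrations named vector of species concentrations in uM.
#' @param response_factors area units per uM, recycled over species.
#' @param noise_rel_sd relative SD of the multiplicative noise (default 0).
#' @param seed integer seed.
#' @return A data frame with columns `species`, `concentration_uM`, `area`.
#' @examples
#' simulate_eic_peaks(c(cA3 = 50, cA4 = 50), response_factors = 1000)
#' @export
simulate_eic_peaks <- function(concentrations, response_factors,
                               noise_rel_sd = 0, seed = NULL) {
  if (any(concentrations < 0) || any(response_factors < 0))
    stop("concentrations and response factors must be >= 0", call. = FALSE)
  if (noise_rel_sd < 0) stop("`noise_rel_sd` must be >= 0", call. = FALSE)
  rf <- rep_len(response_factors, length(concentrations))
  with_seed(seed, {
    noise <- if (noise_rel_sd > 0)
      rnorm(length(concentrations), 0, noise_rel_sd) else 0
    area <- rf * concentrations * (1 + noise)
    if (any(area < 0)) {
      warning("negative simulated peak area(s) clipped to 0", call. = FALSE)
      area <- pmax(area, 0)
    }
    data.frame(species = names(concentrations) %||%
                 paste0("sp", seq_along(concentrations)),
               concentration_uM = as.numeric(concentrations),
               area = area)
  })
}
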