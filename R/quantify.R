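#' Estimate event-rate correction factors from monodisperse traces
#'
#' The cOA classes translocate at different rates per unit concentration, so
#' raw event counts must be converted to abundances with class-specific
#' correction factors CF (events per second per uM). CF for a class is
#' estimated by pooling its calibration traces: total event count divided by
#' the summed concentration x recording-time product. The uncertainty is the
#' SD over per-trace estimates (for a single trace, the Poisson sqrt(N)
#' propagation).
#'
#' @param trace_summaries data frame with one row per calibration trace:
#'   columns `class`, `n_events`, `duration_s`, `concentration_uM`.
#' @return A data frame of class `correction_factors` with columns `class`,
#'   `cf`, `cf_sd`, `n_traces`, `n_events`.
#' @examples
#' estimate_correction_factors(data.frame(
#'   class = "cA6", n_events = 100, duration_s = 100, concentration_uM = 1))
#' @export
estimate_correction_factors <- function(trace_summaries) {
  need <- c("class", "n_events", "duration_s", "concentration_uM")
  if (!all(need %in% names(trace_summaries)))
    stop("`trace_summaries` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(trace_summaries$duration_s <= 0) ||
      any(trace_summaries$concentration_uM <= 0))
    stop("zero or negative concentration/recording time", call. = FALSE)
  out <- lapply(split(trace_summaries, trace_summaries$class), function(g) {
    expo <- g$concentration_uM * g$duration_s        # uM * s exposure
    cf <- sum(g$n_events) / sum(expo)
    per_trace <- g$n_events / expo
    cf_sd <- if (nrow(g) > 1L) sd(per_trace)
             else sqrt(sum(g$n_events)) / sum(expo)  # Poisson single-trace
    data.frame(class = g$class[1L], cf = cf, cf_sd = cf_sd,
               n_traces = nrow(g), n_events = sum(g$n_events))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("correction_factors", "data.frame")
  out
}

#' Mixture composition from classified event counts
#'
#' Converts per-class event counts into abundance fractions by compensating
#' for the class-specific event rates: abundance of class x is proportional
#' to `count_x / (time * CF_x)`; fractions are normalized to sum to 1. The
#' total event rate `r_e` (all classes, events per second) is reported
#' alongside, as it enters the absolute yield computation.
#'
#' @param counts named vector of classified event counts per class.
#' @param time_s total recording time in seconds.
#' @param cfs correction factors: a `correction_factors` data frame or a
#'   named numeric vector (events/s/uM), covering all classes in `counts`.
#' @return A list of class `composition_estimate` with `fractions` (named,
#'   sums to 1), `abundance_uM` (flow-cell scale), `r_e`, `counts`,
#'   `time_s`.
#' @examples
#' estimate_composition(c(cA34 = 17, cA5 = 62, cA6 = 12), time_s = 100,
#'                      cfs = c(cA34 = 0.17, cA5 = 0.62, cA6 = 0.12))
#' @export
estimate_composition <- function(counts, time_s, cfs) {
  stop_if_not_scalar_pos(time_s, "time_s")
  cfv <- as_cf_vector(cfs)
  if (sum(counts) <= 0) stop("zero total events", call. = FALSE)
  missing_cf <- setdiff(names(counts), names(cfv))
  if (length(missing_cf))
    stop("no correction factor for class: ",
         paste(missing_cf, collapse = ", "), call. = FALSE)
  cfv <- cfv[names(counts)]
  abundance <- counts / (time_s * cfv)               # uM at the flow cell
  structure(list(fractions = abundance / sum(abundance),
                 abundance_uM = abundance,
                 r_e = sum(counts) / time_s,
                 counts = counts, time_s = time_s),
            class = "composition_estimate")
}

as_cf_vector <- function(cfs) {
  if (inherits(cfs, "data.frame")) setNames(cfs$cf, cfs$class)
  else if (is.numeric(cfs) && !is.null(names(cfs))) cfs
  else stop("`cfs` must be a correction_factors table or named vector",
            call. = FALSE)
}

#' @export
print.composition_estimate <- function(x, ...) {
  cat("<composition_estimate>\n")
  cat(sprintf("  total event rate r_e = %.4g /s over %.4g s\n",
              x$r_e, x$time_s))
  for (nm in names(x$fractions))
    cat(sprintf("  %-6s %5.1f%%  (%d events)\n", nm,
                100 * x$fractions[[nm]], x$counts[[nm]]))
  invisible(x)
}

#' 95% prediction intervals over cross-validation fold estimates
#'
#' Summarizes the spread of composition estimates obtained by repeating
#' inference with each of the k cross-validation classifiers: interval =
#' mean +/- t(0.975, k-1) x SD over fold estimates, per class. This
#' expresses the uncertainty introduced by training-data variability.
#'
#' @param fold_fractions numeric matrix, one row per fold, one (named)
#'   column per class; at least 3 folds.
#' @param level interval coverage (default 0.95).
#' @return A data frame with columns `class`, `mean`, `sd`, `lower`,
#'   `upper`.
#' @export
prediction_interval <- function(fold_fractions, level = 0.95) {
  fold_fractions <- as.matrix(fold_fractions)
  k <- nrow(fold_fractions)
  if (k < 3) stop("need at least 3 fold estimates", call. = FALSE)
  m <- colMeans(fold_fractions)
  s <- apply(fold_fractions, 2L, sd)
  tq <- qt(1 - (1 - level) / 2, df = k - 1L)
  data.frame(class = colnames(fold_fractions) %||%
               paste0("class", seq_along(m)),
             mean = m, sd = s, lower = m - tq * s, upper = m + tq * s,
             row.names = NULL)
}

#' Absolute enzymatic cOA yield per CRISPR complex
#'
#' Converts an observed nanopore event rate and inferred class fractions
#' into absolute numbers of cOA molecules produced per type III complex:
#' the flow-cell concentration of class x is `r_e * fraction_x / CF_x`
#' (uM), multiplied by the dilution factor `d` to recover the reaction-mix
#' concentration, and divided by the complex concentration to yield
#' molecules per complex (the Avogadro constant cancels in this ratio).
#' Uncertainties are propagated to first order assuming independent
#' Gaussian input errors.
#'
#' @param r_e total event rate in events per second.
#' @param fractions named per-class abundance fractions (sum to 1).
#' @param cfs correction factors (named vector or `correction_factors`
#'   table, events/s/uM).
#' @param d dilution factor between reaction mix and flow cell.
#' @param complex_conc_uM complex concentration during synthesis, in uM.
#' @param r_e_sd,fractions_sd,cf_sd,d_sd,complex_sd optional 1-sigma
#'   uncertainties (0 = exact); `fractions_sd` and `cf_sd` are named like
#'   their values. If `cfs` is a `correction_factors` table its `cf_sd`
#'   column is used unless overridden.
#' @return A list of class `absolute_yield` with `per_class` (data frame:
#'   class, flowcell_uM, reaction_uM, molecules_per_complex, sd), `total`,
#'   `total_sd`, and the echoed inputs.
#' @examples
#' absolute_yield(r_e = 0.47, fractions = c(cA34 = .89, cA5 = .08, cA6 = .03),
#'                cfs = c(cA34 = 0.17, cA5 = 0.62, cA6 = 0.12),
#'                d = 21, complex_conc_uM = 0.0625)
#' @export
absolute_yield <- function(r_e, fractions, cfs, d, complex_conc_uM,
                           r_e_sd = 0, fractions_sd = NULL, cf_sd = NULL,
                           d_sd = 0, complex_sd = 0) {
  stop_if_not_scalar_pos(r_e, "r_e")
  stop_if_not_scalar_pos(d, "d")
  stop_if_not_scalar_pos(complex_conc_uM, "complex_conc_uM")
  if (any(fractions < 0)) stop("fractions must be >= 0", call. = FALSE)
  if (sum(fractions) > 1 + 1e-6)
    stop("fractions sum above 1", call. = FALSE)
  cfv <- as_cf_vector(cfs)
  missing_cf <- setdiff(names(fractions), names(cfv))
  if (length(missing_cf))
    stop("no correction factor for class: ",
         paste(missing_cf, collapse = ", "), call. = FALSE)
  cfv <- cfv[names(fractions)]
  if (is.null(cf_sd)) {
    cf_sd <- if (inherits(cfs, "data.frame"))
      setNames(cfs$cf_sd, cfs$class)[names(fractions)]
    else setNames(rep(0, length(fractions)), names(fractions))
  } else cf_sd <- rep_len(cf_sd, length(fractions))
  if (is.null(fractions_sd)) fractions_sd <- rep(0, length(fractions))
  fractions_sd <- rep_len(fractions_sd, length(fractions))

  flowcell <- r_e * fractions / cfv          # uM
  reaction <- flowcell * d                   # uM
  per_complex <- reaction / complex_conc_uM  # molecules per complex
  total <- sum(per_complex)

  # first-order propagation; r_e, d and complex_conc are shared across
  # classes, so their contributions act on the total, not per class in
  # quadrature
  a <- d / (complex_conc_uM * cfv)           # per_complex = a * r_e * f
  dd_f <- a * r_e                            # d total / d fraction_x
  dd_cf <- -per_complex / cfv                # d total / d CF_x
  var_total <- (total / r_e)^2 * r_e_sd^2 +
    (total / d)^2 * d_sd^2 +
    (total / complex_conc_uM)^2 * complex_sd^2 +
    sum(dd_f^2 * fractions_sd^2) +
    sum(dd_cf^2 * cf_sd^2)
  var_class <- (per_complex / r_e)^2 * r_e_sd^2 +
    (per_complex / d)^2 * d_sd^2 +
    (per_complex / complex_conc_uM)^2 * complex_sd^2 +
    dd_f^2 * fractions_sd^2 + dd_cf^2 * cf_sd^2

  structure(list(
    per_class = data.frame(class = names(fractions),
                           flowcell_uM = unname(flowcell),
                           reaction_uM = unname(reaction),
                           molecules_per_complex = unname(per_complex),
                           sd = unname(sqrt(var_class)), row.names = NULL),
    total = total, total_sd = sqrt(var_total),
    inputs = list(r_e = r_e, fractions = fractions, cfs = cfv, d = d,
                  complex_conc_uM = complex_conc_uM)),
    class = "absolute_yield")
}

#' @export
print.absolute_yield <- function(x, ...) {
  cat("<absolute_yield>\n")
  print(x$per_class, digits = 3)
  cat(sprintf("  total: %.0f +/- %.0f molecules per complex\n",
              x$total, x$total_sd))
  invisible(x)
}

#' LC-MS concentration and ratio estimators from EIC peak areas
#'
#' `lcms_concentrations()` estimates each species' concentration in a
#' mixture from extracted-ion-chromatogram peak areas, using the
#' monodisperse calibration solutions as single-point references:
#' `conc_x = (area_mix_x / area_mono_x) * calib_conc`.
#' `lcms_ratios()` converts concentrations into percentages of the total.
#' Uncertainties are propagated to first order from the supplied area SDs.
#'
#' @param area_mono named vector of monodisperse calibration peak areas
#'   (> 0).
#' @param area_mix named vector of mixture peak areas, same species.
#' @param calib_conc concentration of the monodisperse calibration
#'   solutions in uM (default 50).
#' @param area_mono_sd,area_mix_sd optional area SDs (default 0).
#' @return `lcms_concentrations()`: data frame with `species`,
#'   `concentration_uM`, `sd`. `lcms_ratios()`: data frame with `species`,
#'   `ratio_pct`, `sd` (percentages sum to 100).
#' @examples
#' mono <- c(cA3 = 4e5, cA4 = 5e5, cA5 = 3e5, cA6 = 2e5)
#' conc <- lcms_concentrations(mono, mono / 4)
#' lcms_ratios(conc)
#' @export
lcms_concentrations <- function(area_mono, area_mix, calib_conc = 50,
                                area_mono_sd = 0, area_mix_sd = 0) {
  if (any(area_mono <= 0))
    stop("zero monodisperse peak area for species: ",
         paste(names(area_mono)[area_mono <= 0], collapse = ", "),
         call. = FALSE)
  sp <- names(area_mono)
  if (!identical(sort(sp), sort(names(area_mix))))
    stop("`area_mono` and `area_mix` must cover the same species",
         call. = FALSE)
  area_mix <- area_mix[sp]
  area_mono_sd <- rep_len(area_mono_sd, length(sp))
  area_mix_sd <- rep_len(area_mix_sd, length(sp))
  conc <- (area_mix / area_mono) * calib_conc
  rel_var <- ifelse(area_mix > 0, (area_mix_sd / area_mix)^2, 0) +
    (area_mono_sd / area_mono)^2
  data.frame(species = sp, concentration_uM = unname(conc),
             sd = unname(conc * sqrt(rel_var)), row.names = NULL)
}

#' @rdname lcms_concentrations
#' @param concentrations data frame from `lcms_concentrations()` or a named
#'   vector of concentrations in uM.
#' @export
lcms_ratios <- function(concentrations) {
  if (inherits(concentrations, "data.frame")) {
    conc <- setNames(concentrations$concentration_uM, concentrations$species)
    csd <- setNames(concentrations$sd %||% rep(0, nrow(concentrations)),
                    concentrations$species)
  } else {
    conc <- concentrations
    csd <- setNames(rep(0, length(conc)), names(conc))
  }
  tot <- sum(conc)
  if (tot <= 0) stop("total concentration is zero", call. = FALSE)
  ratio <- 100 * conc / tot
  # d ratio_x / d conc_j = 100 * (delta_xj * tot - conc_x) / tot^2
  var_r <- vapply(seq_along(conc), function(x) {
    grad <- -100 * conc[[x]] / tot^2 + 100 / tot * (seq_along(conc) == x)
    sum(grad^2 * csd^2)
  }, 0)
  data.frame(species = names(conc), ratio_pct = unname(ratio),
             sd = unname(sqrt(var_r)), row.names = NULL)
}
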