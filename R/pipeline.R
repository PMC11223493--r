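#' Pipeline run configuration
#'
#' Bundles every parameter of the simulate -> detect -> train -> classify ->
#' quantify workflow with the acquisition-style defaults (500 kHz
#' simulation, 80 kHz digital low-pass and decimation, 65% threshold,
#' 47-point flanks / 250-point padding, 100 epochs / 5 restarts / Adam at
#' 0.001). Every override is recorded in the run manifest.
#'
#' @param out_dir output directory for all run artifacts.
#' @param traces list of trace specifications; each a list with `id`,
#'   `role` (`"train"` or `"sample"`), `label` (training class, for
#'   role = "train"), `concentrations` (named uM vector over the classes),
#'   and optionally `duration` (s).
#' @param classes per-class simulator parameters (see [default_classes()]).
#' @param seed integer master seed; per-trace seeds are derived from it.
#' @param duration default trace duration in s.
#' @param filter_cutoff,target_rate,threshold_frac,min_event_samples event
#'   extraction parameters (see [extract_events()]).
#' @param flank,width event tensor geometry (see [event_tensors()]).
#' @param epochs,restarts,learning_rate,batch_size training hyperparameters
#'   (see [train_classifier()]).
#' @param cfs correction factors for quantification; `NULL` to estimate
#'   them from the training traces.
#' @param d,complex_conc_uM absolute-yield inputs (dilution factor and
#'   complex concentration); `d = NULL` skips the yield report.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, traces = list(), classes = default_classes(),
                       seed = 1L, duration = 10,
                       filter_cutoff = 8e4, target_rate = 8e4,
                       threshold_frac = 0.65, min_event_samples = 2L,
                       flank = 47L, width = 250L,
                       epochs = 100L, restarts = 5L, learning_rate = 1e-3,
                       batch_size = 32L, cfs = NULL, d = NULL,
                       complex_conc_uM = 0.0625) {
  stopifnot(is.character(out_dir), length(out_dir) == 1L)
  for (sp in traces) {
    if (is.null(sp$id) || is.null(sp$role) || is.null(sp$concentrations))
      stop("each trace spec needs `id`, `role` and `concentrations`",
           call. = FALSE)
    if (sp$role == "train" && is.null(sp$label))
      stop("training trace `", sp$id, "` needs a `label`", call. = FALSE)
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the cOA identification pipeline
#'
#' Executes the requested stages in order, writing versioned plain-text
#' artifacts plus a JSON manifest (configuration, seed, file checksums)
#' under `config$out_dir`. Re-running with an identical configuration and
#' seed reproduces identical artifacts for the deterministic stages.
#'
#' Stages: `"simulate"` (synthetic traces + ground-truth annotations),
#' `"detect"` (filter, decimate, threshold detection; event tables),
#' `"train"` (CNN on the training traces), `"classify"` (per-event
#' predictions for sample traces), `"quantify"` (composition report and,
#' if `config$d` is set, the absolute yield report).
#'
#' @param config a [run_config()].
#' @param stages subset of the stage names, in pipeline order.
#' @return Invisibly, a list of the stage outputs produced in this call.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "detect", "train",
                                    "classify", "quantify")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  if ("simulate" %in% stages) res$simulate <- stage_simulate(config)
  if ("detect" %in% stages) res$detect <- stage_detect(config)
  if ("train" %in% stages) res$train <- stage_train(config)
  if ("classify" %in% stages) res$classify <- stage_classify(config)
  if ("quantify" %in% stages) res$quantify <- stage_quantify(config)

  write_manifest(config, stages)
  invisible(res)
}

stage_simulate <- function(config) {
  tdir <- file.path(config$out_dir, "traces")
  dir.create(tdir, showWarnings = FALSE)
  files <- character(0)
  for (i in seq_along(config$traces)) {
    sp <- config$traces[[i]]
    cls <- config$classes
    for (nm in names(cls)) cls[[nm]]$concentration <- 0
    for (nm in names(sp$concentrations))
      cls[[nm]]$concentration <- sp$concentrations[[nm]]
    cfg <- simulation_config(classes = cls,
                             duration = sp$duration %||% config$duration,
                             seed = config$seed + i)
    sim <- simulate_trace(cfg)
    sim$trace$metadata$trace_id <- sp$id
    sim$trace$metadata$role <- sp$role
    if (!is.null(sp$label)) sim$trace$metadata$label <- sp$label
    f <- file.path(tdir, paste0(sp$id, ".csv"))
    write_trace(sim$trace, f)
    utils::write.table(sim$annotations,
                       file.path(tdir, paste0(sp$id, "_truth.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  files
}

stage_detect <- function(config) {
  tdir <- file.path(config$out_dir, "traces")
  if (!dir.exists(tdir) || !length(list.files(tdir, pattern = "\\.csv$")))
    stop("no traces found under ", tdir, "; run the `simulate` stage first ",
         "(or place trace CSVs there)", call. = FALSE)
  edir <- file.path(config$out_dir, "events")
  ddir <- file.path(config$out_dir, "decimated")
  dir.create(edir, showWarnings = FALSE)
  dir.create(ddir, showWarnings = FALSE)
  all_ev <- list()
  for (f in list.files(tdir, pattern = "\\.csv$", full.names = TRUE)) {
    tr <- read_trace(f)
    ex <- extract_events(tr, config$filter_cutoff, config$target_rate,
                         threshold_frac = config$threshold_frac,
                         min_event_samples = config$min_event_samples)
    id <- tr$metadata$trace_id %||% sub("\\.csv$", "", basename(f))
    ex$events$trace_id <- id
    write_trace(ex$trace, file.path(ddir, basename(f)))
    write_events(ex$events, file.path(edir, paste0(id, ".tsv")))
    all_ev[[id]] <- ex$events
  }
  combined <- do.call(rbind, all_ev)
  write_events(combined, file.path(config$out_dir, "events.tsv"))
  combined
}

# decimated traces + per-trace events, with role/label metadata
load_detected <- function(config) {
  ddir <- file.path(config$out_dir, "decimated")
  edir <- file.path(config$out_dir, "events")
  if (!dir.exists(ddir) || !dir.exists(edir))
    stop("no detection artifacts under ", config$out_dir,
         "; run the `detect` stage first", call. = FALSE)
  out <- list()
  for (f in list.files(ddir, pattern = "\\.csv$", full.names = TRUE)) {
    tr <- read_trace(f)
    id <- tr$metadata$trace_id %||% sub("\\.csv$", "", basename(f))
    ev <- read_events(file.path(edir, paste0(id, ".tsv")))
    out[[id]] <- list(trace = tr, events = ev,
                      role = tr$metadata$role %||% "sample",
                      label = tr$metadata$label)
  }
  out
}

build_tensors <- function(config, detected, ids, dur_stats = NULL) {
  xs <- list(); labs <- character(0); tids <- character(0)
  evs <- list()
  for (id in ids) {
    dt <- detected[[id]]
    if (!nrow(dt$events)) next
    tens <- suppressWarnings(
      event_tensors(dt$trace, dt$events, config$flank, config$width,
                    dur_stats = dur_stats))
    if (!nrow(tens)) next
    xs[[id]] <- tens
    kept <- attr(tens, "kept")
    labs <- c(labs, rep(dt$label %||% NA_character_, nrow(tens)))
    tids <- c(tids, rep(id, nrow(tens)))
    evs[[id]] <- dt$events[kept, , drop = FALSE]
  }
  if (!length(xs)) stop("no usable events", call. = FALSE)
  list(x = do.call(rbind, xs), labels = labs, trace_ids = tids,
       events = do.call(rbind, evs))
}

stage_train <- function(config) {
  detected <- load_detected(config)
  train_ids <- names(detected)[vapply(detected, function(d)
    identical(d$role, "train"), TRUE)]
  if (!length(train_ids))
    stop("no training traces; run `simulate` + `detect` with role = ",
         "\"train\" traces first", call. = FALSE)
  durs <- unlist(lapply(detected[train_ids],
                        function(d) d$events$duration_s))
  dur_stats <- duration_feature_stats(durs)
  tb <- build_tensors(config, detected, train_ids, dur_stats)
  lev <- sort(unique(tb$labels))
  net <- build_classifier(length(lev), input_width = config$width + 1L,
                          class_levels = lev)
  net <- train_classifier(net, tb$x, tb$labels, epochs = config$epochs,
                          learning_rate = config$learning_rate,
                          restarts = config$restarts,
                          batch_size = config$batch_size,
                          seed = config$seed)
  net$dur_stats <- dur_stats
  saveRDS(net, file.path(config$out_dir, "model.rds"))
  utils::write.table(net$log, file.path(config$out_dir, "training_log.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  net
}

stage_classify <- function(config) {
  mfile <- file.path(config$out_dir, "model.rds")
  if (!file.exists(mfile))
    stop("no trained model at ", mfile, "; run the `train` stage first",
         call. = FALSE)
  net <- readRDS(mfile)
  detected <- load_detected(config)
  sample_ids <- names(detected)[vapply(detected, function(d)
    !identical(d$role, "train"), TRUE)]
  if (!length(sample_ids))
    stop("no sample traces to classify", call. = FALSE)
  tb <- build_tensors(config, detected, sample_ids, net$dur_stats)
  pr <- predict(net, tb$x, type = "prob")
  pred <- net$class_levels[max.col(pr, ties.method = "first")]
  out <- cbind(tb$events[, c("trace_id", "event_id", "duration_s",
                             "deltaI_pA")],
               predicted = pred, as.data.frame(pr))
  utils::write.table(out, file.path(config$out_dir, "predictions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  out
}

stage_quantify <- function(config) {
  pfile <- file.path(config$out_dir, "predictions.tsv")
  if (!file.exists(pfile))
    stop("no predictions at ", pfile, "; run the `classify` stage first",
         call. = FALSE)
  preds <- utils::read.delim(pfile)
  detected <- load_detected(config)
  sample_ids <- unique(preds$trace_id)
  time_s <- sum(vapply(detected[as.character(sample_ids)], function(d)
    length(d$trace$samples) / d$trace$sampling_rate, 0))
  cfs <- config$cfs
  if (is.null(cfs)) {
    train_ids <- names(detected)[vapply(detected, function(d)
      identical(d$role, "train"), TRUE)]
    summaries <- do.call(rbind, lapply(train_ids, function(id) {
      d <- detected[[id]]
      data.frame(class = d$label, n_events = nrow(d$events),
                 duration_s = length(d$trace$samples) / d$trace$sampling_rate,
                 concentration_uM = d$trace$metadata$concentration_um)
    }))
    cfs <- estimate_correction_factors(summaries)
  }
  lev <- sort(unique(preds$predicted))
  counts <- table(factor(preds$predicted, lev))
  comp <- estimate_composition(setNames(as.numeric(counts), lev),
                               time_s, cfs)
  comp_df <- data.frame(class = names(comp$fractions),
                        fraction = as.numeric(comp$fractions),
                        count = as.numeric(comp$counts),
                        r_e = comp$r_e, time_s = comp$time_s)
  utils::write.table(comp_df, file.path(config$out_dir, "composition.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  out <- list(composition = comp, cfs = cfs)
  if (!is.null(config$d)) {
    yld <- absolute_yield(comp$r_e, comp$fractions, cfs, config$d,
                          config$complex_conc_uM)
    utils::write.table(yld$per_class,
                       file.path(config$out_dir, "yield.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    out$yield <- yld
  }
  out
}

write_manifest <- function(config, stages) {
  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$|\\.rds$", files)]
  sums <- tools::md5sum(files)
  cfg <- config
  cfg$traces <- lapply(cfg$traces, function(sp) {
    sp$concentrations <- as.list(sp$concentrations); sp
  })
  manifest <- list(
    package = "coapore",
    version = as.character(utils::packageVersion("coapore")),
    seed = config$seed,
    stages = stages,
    config_hash = substr(paste(
      tools::md5sum(files = character(0)),
      digest_config(cfg), collapse = ""), 1, 32),
    config = cfg[setdiff(names(cfg), "classes")],
    files = as.list(setNames(unname(sums),
                             sub(paste0("^", config$out_dir, "/?"), "",
                                 names(sums)))))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(manifest)
}

digest_config <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(cfg[setdiff(names(cfg), "out_dir")]), tf)
  unname(tools::md5sum(tf))
}
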