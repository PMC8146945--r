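# End-to-end pipeline: encode -> build -> train per condition -> subtract
# each condition vs Pre -> retain top changes -> region summaries.

#' Pipeline configuration
#'
#' One block per stage, each validating its own invariants. The analysis
#' rate must divide the acquisition rate.
#'
#' @param acquisition_rate raw sampling rate (Hz).
#' @param analysis_rate analysis rate after downsampling (Hz).
#' @param encoder [encoder_params()].
#' @param swc [swc_params()].
#' @param lif [lif_params()].
#' @param stdp [stdp_params()].
#' @param grid_n_per_axis synthetic-grid resolution used when no template
#'   file is given (11 gives the 503-neuron desk grid).
#' @param retain_fraction fraction of relative changes kept (default 0.05).
#' @param relative rank retained changes by relative (default) or absolute
#'   delta.
#' @param fixture_duration seconds per condition when inputs = "fixture".
#' @param seed master seed.
#' @return `snn_pipeline_config` list.
#' @export
pipeline_config <- function(acquisition_rate = 8192, analysis_rate = 256,
                            encoder = encoder_params(optimize = TRUE),
                            swc = swc_params(), lif = lif_params(),
                            stdp = stdp_params(),
                            grid_n_per_axis = 11L,
                            retain_fraction = 0.05, relative = TRUE,
                            fixture_duration = 60, seed = 1L) {
  if (abs(acquisition_rate / analysis_rate -
          round(acquisition_rate / analysis_rate)) > 1e-9)
    stop("analysis rate must divide the acquisition rate")
  structure(list(acquisition_rate = acquisition_rate,
                 analysis_rate = analysis_rate,
                 encoder = encoder, swc = swc, lif = lif, stdp = stdp,
                 grid_n_per_axis = as.integer(grid_n_per_axis),
                 retain_fraction = retain_fraction, relative = relative,
                 fixture_duration = fixture_duration,
                 seed = as.integer(seed), schema = 1L),
            class = "snn_pipeline_config")
}

#' Serialize / parse a pipeline configuration
#'
#' @param config an `snn_pipeline_config`.
#' @param path optional file; when `NULL`, the JSON string is returned.
#' @return `config_to_json` returns JSON (or writes it);
#'   `config_from_json` returns the round-tripped config.
#' @export
config_to_json <- function(config, path = NULL) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  js <- jsonlite::toJSON(strip(config), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(path)) }
  js
}

#' @rdname config_to_json
#' @param json JSON string or file path.
#' @export
config_from_json <- function(json) {
  lst <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  pipeline_config(
    acquisition_rate = lst$acquisition_rate,
    analysis_rate = lst$analysis_rate,
    encoder = do.call(encoder_params, lst$encoder[
      names(lst$encoder) %in% names(formals(encoder_params))]),
    swc = do.call(swc_params, lst$swc),
    lif = do.call(lif_params, lst$lif),
    stdp = do.call(stdp_params, lst$stdp),
    grid_n_per_axis = lst$grid_n_per_axis,
    retain_fraction = lst$retain_fraction, relative = lst$relative,
    fixture_duration = lst$fixture_duration, seed = lst$seed)
}

#' Run the full analysis pipeline
#'
#' With `inputs = "fixture"` the study fixture is generated at the config
#' seed; otherwise `inputs` is a vector of recording paths (TSV/EDF/BDF),
#' one per condition, downsampled to the analysis rate when needed. Every
#' condition is encoded, trained from one shared seeded reservoir, and
#' contrasted against Pre.
#'
#' @param config [pipeline_config()].
#' @param inputs `"fixture"` or a character vector of file paths.
#' @param out_dir optional directory for artifacts (delta TSVs, summary CSVs
#'   and `report.json`).
#' @param conditions conditions to process (must include "Pre").
#' @return Report list: per-contrast spike/firing/retained-edge counts and
#'   dominance, plus the full `summaries` and `deltas` (class
#'   `snn_pipeline_result`).
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(fixture_duration = 4, grid_n_per_axis = 7)
#' res <- run_pipeline(cfg, conditions = c("Pre", "Sound1"))
#' res$report$contrasts$Sound1$dominance
#' }
run_pipeline <- function(config = pipeline_config(), inputs = "fixture",
                         out_dir = NULL,
                         conditions = condition_levels()) {
  stopifnot(inherits(config, "snn_pipeline_config"))
  if (!"Pre" %in% conditions) stop("conditions must include the Pre baseline")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  montage <- make_default_montage()
  recs <- stage("inputs", {
    if (identical(inputs, "fixture")) {
      make_study_fixture(seed = config$seed,
                         duration = config$fixture_duration,
                         rate = config$analysis_rate,
                         conditions = conditions)$recordings
    } else {
      rl <- lapply(inputs, read_recording, montage = montage)
      rl <- lapply(rl, function(r)
        if (r$rate != config$analysis_rate)
          downsample(r, config$analysis_rate) else r)
      names(rl) <- vapply(rl, function(r) as.character(r$condition),
                          character(1))
      rl[intersect(condition_levels(), names(rl))]
    }
  })
  grid <- stage("grid", synthetic_grid(config$grid_n_per_axis))
  base <- stage("reservoir",
                init_small_world(grid, config$swc,
                                 seed = derive_seed(config$seed, "reservoir"),
                                 lif = config$lif, montage = montage))
  rasters <- stage("encode",
                   lapply(recs, sf_encode, params = config$encoder))
  models <- stage("train", {
    out <- lapply(rasters, function(r) stdp_train(base, r, config$stdp))
    names(out) <- names(recs)
    out
  })
  contrasts <- setdiff(names(models), "Pre")
  deltas <- list(); summaries <- list()
  for (cond in contrasts) {
    deltas[[cond]] <- stage(paste0("subtract:", cond), {
      retain_top(subtract_models(models$Pre, models[[cond]]),
                 fraction = config$retain_fraction,
                 relative = config$relative)
    })
    summaries[[cond]] <- stage(paste0("regions:", cond),
                               summarize_regions(deltas[[cond]],
                                                 montage = montage))
  }
  report <- list(
    schema = config$schema,
    seed = config$seed,
    conditions = names(models),
    spike_counts = lapply(rasters, function(r) sum(r$spikes != 0)),
    firing_counts = lapply(models, function(m) m$activity$n_fired),
    contrasts = lapply(summaries, function(s)
      list(retained_edges = s$n_retained, assigned_edges = s$n_assigned,
           dominance = s$dominance)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (cond in contrasts) {
      write.table(deltas[[cond]]$edges,
                  file.path(out_dir, sprintf("delta_Pre_vs_%s.tsv", cond)),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.csv(summaries[[cond]]$increase - summaries[[cond]]$decrease,
                       file.path(out_dir, sprintf("regions_Pre_vs_%s.csv",
                                                  cond)))
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(report = report, summaries = summaries, deltas = deltas,
                 models = models, config = config),
            class = "snn_pipeline_result")
}
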