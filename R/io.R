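#' Read / write event-record concentration data
#'
#' The on-disk format is a plain CSV in pharmacometric event-record layout,
#' one row per event: `ID` (dataset), `OCC` (occasion: 1 pre-, 2
#' post-treatment), `TIME` \[s\], `TISSUE` (muscle / tumor / liver; empty
#' on dose rows), `DV` (observed concentration \[mM\]; empty on dose rows),
#' `AMT` (dose \[µmol\]; empty on observation rows), `EVID` (1 dose, 0
#' observation), `ANEST` (0/1) and `VTI` (1-4). Reading validates the
#' schema loudly: a missing column, an unknown tissue label, or
#' non-monotone times within a curve each raise a distinct error class.
#' `write_dataset()` round-trips bit-exact on text fields.
#'
#' @param path CSV file path.
#' @return `read_dataset()` returns a validated event-record tibble;
#'   `write_dataset()` returns `path` invisibly.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("No such file: ", path), class = "dcepop_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  .validate_records(df)
}

#' @rdname read_dataset
#' @param data Event-record data (a `study_data` object or tibble).
#' @export
write_dataset <- function(data, path) {
  if (inherits(data, "study_data")) data <- data$data
  data <- .validate_records(data)
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run manifest
#'
#' Reproducibility header attached to pipeline outputs: seed, model
#' identifiers, a content hash of the dataset, package version and
#' timestamp. Identical manifests imply identical outputs for the
#' deterministic stages.
#'
#' @param data Event-record data.
#' @param models Character vector of model identifiers.
#' @param seed Integer seed.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(data, models, seed) {
  if (inherits(data, "study_data")) data <- data$data
  structure(
    list(seed = as.integer(seed), models = models,
         data_hash = .hash_records(data),
         n_datasets = length(unique(data$ID)),
         version = as.character(utils::packageVersion("dcepop")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest"
  )
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> seed ", x$seed, ", ", x$n_datasets,
      " datasets, models: ", paste(x$models, collapse = ", "),
      "\n  data ", x$data_hash, ", dcepop ", x$version, ", ",
      x$timestamp, "\n", sep = "")
  invisible(x)
}

#' End-to-end analysis pipeline
#'
#' Orchestrates simulate (optional) -> fit -> diagnose -> compare for a
#' configured list of candidate topologies: fits every model to the same
#' data, computes CWRES and chain-stability diagnostics for the reference
#' model, and tabulates the OFV/DIC comparison. All randomness flows from
#' `config$seed` via the manifest; no hidden global state.
#'
#' @param x A [study_design()] (data are simulated first) or event-record
#'   data.
#' @param models Named list of [compartment_graph()]s, or a character
#'   vector of preset names. The first entry is the reference model.
#' @param config A [sampler_config()].
#' @param outdir Optional directory; when given, writes `data.csv`,
#'   `summary_<model>.csv`, `cwres.csv`, `comparison.csv` and
#'   `manifest.yaml` there.
#' @return List of class `pipeline_result`: `manifest`, `data`, `fits`,
#'   `summaries`, `cwres`, `stability`, `comparison`.
#' @export
run_pipeline <- function(x, models = "mtl3",
                         config = sampler_config("fast"),
                         outdir = NULL) {
  if (length(models) == 0) {
    abort("`models` must name at least one topology.",
          class = "dcepop_config_error")
  }
  if (is.character(models)) {
    models <- setNames(lapply(models, graph_preset), models)
  }
  if (is.null(names(models)) || any(names(models) == "")) {
    abort("`models` must be named.", class = "dcepop_config_error")
  }
  data <- if (inherits(x, "study_design")) {
    generate_study(x, seed = config$seed)$data
  } else if (inherits(x, "study_data")) {
    x$data
  } else {
    .validate_records(x)
  }
  manifest <- run_manifest(data, names(models), config$seed)
  fits <- list()
  for (nm in names(models)) {
    fits[[nm]] <- tryCatch(
      fit_population(data, models[[nm]], config = config),
      error = function(e) {
        abort(paste0("Stage `fit` failed for model ", nm, ": ",
                     conditionMessage(e)),
              class = "dcepop_pipeline_error", parent = e)
      }
    )
  }
  ref <- names(models)[1]
  cwres <- compute_cwres(fits[[ref]])
  stability <- chain_stability(fits[[ref]])
  comparison <- compare_models(fits, reference = ref)
  summaries <- lapply(fits, summarize_posterior)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_dataset(data, file.path(outdir, "data.csv"))
    for (nm in names(summaries)) {
      utils::write.csv(summaries[[nm]],
                       file.path(outdir, paste0("summary_", nm, ".csv")),
                       row.names = FALSE)
    }
    utils::write.csv(cwres, file.path(outdir, "cwres.csv"),
                     row.names = FALSE)
    utils::write.csv(comparison, file.path(outdir, "comparison.csv"),
                     row.names = FALSE)
    yaml::write_yaml(unclass(manifest), file.path(outdir, "manifest.yaml"))
  }
  structure(
    list(manifest = manifest, data = data, fits = fits,
         summaries = summaries, cwres = cwres, stability = stability,
         comparison = comparison),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$manifest)
  print(x$comparison)
  invisible(x)
}
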