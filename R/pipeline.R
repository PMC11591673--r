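#' Pipeline configuration
#'
#' Collects the full parameter set of a pipeline run. Unknown keys passed via
#' `...` are rejected (fail-fast); the effective configuration is serialised
#' as JSON into the output directory for provenance.
#'
#' @param input_dir directory of spectrum files (and the manifest, unless
#'   `manifest` points elsewhere).
#' @param output_dir output directory.
#' @param manifest manifest path; default `file.path(input_dir,
#'   "manifest.csv")`.
#' @param simulate logical: generate the input dataset first (into
#'   `input_dir`) with [simulateDataset()].
#' @param seed global seed driving every stochastic stage (simulation and
#'   fit-restart jitter).
#' @param organs optional organ subset.
#' @param snr simulated signal-to-noise ratio (simulate mode).
#' @param delta band clustering gap tolerance, cm-1.
#' @param threshold presence retention threshold.
#' @param collapse replicate collapse rule for [buildFeatures()].
#' @param ncomp_max,q2_gain,module_method,normalise chemometric settings, see
#'   [fingerprint()].
#' @param fit a [fitConfig()] list.
#' @return named list of class `"zfRamanConfig"`.
#' @export
pipelineConfig <- function(input_dir, output_dir,
                           manifest = file.path(input_dir, "manifest.csv"),
                           simulate = FALSE, seed = 1L, organs = NULL,
                           snr = 20, delta = 10, threshold = 0.60,
                           collapse = "maxA", ncomp_max = 7L, q2_gain = 0.01,
                           module_method = "norm", normalise = FALSE,
                           fit = fitConfig(), ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(names(extra), collapse = ", "))
  cfg <- list(input_dir = input_dir, output_dir = output_dir,
              manifest = manifest, simulate = simulate,
              seed = as.integer(seed), organs = organs, snr = snr,
              delta = delta, threshold = threshold, collapse = collapse,
              ncomp_max = as.integer(ncomp_max), q2_gain = q2_gain,
              module_method = module_method, normalise = normalise,
              fit = fit)
  class(cfg) <- "zfRamanConfig"
  cfg
}

.logLine <- function(log, msg, quiet = FALSE) {
  if (!quiet) message(msg)
  cat(msg, "\n", file = log, append = TRUE, sep = "")
}

#' Run the full fingerprinting pipeline
#'
#' Orchestrates, with a single seed: (optional) simulation, manifest and
#' spectrum reading, per-spectrum deconvolution, band clustering, presence
#' computation, the >60% retention rule, per-organ feature matrices, PLS-DA
#' with Q2 component selection, and the scalar-projection / vector-module
#' fingerprints. Writes per-stage CSV outputs plus `run.log` and
#' `config.json` into the output directory. Re-running on unchanged inputs
#' and configuration reproduces every CSV byte-identically.
#'
#' Outputs: `fit_report.csv`, `registry.csv`, `presence.csv`,
#' `retained.csv`, `band_annotations.csv` and, per organ,
#' `features_<organ>.csv`, `pls_report_<organ>.csv`,
#' `fingerprint_<organ>.csv`. On a stage failure a `FAILED` marker naming the
#' stage is left in the output directory and the error re-raised.
#'
#' @param config a [pipelineConfig()] list.
#' @param quiet suppress console messages (the run log is always written).
#' @return the output directory path, invisibly.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "zfRamanConfig"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(out, "run.log")
  cat("", file = log)
  jsonlite::write_json(config[setdiff(names(config), "fit")],
                       file.path(out, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  stage <- "init"
  result <- tryCatch({
    if (isTRUE(config$simulate)) {
      stage <- "simulate"
      .logLine(log, sprintf("[simulate] seed %d -> %s", config$seed,
                            config$input_dir), quiet)
      simulateDataset(config$input_dir,
                      organs = config$organs %||%
                        names(defaultBandLibrary()$organs),
                      snr = config$snr, seed = config$seed)
    }
    stage <- "manifest"
    manifest <- readManifest(config$manifest)
    if (!is.null(config$organs))
      manifest <- manifest[manifest$organ %in% config$organs, , drop = FALSE]
    missingFiles <- manifest$file[!file.exists(file.path(config$input_dir,
                                                         manifest$file))]
    if (length(missingFiles))
      stop("manifest references missing file(s): ",
           paste(missingFiles, collapse = ", "))
    .logLine(log, sprintf("[manifest] %d spectra, %d organs",
                          nrow(manifest), length(unique(manifest$organ))),
             quiet)
    stage <- "fit"
    fitcfg <- config$fit
    fitcfg$seed <- config$seed
    t0 <- proc.time()[["elapsed"]]
    fits <- fitDataset(config$input_dir, manifest, fitcfg)
    .logLine(log, sprintf("[fit] %d components from %d spectra (%.1f s)",
                          nrow(fits), nrow(manifest),
                          proc.time()[["elapsed"]] - t0), quiet)
    writeTable(fits, file.path(out, "fit_report.csv"))
    stage <- "registry"
    registry <- clusterBandFrequencies(fits, delta = config$delta,
                                       refine = TRUE)
    writeTable(bandTable(registry), file.path(out, "registry.csv"))
    .logLine(log, sprintf("[registry] %d canonical bands",
                          nrow(bandTable(registry))), quiet)
    stage <- "presence"
    presence <- presenceTable(registry, manifest)
    writeTable(presence, file.path(out, "presence.csv"))
    stage <- "retention"
    retained <- retainBands(presence, threshold = config$threshold)
    writeTable(retained, file.path(out, "retained.csv"))
    writeTable(annotateBands(attr(retained, "bands")),
               file.path(out, "band_annotations.csv"))
    .logLine(log, sprintf("[retention] %d bands retained across organs",
                          length(attr(retained, "bands"))), quiet)
    stage <- "fingerprint"
    members <- bandMembers(registry)
    for (org in sort(unique(retained$organ))) {
      fm <- buildFeatures(members, retained, org, manifest,
                          collapse = config$collapse)
      writeTable(as.data.frame(fm), file.path(out, paste0("features_", org,
                                                          ".csv")))
      fp <- withCallingHandlers(
        fingerprint(fm, ncomp_max = config$ncomp_max,
                    q2_gain = config$q2_gain,
                    module_method = config$module_method,
                    normalise = config$normalise),
        warning = function(w) {
          .logLine(log, sprintf("[fingerprint:%s] warning: %s", org,
                                conditionMessage(w)), quiet = TRUE)
          invokeRestart("muffleWarning")
        })
      writeTable(as.data.frame(fp),
                 file.path(out, paste0("fingerprint_", org, ".csv")))
      writeTable(data.frame(component = seq_along(fp@r2),
                            r2_cum = fp@r2, q2 = fp@q2,
                            selected = seq_along(fp@r2) <= fp@n_components),
                 file.path(out, paste0("pls_report_", org, ".csv")))
      .logLine(log, sprintf("[fingerprint] %s: %d descriptors, A* = %d", org,
                            length(modules(fp)), fp@n_components), quiet)
    }
    .logLine(log, "[done]", quiet)
    out
  }, error = function(e) {
    marker <- file.path(out, "FAILED")
    writeLines(c(paste("stage:", stage), conditionMessage(e)), marker)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
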