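#' Accessors for zfRaman classes
#'
#' Small accessor generics: `wavenumbers()` / `intensities()` / `sampleMeta()`
#' for [RamanSpectrum-class]; `components()` for [DHOFitResult-class];
#' `bandTable()` / `bandMembers()` for [BandRegistry-class];
#' `featureValues()` for [FeatureMatrix-class]; `modules()` / `projections()`
#' for [FingerprintTable-class].
#'
#' @param x an object of the corresponding class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))
#' @rdname accessors
#' @export
setGeneric("components", function(x) standardGeneric("components"))
#' @rdname accessors
#' @export
setGeneric("bandTable", function(x) standardGeneric("bandTable"))
#' @rdname accessors
#' @export
setGeneric("bandMembers", function(x) standardGeneric("bandMembers"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("modules", function(x) standardGeneric("modules"))
#' @rdname accessors
#' @export
setGeneric("projections", function(x) standardGeneric("projections"))

#' @rdname accessors
#' @export
setMethod("wavenumbers", "RamanSpectrum", function(x) x@wavenumbers)
#' @rdname accessors
#' @export
setMethod("intensities", "RamanSpectrum", function(x) x@intensities)
#' @rdname accessors
#' @export
setMethod("sampleMeta", "RamanSpectrum", function(x) x@sample)
#' @rdname accessors
#' @export
setMethod("components", "DHOFitResult", function(x) x@components)
#' @rdname accessors
#' @export
setMethod("bandTable", "BandRegistry", function(x) x@bands)
#' @rdname accessors
#' @export
setMethod("bandMembers", "BandRegistry", function(x) x@members)
#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("modules", "FingerprintTable", function(x) x@modules)
#' @rdname accessors
#' @export
setMethod("projections", "FingerprintTable", function(x) x@projections)

setMethod("show", "RamanSpectrum", function(object) {
  w <- object@wavenumbers
  cat(sprintf("RamanSpectrum: %d points, %.1f-%.1f cm-1\n",
              length(w), min(w), max(w)))
  if (nrow(object@sample))
    cat(sprintf("  sample: animal %s, %s, %d hpf (replicate %d)\n",
                object@sample$animal_id[1], object@sample$organ[1],
                object@sample$stage_hpf[1], object@sample$replicate[1]))
  invisible(object)
})

setMethod("show", "DHOFitResult", function(object) {
  cat(sprintf("DHOFitResult: %d components, rms residual %.4g, %s\n",
              nrow(object@components), object@rms_residual,
              if (object@converged) "converged" else "NOT converged"))
  if (nrow(object@components)) {
    cat("  F (cm-1):", paste(round(object@components$F, 1), collapse = ", "), "\n")
  }
  invisible(object)
})

setMethod("show", "BandRegistry", function(object) {
  cat(sprintf("BandRegistry: %d canonical bands from %d components (delta = %g cm-1)\n",
              nrow(object@bands), nrow(object@members), object@delta))
  cat("  bands:", paste(object@bands$band, collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix [%s]: %d observations x %d descriptors (%s)\n",
              object@organ, nrow(object@values), ncol(object@values),
              if (object@scaled) "autoscaled" else "raw"))
  cat(sprintf("  missing entries: %d\n", sum(is.na(object@values))))
  invisible(object)
})

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d components, %d observations, %d descriptors, %d classes\n",
              ncol(object@scores), nrow(object@scores), nrow(object@weights),
              length(object@classes)))
  cat("  cumulative R2:", paste(sprintf("%.3f", object@r2), collapse = ", "), "\n")
  if (length(object@q2))
    cat("  Q2:", paste(sprintf("%.3f", object@q2), collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "FingerprintTable", function(object) {
  cat(sprintf("FingerprintTable [%s]: %d descriptors, %d stages, A* = %d\n",
              object@organ, length(object@modules), nrow(object@projections),
              object@n_components))
  top <- utils::head(object@modules, 6L)
  cat("  top modules:",
      paste(sprintf("%s=%.3g", names(top), top), collapse = ", "), "\n")
  invisible(object)
})

#' Convert a FingerprintTable to a data frame
#'
#' One row per descriptor, sorted by decreasing vector module; columns are the
#' module followed by one signed scalar projection per developmental stage —
#' the tabular equivalent of a per-organ fingerprint heatmap.
#'
#' @param x a [FingerprintTable-class].
#' @param ... ignored.
#' @return a `data.frame` with columns `descriptor`, `module`, `proj_<hpf>...`.
#' @export
as.data.frame.FingerprintTable <- function(x, ...) {
  ord <- names(x@modules)
  pr <- t(x@projections[, ord, drop = FALSE])
  colnames(pr) <- paste0("proj_", rownames(x@projections))
  data.frame(descriptor = ord, module = unname(x@modules), pr,
             row.names = NULL, check.names = FALSE)
}

setMethod("show", "BackgroundModel", function(object) {
  cat(sprintf("BackgroundModel: %s (%s = %g)\n", object@kind,
              if (object@kind == "polynomial") "degree" else "lambda",
              object@param))
  invisible(object)
})
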