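#' @import methods
NULL

ORGAN_LEVELS <- c("iris", "forebrain", "melanocytes", "heart", "muscle", "swim_bladder")
STAGE_LEVELS <- seq(24L, 168L, by = 24L)

#' RamanSpectrum: one acquisition
#'
#' A single Raman acquisition: a strictly increasing wavenumber grid (cm-1),
#' the measured intensities (detector counts, arbitrary units) and the sample
#' metadata row (animal, clutch, organ, stage in hours post-fertilisation,
#' replicate).
#'
#' @slot wavenumbers numeric, strictly increasing, cm-1.
#' @slot intensities numeric, same length as `wavenumbers`.
#' @slot sample one-row `data.frame` of sample metadata (may have zero rows
#'   when no metadata are attached).
#' @exportClass RamanSpectrum
setClass("RamanSpectrum",
  representation(wavenumbers = "numeric", intensities = "numeric", sample = "data.frame"))

setValidity("RamanSpectrum", function(object) {
  w <- object@wavenumbers
  msg <- character()
  if (length(w) != length(object@intensities))
    msg <- c(msg, "wavenumbers and intensities differ in length")
  if (length(w) < 50L)
    msg <- c(msg, "spectrum has fewer than 50 points")
  if (anyNA(w) || anyNA(object@intensities))
    msg <- c(msg, "NA values in spectrum")
  if (length(w) > 1L && any(diff(w) <= 0))
    msg <- c(msg, "wavenumbers must be strictly increasing")
  if (length(w) && (min(w) < 50 || max(w) > 4100))
    msg <- c(msg, "wavenumber span outside the supported [50, 4100] cm-1 range")
  if (length(msg)) msg else TRUE
})

#' BackgroundModel: smooth spectral baseline
#'
#' @slot kind `"polynomial"` (coefficients in a scaled monomial basis) or
#'   `"asymmetric_smooth"` (Whittaker/asymmetric-least-squares curve sampled on
#'   its fitting grid).
#' @slot coefficients numeric; polynomial coefficients or the sampled curve.
#' @slot param numeric; polynomial degree, or the smoothing penalty lambda.
#' @slot grid numeric; fit window for the polynomial scaling, or the sampling
#'   grid of the smooth curve.
#' @exportClass BackgroundModel
setClass("BackgroundModel",
  representation(kind = "character", coefficients = "numeric",
                 param = "numeric", grid = "numeric"))

setValidity("BackgroundModel", function(object) {
  if (!object@kind %in% c("polynomial", "asymmetric_smooth"))
    return("kind must be 'polynomial' or 'asymmetric_smooth'")
  if (anyNA(object@coefficients) || any(!is.finite(object@coefficients)))
    return("background coefficients must be finite")
  TRUE
})

#' DHOFitResult: a deconvoluted spectrum
#'
#' Result of fitting background + a sum of damped-harmonic-oscillator band
#' profiles to one spectrum. `components` holds one row per fitted band with
#' columns `F` (natural frequency, cm-1), `W` (damping width Gamma, cm-1),
#' `A` (integrated band area, counts * cm-1) and `amplitude` (internal DHO
#' scale factor), sorted by increasing `F`.
#'
#' @slot components `data.frame` with columns `F`, `W`, `A`, `amplitude`.
#' @slot background a [BackgroundModel-class].
#' @slot rms_residual root-mean-square fit residual, counts.
#' @slot converged logical optimiser status.
#' @slot n_iterations integer.
#' @exportClass DHOFitResult
setClass("DHOFitResult",
  representation(components = "data.frame", background = "BackgroundModel",
                 rms_residual = "numeric", converged = "logical",
                 n_iterations = "integer"))

setValidity("DHOFitResult", function(object) {
  cm <- object@components
  need <- c("F", "W", "A", "amplitude")
  if (!all(need %in% names(cm)))
    return("components must have columns F, W, A, amplitude")
  if (nrow(cm)) {
    if (any(cm$F <= 0) || any(cm$W <= 0) || any(cm$A < 0))
      return("component parameters out of range (need F > 0, W > 0, A >= 0)")
    if (is.unsorted(cm$F, strictly = TRUE))
      return("components must be sorted strictly ascending in F")
  }
  TRUE
})

#' BandRegistry: canonical bands across a dataset
#'
#' Groups all fitted band frequencies into canonical bands via single-linkage
#' gap clustering. `bands` has one row per canonical band (`band` label,
#' `canonical_F` median frequency, `n_members`); `members` maps every input
#' component to its band label.
#'
#' @slot bands `data.frame` with columns `band`, `canonical_F`, `n_members`.
#' @slot members `data.frame`: the input component table plus a `band` column.
#' @slot delta numeric clustering gap tolerance, cm-1.
#' @exportClass BandRegistry
setClass("BandRegistry",
  representation(bands = "data.frame", members = "data.frame", delta = "numeric"))

setValidity("BandRegistry", function(object) {
  if (anyDuplicated(object@bands$band))
    return("band labels must be unique")
  TRUE
})

#' FeatureMatrix: per-organ descriptor matrix
#'
#' Rows are (animal, stage) observations of one organ; columns are descriptors
#' named `A<band>`, `W<band>`, `F<band>` for that organ's retained bands.
#' Missing entries (band not presented by that animal at that stage) are `NA`
#' until [autoscale()] imputes them.
#'
#' @slot values numeric matrix, possibly containing `NA`.
#' @slot animal_id character, one per row.
#' @slot stage_hpf integer, one per row.
#' @slot organ character scalar.
#' @slot scaled logical: has autoscaling been applied?
#' @slot center,scale numeric scaling parameters (empty until scaled).
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(values = "matrix", animal_id = "character",
                 stage_hpf = "integer", organ = "character",
                 scaled = "logical", center = "numeric", scale = "numeric"))

setValidity("FeatureMatrix", function(object) {
  if (nrow(object@values) != length(object@animal_id) ||
      nrow(object@values) != length(object@stage_hpf))
    return("row metadata lengths do not match the value matrix")
  cn <- colnames(object@values)
  if (is.null(cn) || !all(grepl("^[AWF][0-9]+$", cn)))
    return("descriptor names must match ^[AWF]<band>$")
  TRUE
})

#' PLSModel: NIPALS PLS2 discriminant model
#'
#' Fitted on an autoscaled descriptor matrix X with the developmental stages
#' encoded as a centered one-column-per-stage indicator matrix Y.
#'
#' @slot scores X-score matrix T (observations x components).
#' @slot weights X-weight matrix W (descriptors x components), unit columns.
#' @slot loadings X-loading matrix P (descriptors x components).
#' @slot yloadings Y-loading matrix Q (stage classes x components).
#' @slot r2 cumulative fraction of Y variance explained, per component count.
#' @slot q2 cross-validated Q2 per component count (empty until computed).
#' @slot classes integer stage values (hpf) defining the Y columns.
#' @slot ymeans numeric column means of the raw indicator matrix.
#' @exportClass PLSModel
setClass("PLSModel",
  representation(scores = "matrix", weights = "matrix", loadings = "matrix",
                 yloadings = "matrix", r2 = "numeric", q2 = "numeric",
                 classes = "integer", ymeans = "numeric"))

setValidity("PLSModel", function(object) {
  a <- ncol(object@scores)
  if (ncol(object@weights) != a || ncol(object@loadings) != a ||
      ncol(object@yloadings) != a)
    return("score/weight/loading matrices disagree on component count")
  if (length(object@r2) != a)
    return("need one cumulative R2 value per component")
  if (a > 1L && any(diff(object@r2) < -1e-10))
    return("cumulative R2 must be non-decreasing")
  TRUE
})

#' FingerprintTable: scalar projections and vector modules for one organ
#'
#' @slot projections matrix (stage classes x descriptors) of signed scalar
#'   projections of the stage Y-loadings on the descriptor X-loading
#'   directions, in the space of the retained PLS components.
#' @slot modules named numeric vector of per-descriptor vector modules (>= 0),
#'   sorted decreasing.
#' @slot organ character scalar.
#' @slot n_components integer: retained components A*.
#' @slot r2,q2 numeric: the model-selection traces.
#' @slot module_method character: module definition used.
#' @exportClass FingerprintTable
setClass("FingerprintTable",
  representation(projections = "matrix", modules = "numeric", organ = "character",
                 n_components = "integer", r2 = "numeric", q2 = "numeric",
                 module_method = "character"))

setValidity("FingerprintTable", function(object) {
  if (any(object@modules < 0))
    return("vector modules must be non-negative")
  if (!all(names(object@modules) %in% colnames(object@projections)))
    return("module names must be projection columns")
  TRUE
})
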