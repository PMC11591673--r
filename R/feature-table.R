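#' Build the per-organ descriptor matrix
#'
#' One row per (animal, stage) observation of the organ (rows come from the
#' manifest, so an animal with no detected components still yields a row of
#' missing values); columns are `A<band>`, `W<band>`, `F<band>` for the
#' organ's retained bands in band-then-variable order (`A980, W980, F980,
#' A1002, ...`). When an animal presents a band at a stage, the component with
#' the largest area among its replicate spectra fills the three descriptors
#' (`collapse = "maxA"`), or the replicate mean with `collapse = "mean"`;
#' otherwise the cell is missing (`NA`).
#'
#' @param fitReport fit report of [fitDataset()] augmented with a `band`
#'   column — i.e. the member table of a [BandRegistry-class] built from it.
#' @param retained retained-band pairs from [retainBands()].
#' @param organ organ name.
#' @param manifest the dataset manifest.
#' @param collapse replicate collapse rule, `"maxA"` (default) or `"mean"`.
#' @return a [FeatureMatrix-class] (raw, unscaled).
#' @export
buildFeatures <- function(fitReport, retained, organ, manifest,
                          collapse = c("maxA", "mean")) {
  collapse <- match.arg(collapse)
  organ <- .normalizeOrgan(organ)
  bands <- retained$band[retained$organ == organ]
  if (!length(bands))
    stop("no retained bands for organ '", organ, "'")
  bands <- bands[order(as.numeric(bands))]
  man <- manifest[manifest$organ == organ, , drop = FALSE]
  obs <- unique(man[, c("animal_id", "stage_hpf")])
  obs <- obs[order(obs$animal_id, obs$stage_hpf), , drop = FALSE]
  cols <- as.vector(t(outer(bands, c("A", "W", "F"),
                            function(b, v) paste0(v, b))))
  vals <- matrix(NA_real_, nrow(obs), length(cols),
                 dimnames = list(NULL, cols))
  sub <- fitReport[fitReport$organ == organ & fitReport$band %in% bands, ,
                   drop = FALSE]
  for (i in seq_len(nrow(obs))) {
    rows <- sub[sub$animal_id == obs$animal_id[i] &
                sub$stage_hpf == obs$stage_hpf[i], , drop = FALSE]
    if (!nrow(rows)) next
    for (b in unique(rows$band)) {
      rb <- rows[rows$band == b, , drop = FALSE]
      if (collapse == "maxA") {
        j <- which.max(rb$A)
        awf <- c(rb$A[j], rb$W[j], rb$F[j])
      } else {
        awf <- c(mean(rb$A), mean(rb$W), mean(rb$F))
      }
      vals[i, paste0(c("A", "W", "F"), b)] <- awf
    }
  }
  new("FeatureMatrix", values = vals, animal_id = as.character(obs$animal_id),
      stage_hpf = as.integer(obs$stage_hpf), organ = organ,
      scaled = FALSE, center = numeric(), scale = numeric())
}

#' Construct a FeatureMatrix from plain arrays
#'
#' Convenience constructor for simulated or externally assembled descriptor
#' matrices.
#'
#' @param values numeric matrix with descriptor column names (`A980`, ...).
#' @param animal_id,stage_hpf row metadata vectors.
#' @param organ organ tag.
#' @return a [FeatureMatrix-class].
#' @export
featureMatrix <- function(values, animal_id, stage_hpf, organ = "unknown") {
  new("FeatureMatrix", values = as.matrix(values),
      animal_id = as.character(animal_id), stage_hpf = as.integer(stage_hpf),
      organ = organ, scaled = FALSE, center = numeric(), scale = numeric())
}

#' Autoscale a feature matrix
#'
#' Column-wise: subtract the mean and divide by the sample standard deviation,
#' both computed over non-missing entries; missing entries are then imputed
#' with 0 (the column mean — neutral under centered PLS). Columns with zero
#' variance (or fewer than 2 non-missing values) are dropped with a warning.
#' The scaling parameters are kept on the object for the inverse transform.
#'
#' @param fm a raw [FeatureMatrix-class].
#' @return the scaled [FeatureMatrix-class]; `@center` and `@scale` hold the
#'   per-column parameters.
#' @seealso [inverseAutoscale()]
#' @export
autoscale <- function(fm) {
  stopifnot(is(fm, "FeatureMatrix"))
  if (fm@scaled) stop("feature matrix is already autoscaled")
  x <- fm@values
  ctr <- colMeans(x, na.rm = TRUE)
  scl <- apply(x, 2, stats::sd, na.rm = TRUE)
  nok <- colSums(!is.na(x))
  drop <- which(nok < 2L | !is.finite(scl) | scl < 1e-12)
  if (length(drop)) {
    warning("dropping zero-variance descriptor(s): ",
            paste(colnames(x)[drop], collapse = ", "))
    x <- x[, -drop, drop = FALSE]
    ctr <- ctr[-drop]; scl <- scl[-drop]
  }
  z <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  z[is.na(z)] <- 0
  new("FeatureMatrix", values = z, animal_id = fm@animal_id,
      stage_hpf = fm@stage_hpf, organ = fm@organ, scaled = TRUE,
      center = ctr, scale = scl)
}

#' Invert autoscaling
#'
#' Maps a scaled matrix back to the original descriptor units. Imputed cells
#' come back as the column mean, so only originally observed values are
#' reproduced exactly.
#'
#' @param fm an autoscaled [FeatureMatrix-class].
#' @return a raw [FeatureMatrix-class].
#' @export
inverseAutoscale <- function(fm) {
  stopifnot(is(fm, "FeatureMatrix"), fm@scaled)
  x <- sweep(sweep(fm@values, 2, fm@scale, "*"), 2, fm@center, "+")
  new("FeatureMatrix", values = x, animal_id = fm@animal_id,
      stage_hpf = fm@stage_hpf, organ = fm@organ, scaled = FALSE,
      center = numeric(), scale = numeric())
}

#' Export a FeatureMatrix as a data frame
#' @param x a [FeatureMatrix-class].
#' @param ... ignored.
#' @return `data.frame` with `animal_id`, `stage_hpf`, then descriptors.
#' @export
as.data.frame.FeatureMatrix <- function(x, ...) {
  data.frame(animal_id = x@animal_id, stage_hpf = x@stage_hpf,
             x@values, row.names = NULL, check.names = FALSE)
}
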