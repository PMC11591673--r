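#' Read a two-column Raman spectrum file
#'
#' Accepts whitespace-, tab- or comma-delimited two-column numeric text
#' (wavenumber in cm-1, intensity in counts). Lines starting with `#` are
#' comments; an optional `wavenumber,intensity` header line is recognised.
#' Spectra recorded high-to-low wavenumber are silently reversed so the
#' returned grid is always ascending.
#'
#' @param path file path.
#' @param meta optional one-row `data.frame` of sample metadata (as produced
#'   by [readManifest()]) to attach to the spectrum.
#' @return a [RamanSpectrum-class].
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(sprintf("%g %g", seq(100, 4000, 2), rexp(1951) + 10), f)
#' sp <- readSpectrum(f)
#' range(wavenumbers(sp))
#' @export
readSpectrum <- function(path, meta = NULL) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) && grepl("^\\s*wavenumber", lines[idx[1]], ignore.case = TRUE))
    idx <- idx[-1]
  if (!length(idx)) stop("no data rows in ", path)
  parts <- strsplit(trimws(lines[idx]), "[,\t ]+")
  n <- lengths(parts)
  if (any(n < 2L))
    stop("malformed row at line ", idx[which(n < 2L)[1]], " of ", path)
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(!is.finite(w) | !is.finite(y))
  if (length(bad))
    stop("non-numeric value at line ", idx[bad[1]], " of ", path)
  if (length(w) < 50L)
    stop("degenerate spectrum (", length(w), " points < 50) in ", path)
  if (anyDuplicated(w))
    stop("duplicate wavenumbers in ", path)
  if (all(diff(w) < 0)) { w <- rev(w); y <- rev(y) }
  if (is.unsorted(w, strictly = TRUE)) {
    o <- order(w); w <- w[o]; y <- y[o]
  }
  new("RamanSpectrum", wavenumbers = w, intensities = y,
      sample = if (is.null(meta)) data.frame() else as.data.frame(meta))
}

#' Write a spectrum as two-column ASCII
#'
#' Full `%.17g` precision so a write-then-read round trip reproduces the
#' numeric arrays bit-identically.
#'
#' @param spectrum a [RamanSpectrum-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  stopifnot(is(spectrum, "RamanSpectrum"))
  con <- file(path, open = "wb")  # binary: fixed "\n" endings on any platform
  on.exit(close(con))
  writeLines(c("# wavenumber_cm-1 intensity_counts",
               sprintf("%.17g %.17g", spectrum@wavenumbers, spectrum@intensities)),
             con, sep = "\n")
  invisible(path)
}

.normalizeOrgan <- function(x) {
  gsub("[ -]+", "_", tolower(trimws(x)))
}

#' Read a dataset manifest
#'
#' The manifest is the single source of truth for sample metadata: a CSV with
#' columns `file`, `animal_id`, `clutch_id`, `organ`, `stage_hpf`,
#' `replicate`. Organ names are normalised case-insensitively (e.g.
#' `"Swim Bladder"` to `"swim_bladder"`). Stages must lie in 24..168 hpf in
#' 24 h steps. Organ/stage combinations outside the study observation windows
#' (iris and forebrain from 24 hpf; melanocytes, heart and muscle from 48 hpf;
#' swim bladder from 96 hpf) raise a warning, or an error when
#' `strict = TRUE`.
#'
#' @param path CSV file path.
#' @param strict logical; escalate window violations and out-of-grid stages
#'   from warning to error.
#' @return a `data.frame`, one row per spectrum file.
#' @export
readManifest <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "animal_id", "clutch_id", "organ", "stage_hpf", "replicate")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stop("manifest is missing required column(s): ", paste(missing, collapse = ", "))
  m$organ <- .normalizeOrgan(m$organ)
  bad <- setdiff(unique(m$organ), ORGAN_LEVELS)
  if (length(bad))
    stop("unknown organ value(s): ", paste(bad, collapse = ", "))
  m$stage_hpf <- as.integer(m$stage_hpf)
  m$replicate <- as.integer(m$replicate)
  if (any(m$replicate < 1L)) stop("replicate must be >= 1")
  offgrid <- !(m$stage_hpf %in% STAGE_LEVELS)
  if (any(offgrid)) {
    msg <- paste("stage_hpf outside {24,48,...,168}:",
                 paste(unique(m$stage_hpf[offgrid]), collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  starts <- organStageWindows()
  early <- m$stage_hpf < starts[m$organ]
  if (any(early, na.rm = TRUE)) {
    msg <- paste0("organ/stage combinations before the observation window: ",
                  paste(unique(paste0(m$organ[early], "@", m$stage_hpf[early])),
                        collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  m$animal_id <- as.character(m$animal_id)
  m$clutch_id <- as.character(m$clutch_id)
  m
}

#' Observation windows per organ
#'
#' First stage (hpf) at which each organ is measurable: iris and forebrain
#' from 24 hpf, melanocytes/heart/muscle from 48 hpf, swim bladder from
#' 96 hpf; all run to 168 hpf.
#'
#' @return named integer vector of window start stages.
#' @export
organStageWindows <- function() {
  c(iris = 24L, forebrain = 24L, melanocytes = 48L, heart = 48L,
    muscle = 48L, swim_bladder = 96L)
}

#' Stages at which an organ is observed
#' @param organ organ name.
#' @param stages candidate stage grid (hpf).
#' @return integer vector of stages within the organ's window.
#' @export
organStages <- function(organ, stages = STAGE_LEVELS) {
  organ <- .normalizeOrgan(organ)
  start <- organStageWindows()[[organ]]
  as.integer(stages[stages >= start])
}

#' Write a pipeline output table as CSV
#'
#' UTF-8, `.` decimal separator, header, deterministic column order (as given).
#' Numbers are written with full double precision (15 significant digits), so
#' re-reading reproduces values to better than 12 significant digits.
#'
#' @param rows a `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTable <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(rows, con, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
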