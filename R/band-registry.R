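#' Cluster fitted band frequencies into canonical bands
#'
#' Single-linkage clustering in one dimension: all fitted `F` values are
#' sorted and cut wherever the gap between consecutive values exceeds
#' `delta`; each run becomes one canonical band. The canonical frequency is
#' the median of the member frequencies and the label its nearest integer
#' (made unique by appending the exact rounded median when two clusters round
#' to the same integer, which cannot happen for gaps > 1).
#'
#' With `refine = TRUE`, clusters whose frequency span exceeds `max_span`
#' are recursively split at their largest internal gap. This guards the
#' plain gap rule against rare "bridge" components — compromise fits that
#' land between two close bands and chain them into one cluster — while
#' leaving genuinely tight clusters (spans a few cm-1) untouched. The
#' pipeline enables it; the default is the unrefined single-linkage rule.
#'
#' @param componentTable `data.frame` with at least a numeric `F` column —
#'   typically the fit report of [fitDataset()]; all other columns are kept in
#'   the member table.
#' @param delta gap tolerance, cm-1 (default 10; the closest canonical
#'   zebrafish bands are 19 cm-1 apart).
#' @param refine split over-wide clusters at their largest internal gap.
#' @param max_span refinement threshold on the cluster frequency span
#'   (default `1.5 * delta`).
#' @return a [BandRegistry-class]; empty input gives an empty registry.
#' @examples
#' reg <- clusterBandFrequencies(data.frame(F = c(979, 981, 1408, 1410)), delta = 10)
#' bandTable(reg)$band   # "980"  "1409"
#' @export
clusterBandFrequencies <- function(componentTable, delta = 10, refine = FALSE,
                                   max_span = 1.5 * delta) {
  stopifnot(delta > 0)
  if (is.numeric(componentTable))
    componentTable <- data.frame(F = componentTable)
  if (!nrow(componentTable)) {
    return(new("BandRegistry",
               bands = data.frame(band = character(), canonical_F = numeric(),
                                  n_members = integer()),
               members = cbind(componentTable, band = character(0)),
               delta = delta))
  }
  o <- order(componentTable$F)
  f <- componentTable$F[o]
  bounds <- c(0L, which(diff(f) > delta), length(f))
  runs <- lapply(seq_len(length(bounds) - 1L),
                 function(k) (bounds[k] + 1L):bounds[k + 1L])
  if (refine) {
    splitWide <- function(idx) {
      if (length(idx) < 2L || diff(range(f[idx])) <= max_span)
        return(list(idx))
      g <- which.max(diff(f[idx]))
      c(splitWide(idx[seq_len(g)]), splitWide(idx[-seq_len(g)]))
    }
    runs <- do.call(c, lapply(runs, splitWide))
  }
  cl <- integer(length(f))
  for (k in seq_along(runs)) cl[runs[[k]]] <- k
  canon <- tapply(f, cl, stats::median)
  labels <- as.character(round(canon))
  if (anyDuplicated(labels))
    labels <- make.unique(labels, sep = "_")
  members <- componentTable
  members$band <- labels[cl][order(o)]
  bands <- data.frame(band = labels,
                      canonical_F = as.numeric(canon),
                      n_members = as.integer(table(cl)),
                      row.names = NULL)
  new("BandRegistry", bands = bands, members = members, delta = delta)
}

#' Presence fractions per (organ, stage, band)
#'
#' For each organ, stage and canonical band: the fraction of animals measured
#' at that organ/stage that present the band, where an animal presents a band
#' if any of its replicate spectra contains a member component (replicate
#' multiplicity never inflates the count). (organ, stage) cells with zero
#' measured animals are omitted.
#'
#' @param registry a [BandRegistry-class] whose member table carries `organ`,
#'   `animal_id`, `stage_hpf` columns.
#' @param manifest the dataset manifest (defines which animals were measured
#'   for each organ/stage, independently of any detection).
#' @return long `data.frame`: `organ`, `stage_hpf`, `band`, `fraction`,
#'   `n_animals`.
#' @export
presenceTable <- function(registry, manifest) {
  stopifnot(is(registry, "BandRegistry"))
  mem <- bandMembers(registry)
  need <- c("organ", "animal_id", "stage_hpf")
  if (!all(need %in% names(mem)))
    stop("registry members lack metadata columns: ",
         paste(setdiff(need, names(mem)), collapse = ", "))
  cells <- unique(manifest[, c("organ", "stage_hpf")])
  cells <- cells[order(cells$organ, cells$stage_hpf), , drop = FALSE]
  bands <- bandTable(registry)$band
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    org <- cells$organ[i]; st <- cells$stage_hpf[i]
    animals <- unique(manifest$animal_id[manifest$organ == org &
                                         manifest$stage_hpf == st])
    n <- length(animals)
    if (!n) next
    sub <- mem[mem$organ == org & mem$stage_hpf == st &
               mem$animal_id %in% animals, c("band", "animal_id")]
    cnt <- vapply(bands, function(b)
      length(unique(sub$animal_id[sub$band == b])), integer(1))
    out[[i]] <- data.frame(organ = org, stage_hpf = st, band = bands,
                           fraction = cnt / n, n_animals = n,
                           row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply the >60% presence retention rule
#'
#' A band is retained for an organ when there exists at least one stage at
#' which strictly more than `threshold` of the measured animals present it
#' (a fraction exactly equal to the threshold does not retain). The global
#' retained set is the union over organs.
#'
#' @param presence output of [presenceTable()].
#' @param threshold retention fraction in (0, 1); default 0.60.
#' @return `data.frame` with columns `organ`, `band` (retained pairs); the
#'   union of retained band labels is in `attr(, "bands")`.
#' @export
retainBands <- function(presence, threshold = 0.60) {
  stopifnot(threshold > 0, threshold < 1)
  keep <- presence$fraction > threshold
  pairs <- unique(presence[keep, c("organ", "band")])
  pairs <- pairs[order(pairs$organ, pairs$band), , drop = FALSE]
  rownames(pairs) <- NULL
  attr(pairs, "bands") <- sort(unique(pairs$band))
  pairs
}

.BAND_ASSIGNMENTS <- local({
  a <- c(
    "796"  = "O-P-O stretching / DNA phosphodiester backbone",
    "980"  = "symmetric stretching of phosphate (PO4 3-)",
    "1002" = "phenylalanine ring breathing",
    "1032" = "aromatic amino acids (Phe/Trp/Tyr) / amide",
    "1156" = "aromatic amino acids / carotenoid-associated region",
    "1199" = "amide III",
    "1307" = "CH bending/scissoring",
    "1375" = "CH bending/scissoring",
    "1409" = "CH bending/scissoring",
    "1450" = "CH bending/scissoring",
    "1519" = "carotenoids / amide",
    "1603" = "aromatic amino acids (Phe/Trp/Tyr) / amide I",
    "1639" = "amide I / C=C stretching",
    "2852" = "CH stretching (lipids/proteins)",
    "2929" = "CH2/CH3 stretching (lipids/proteins)",
    "2978" = "CH stretching (lipids/proteins)",
    "3002" = "CH stretching (lipids/proteins)",
    "3058" = "CH stretching",
    "3213" = "O-H stretching (water)",
    "3431" = "O-H stretching (water)")
  unl <- c("223", "621", "845", "1584")
  c(a, stats::setNames(rep("unassigned", length(unl)), unl))
})

#' Literature vibration assignments for the canonical bands
#'
#' Static annotation table for the 24 canonical zebrafish band labels;
#' labels outside the canonical set are annotated `"unknown band"`.
#'
#' @param labels character vector of band labels (e.g. `"980"`); defaults to
#'   the full canonical set.
#' @return `data.frame` with columns `band`, `assignment`.
#' @examples
#' annotateBands(c("980", "1199", "9999"))
#' @export
annotateBands <- function(labels = names(.BAND_ASSIGNMENTS)) {
  labels <- as.character(labels)
  ann <- .BAND_ASSIGNMENTS[labels]
  ann[is.na(ann)] <- "unknown band"
  data.frame(band = labels, assignment = unname(ann), row.names = NULL)
}
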