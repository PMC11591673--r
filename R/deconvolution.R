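#' Damped-harmonic-oscillator band profile
#'
#' Spectral response of a damped harmonic oscillator with natural frequency
#' `F` (cm-1), damping width `W` (Gamma, cm-1) and scale factor `amplitude`:
#'
#' \deqn{I(\nu) = A_0 \frac{F^2 W \nu}{(F^2-\nu^2)^2 + (W\nu)^2}}
#'
#' On resonance (`nu == F`) the profile equals `amplitude * F / W`; for
#' `W << F` it is near-Lorentzian with FWHM approximately `W`, and for strong
#' damping its argmax shifts below `F`. The reported band frequency is always
#' the natural frequency, not the profile maximum.
#'
#' @param nu wavenumber(s), cm-1, `>= 0`.
#' @param F natural frequency, cm-1, `> 0`.
#' @param W damping width, cm-1, `> 0`.
#' @param amplitude scale factor `A0`, counts, `>= 0`.
#' @return intensities, same length as `nu`.
#' @examples
#' dhoProfile(1000, F = 1000, W = 20, amplitude = 1)  # = F/W = 50
#' @export
dhoProfile <- function(nu, F, W, amplitude = 1) {
  if (any(F <= 0)) stop("F must be > 0")
  if (any(W <= 0)) stop("W must be > 0")
  if (any(amplitude < 0)) stop("amplitude must be >= 0")
  amplitude * (F^2 * W * nu) / ((F^2 - nu^2)^2 + (W * nu)^2)
}

# peak height <-> A0 conversion at resonance
.dhoHeightToAmp <- function(height, F, W) height * W / F

# d(profile)/d(F, W, A0) at fixed nu; returns list of vectors
.dhoGrad <- function(nu, F, W, A0) {
  d <- (F^2 - nu^2)^2 + (W * nu)^2
  base <- F^2 * W * nu / d
  list(
    dA0 = base,
    dF  = A0 * W * nu * 2 * F * (d - 2 * F^2 * (F^2 - nu^2)) / d^2,
    dW  = A0 * F^2 * nu * (d - 2 * W^2 * nu^2) / d^2
  )
}

#' Deconvolution configuration
#'
#' Collects every tunable of the deconvolution stage with its default. Unknown
#' names are rejected.
#'
#' @param background_kind `"polynomial"` (fitted jointly with the bands) or
#'   `"asymmetric_smooth"` (Whittaker asymmetric-least-squares pre-fit).
#' @param background_degree polynomial degree (default 3).
#' @param background_lambda smoothing penalty for the asymmetric baseline.
#' @param prominence_k peak-seed prominence threshold, in units of the noise
#'   median absolute deviation (default 5).
#' @param max_bands maximum number of seeded bands per spectrum.
#' @param min_amplitude prune fitted components whose amplitude-at-resonance
#'   (peak height) falls below this value; `NULL` (default) uses 2x the
#'   estimated noise sd.
#' @param merge_cm1 components closer than this after fitting are merged
#'   (default 5 cm-1).
#' @param restarts maximum jittered restarts on optimiser failure (default 3).
#' @param seed RNG seed for restart jitter.
#' @param ftol,ptol relative cost / parameter convergence tolerances.
#' @param maxiter maximum Levenberg-Marquardt iterations.
#' @param f_window half-width of the box constraint on each component's `F`
#'   around its seed, cm-1.
#' @param w_min,w_max bounds on the damping width, cm-1.
#' @return a named list with class `"dhoFitConfig"`.
#' @export
fitConfig <- function(background_kind = "polynomial", background_degree = 3L,
                      background_lambda = 1e6, prominence_k = 5,
                      max_bands = 30L, min_amplitude = NULL, merge_cm1 = 5,
                      restarts = 3L, seed = 1L, ftol = 1e-8, ptol = 1e-8,
                      maxiter = 200L, f_window = 12, w_min = 2, w_max = 200) {
  cfg <- list(background_kind = match.arg(background_kind,
                                          c("polynomial", "asymmetric_smooth")),
              background_degree = as.integer(background_degree),
              background_lambda = background_lambda,
              prominence_k = prominence_k, max_bands = as.integer(max_bands),
              min_amplitude = min_amplitude, merge_cm1 = merge_cm1,
              restarts = as.integer(restarts), seed = as.integer(seed),
              ftol = ftol, ptol = ptol, maxiter = as.integer(maxiter),
              f_window = f_window, w_min = w_min, w_max = w_max)
  class(cfg) <- "dhoFitConfig"
  cfg
}

# scaled monomial basis on x in [-1, 1]; conditioning for the joint fit
.polyBasis <- function(nu, lo, hi, degree) {
  x <- (nu - (lo + hi) / 2) / ((hi - lo) / 2)
  vapply(0:degree, function(k) x^k, numeric(length(nu)))
}

#' Evaluate a background model
#' @param background a [BackgroundModel-class].
#' @param nu wavenumbers, cm-1.
#' @return baseline intensities at `nu`.
#' @export
evalBackground <- function(background, nu) {
  stopifnot(is(background, "BackgroundModel"))
  if (background@kind == "polynomial") {
    b <- .polyBasis(nu, background@grid[1], background@grid[2],
                    length(background@coefficients) - 1L)
    drop(b %*% background@coefficients)
  } else {
    stats::approx(background@grid, background@coefficients, xout = nu,
                  rule = 2)$y
  }
}

#' Estimate a smooth spectral baseline
#'
#' Two estimators. `"polynomial"` is an iteratively clipped polynomial
#' (modified polyfit): fit, replace the signal by the pointwise minimum of
#' signal and fit, repeat until stable — this pins the polynomial to the
#' spectral envelope below the peaks. `"asymmetric_smooth"` is a Whittaker
#' smoother with asymmetric weights (positive residuals strongly
#' down-weighted), the standard asymmetric-least-squares baseline.
#'
#' The returned model seeds peak detection and, for the polynomial kind,
#' supplies the starting background coefficients of the joint fit.
#'
#' @param spectrum a [RamanSpectrum-class].
#' @param config a [fitConfig()] list.
#' @return a [BackgroundModel-class].
#' @export
estimateBackground <- function(spectrum, config = fitConfig()) {
  stopifnot(is(spectrum, "RamanSpectrum"))
  w <- spectrum@wavenumbers; y <- spectrum@intensities
  if (config$background_kind == "polynomial") {
    deg <- config$background_degree
    basis <- .polyBasis(w, min(w), max(w), deg)
    ywork <- y
    coef <- NULL
    for (i in seq_len(100L)) {
      fit <- stats::lm.fit(basis, ywork)
      z <- drop(basis %*% fit$coefficients)
      ynew <- pmin(ywork, z)
      coef <- fit$coefficients
      if (max(abs(ynew - ywork)) < 1e-9 * (stats::sd(y) + 1e-12)) { ywork <- ynew; break }
      ywork <- ynew
    }
    new("BackgroundModel", kind = "polynomial", coefficients = unname(coef),
        param = as.numeric(deg), grid = c(min(w), max(w)))
  } else {
    z <- .asls(y, lambda = config$background_lambda, p = 0.001, maxit = 15L)
    new("BackgroundModel", kind = "asymmetric_smooth", coefficients = z,
        param = config$background_lambda, grid = w)
  }
}

# Whittaker smoother with asymmetric weights (Eilers-Boelens style)
.asls <- function(y, lambda = 1e6, p = 0.001, maxit = 15L) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2L, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  DtD <- lambda * Matrix::crossprod(D)
  wts <- rep(1, n)
  z <- y
  for (i in seq_len(maxit)) {
    Wm <- Matrix::Diagonal(n, wts)
    z <- as.numeric(Matrix::solve(Wm + DtD, wts * y))
    wnew <- ifelse(y > z, p, 1 - p)
    if (all(wnew == wts)) break
    wts <- wnew
  }
  z
}

# robust noise sd from lag-1 differences
.noiseSd <- function(y) stats::mad(diff(y)) / sqrt(2)

# prominence of local maxima (index positions) in a signal
.peakProminence <- function(y, peaks) {
  vapply(peaks, function(i) {
    # walk outwards until a higher point (or the edge); base = min en route
    left <- if (i > 1L) {
      seg <- y[seq(i - 1L, 1L)]
      higher <- which(seg > y[i])
      if (length(higher)) min(seg[seq_len(higher[1])]) else min(seg)
    } else y[i]
    right <- if (i < length(y)) {
      seg <- y[seq(i + 1L, length(y))]
      higher <- which(seg > y[i])
      if (length(higher)) min(seg[seq_len(higher[1])]) else min(seg)
    } else y[i]
    y[i] - max(left, right)
  }, numeric(1))
}

#' Detect initial band seeds
#'
#' Local maxima of the smoothed (Savitzky-Golay), background-subtracted signal
#' whose topographic prominence exceeds `prominence_k` times the noise MAD.
#' Overlapped shoulders that produce no distinct maximum are additionally
#' seeded from minima of the smoothed second derivative (the standard
#' band-resolving trick in vibrational spectroscopy), subject to the same
#' kind of prominence threshold on the negated second derivative; derivative
#' seeds closer than 6 cm-1 to a direct maximum are discarded as duplicates.
#' Each seed carries a frequency (the maximum's wavenumber), a width guess
#' (full width at half prominence) and an amplitude guess (the smoothed
#' height).
#'
#' @param spectrum a [RamanSpectrum-class].
#' @param background optional [BackgroundModel-class]; estimated if missing.
#' @param config a [fitConfig()] list.
#' @return a `data.frame` with columns `F`, `W`, `height`, sorted by `F`;
#'   zero rows when nothing exceeds the threshold.
#' @export
initialPeaks <- function(spectrum, background = NULL, config = fitConfig()) {
  stopifnot(is(spectrum, "RamanSpectrum"))
  if (is.null(background)) background <- estimateBackground(spectrum, config)
  w <- spectrum@wavenumbers
  r <- spectrum@intensities - evalBackground(background, w)
  sigma <- .noiseSd(r)
  n <- length(r)
  fl <- min(11L, if (n %% 2L) n else n - 1L)
  s <- if (fl >= 5) signal::sgolayfilt(r, p = 2, n = fl) else r
  core <- 2:(n - 1L)
  pk <- core[s[core] > s[core - 1L] & s[core] >= s[core + 1L]]
  prom <- .peakProminence(s, pk)
  keep <- prom > config$prominence_k * sigma
  pk <- pk[keep]; prom <- prom[keep]
  # shoulder seeds: minima of the smoothed 2nd derivative inside band regions
  if (length(pk) && fl >= 9) {
    nd2 <- -signal::sgolayfilt(r, p = 3, n = max(fl, 15L), m = 2)
    # curvature scale of the smoothed noise; true band centers sit far above
    sig2 <- stats::mad(nd2)
    pk2 <- core[nd2[core] > nd2[core - 1L] & nd2[core] >= nd2[core + 1L]]
    keep2 <- nd2[pk2] > config$prominence_k * sig2 &
      s[pk2] > config$prominence_k * sigma
    pk2 <- pk2[keep2]
    dup <- vapply(pk2, function(i) any(abs(w[pk] - w[i]) < 6), logical(1))
    pk2 <- pk2[!dup]
    if (length(pk2)) {
      pk <- c(pk, pk2)
      prom <- c(prom, s[pk2])  # shoulder prominence proxy: smoothed height
      o <- order(pk); pk <- pk[o]; prom <- prom[o]
    }
  }
  if (!length(pk)) return(data.frame(F = numeric(), W = numeric(), height = numeric()))
  # width at half prominence around each maximum
  wseed <- vapply(seq_along(pk), function(j) {
    i <- pk[j]; half <- s[i] - prom[j] / 2
    l <- i; while (l > 1L && s[l] > half) l <- l - 1L
    rgt <- i; while (rgt < n && s[rgt] > half) rgt <- rgt + 1L
    max(w[rgt] - w[l], 4)
  }, numeric(1))
  out <- data.frame(F = w[pk], W = pmin(pmax(wseed, config$w_min), config$w_max),
                    height = pmax(s[pk], 0))
  out <- out[order(-out$height), , drop = FALSE]
  out <- utils::head(out, config$max_bands)
  out <- out[order(out$F), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# model evaluation: background coefs (in basis) + all components
.dhoModel <- function(par, basis, w, nb) {
  nbg <- ncol(basis)
  yhat <- drop(basis %*% par[seq_len(nbg)])
  if (nb) for (j in seq_len(nb)) {
    o <- nbg + 3L * (j - 1L)
    yhat <- yhat + dhoProfile(w, par[o + 1L], par[o + 2L], par[o + 3L])
  }
  yhat
}

.dhoJac <- function(par, basis, w, nb) {
  nbg <- ncol(basis)
  J <- matrix(0, length(w), nbg + 3L * nb)
  J[, seq_len(nbg)] <- basis
  if (nb) for (j in seq_len(nb)) {
    o <- nbg + 3L * (j - 1L)
    g <- .dhoGrad(w, par[o + 1L], par[o + 2L], par[o + 3L])
    J[, o + 1L] <- g$dF; J[, o + 2L] <- g$dW; J[, o + 3L] <- g$dA0
  }
  J
}

# one bounded LM solve; returns list(par, rms, converged, niter)
.lmSolve <- function(par0, lower, upper, basis, w, y, config) {
  res <- function(p) .dhoModel(p, basis, w, (length(p) - ncol(basis)) / 3L) - y
  jac <- function(p) .dhoJac(p, basis, w, (length(p) - ncol(basis)) / 3L)
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = res, jac = jac,
                            control = minpack.lm::nls.lm.control(
                              ftol = config$ftol, ptol = config$ptol,
                              maxiter = config$maxiter))
  list(par = fit$par, rms = sqrt(mean(fit$fvec^2)),
       converged = fit$info %in% 1:4, niter = fit$niter)
}

# numeric area of one component over [lo, hi] (trapezoid, 0.5 cm-1 grid)
.componentArea <- function(F, W, A0, lo, hi) {
  g <- seq(lo, hi, by = 0.5)
  v <- dhoProfile(g, F, W, A0)
  sum((v[-1] + v[-length(v)]) / 2) * 0.5
}

#' Fit a spectrum as background + sum of DHO bands
#'
#' Joint bounded Levenberg-Marquardt least squares over the polynomial
#' background coefficients and every band's `(F, W, amplitude)`, with an
#' analytic Jacobian. Each band's `F` is constrained to a window around its
#' seed. After the first solve, components whose peak height falls below the
#' pruning threshold are removed and the fit re-run once; components closer
#' than `merge_cm1` are merged (areas summed, amplitude-weighted `F` and `W`).
#' Band areas are computed by trapezoidal quadrature of each component profile
#' over the fit window on a 0.5 cm-1 grid.
#'
#' On optimiser failure the fit is restarted up to `config$restarts` times
#' from jittered seeds (jitter RNG seeded from `config$seed`); a fit that
#' never converges is returned with `converged = FALSE`, never as an error.
#'
#' @param spectrum a [RamanSpectrum-class] with finite intensities.
#' @param seeds `data.frame` with columns `F`, `W`, `height` (peak height,
#'   counts), or `NULL` to detect seeds with [initialPeaks()].
#' @param config a [fitConfig()] list.
#' @return a [DHOFitResult-class].
#' @export
fitSpectrum <- function(spectrum, seeds = NULL, config = fitConfig()) {
  stopifnot(is(spectrum, "RamanSpectrum"))
  if (any(!is.finite(spectrum@intensities)))
    stop("non-finite intensities")
  w <- spectrum@wavenumbers; y <- spectrum@intensities
  bg0 <- estimateBackground(spectrum,
                            if (config$background_kind == "polynomial") config
                            else config)
  if (is.null(seeds)) seeds <- initialPeaks(spectrum, bg0, config)
  deg <- config$background_degree
  basis <- .polyBasis(w, min(w), max(w), deg)
  # starting background coefficients from the pre-fit baseline
  bgy <- evalBackground(bg0, w)
  cstart <- stats::lm.fit(basis, bgy)$coefficients
  mkpar <- function(sd) {
    nb <- nrow(sd)
    par <- c(cstart)
    lower <- rep(-Inf, deg + 1L); upper <- rep(Inf, deg + 1L)
    if (nb) for (j in seq_len(nb)) {
      A0 <- .dhoHeightToAmp(max(sd$height[j], 1e-9), sd$F[j], sd$W[j])
      par <- c(par, sd$F[j], sd$W[j], A0)
      lower <- c(lower, max(sd$F[j] - config$f_window, min(w)),
                 config$w_min, 0)
      upper <- c(upper, min(sd$F[j] + config$f_window, max(w)),
                 config$w_max, Inf)
    }
    list(par = par, lower = lower, upper = upper)
  }
  runfit <- function(sd) {
    p <- mkpar(sd)
    sol <- .lmSolve(p$par, p$lower, p$upper, basis, w, y, config)
    if (!sol$converged && config$restarts > 0L && nrow(sd)) {
      rng <- .saveRNG(); on.exit(.restoreRNG(rng), add = TRUE)
      set.seed(config$seed)
      for (r in seq_len(config$restarts)) {
        sd2 <- sd
        sd2$F <- sd$F + stats::rnorm(nrow(sd), 0, 2)
        sd2$W <- sd$W * exp(stats::rnorm(nrow(sd), 0, 0.15))
        p2 <- mkpar(sd2)
        s2 <- .lmSolve(p2$par, p2$lower, p2$upper, basis, w, y, config)
        if (s2$rms < sol$rms) sol <- s2
        if (sol$converged) break
      }
    }
    sol
  }
  sol <- runfit(seeds)
  parseComp <- function(par) {
    nb <- (length(par) - deg - 1L) / 3L
    if (!nb) return(data.frame(F = numeric(), W = numeric(), amplitude = numeric()))
    idx <- deg + 1L + 3L * (seq_len(nb) - 1L)
    data.frame(F = par[idx + 1L], W = par[idx + 2L], amplitude = par[idx + 3L])
  }
  comp <- parseComp(sol$par)
  # prune weak components (threshold on peak height A0*F/W) and refit once
  minamp <- config$min_amplitude
  if (is.null(minamp)) minamp <- 2 * .noiseSd(y)
  if (nrow(comp)) {
    height <- comp$amplitude * comp$F / comp$W
    keep <- height >= minamp
    if (!all(keep)) {
      sd2 <- data.frame(F = comp$F[keep], W = comp$W[keep],
                        height = height[keep])
      sol <- runfit(sd2)
      comp <- parseComp(sol$par)
    }
  }
  comp <- comp[order(comp$F), , drop = FALSE]
  # merge components closer than merge_cm1
  if (nrow(comp) > 1L) {
    repeat {
      gaps <- diff(comp$F)
      i <- which(gaps < config$merge_cm1)
      if (!length(i)) break
      i <- i[1]
      a1 <- comp$amplitude[i]; a2 <- comp$amplitude[i + 1L]
      wsum <- a1 + a2
      if (wsum <= 0) { comp <- comp[-(i + 1L), , drop = FALSE]; next }
      comp$F[i] <- (a1 * comp$F[i] + a2 * comp$F[i + 1L]) / wsum
      comp$W[i] <- (a1 * comp$W[i] + a2 * comp$W[i + 1L]) / wsum
      comp$amplitude[i] <- wsum
      comp <- comp[-(i + 1L), , drop = FALSE]
    }
  }
  lo <- min(w); hi <- max(w)
  comp$A <- if (nrow(comp))
    vapply(seq_len(nrow(comp)),
           function(j) .componentArea(comp$F[j], comp$W[j], comp$amplitude[j], lo, hi),
           numeric(1)) else numeric()
  comp <- comp[, c("F", "W", "A", "amplitude")]
  rownames(comp) <- NULL
  bgout <- new("BackgroundModel", kind = "polynomial",
               coefficients = unname(sol$par[seq_len(deg + 1L)]),
               param = as.numeric(deg), grid = c(lo, hi))
  new("DHOFitResult", components = comp, background = bgout,
      rms_residual = sol$rms, converged = sol$converged,
      n_iterations = as.integer(sol$niter))
}

.saveRNG <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.restoreRNG <- function(s) {
  if (is.null(s)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", s, envir = globalenv())
}

#' Deconvolute every spectrum of a dataset
#'
#' Runs [fitSpectrum()] over a manifest, returning the long per-component fit
#' report used by the downstream band registry.
#'
#' @param dir directory containing the spectrum files named in the manifest.
#' @param manifest manifest `data.frame` from [readManifest()].
#' @param config a [fitConfig()] list.
#' @param verbose print one line per spectrum.
#' @return `data.frame` with columns `file`, `organ`, `animal_id`,
#'   `clutch_id`, `stage_hpf`, `replicate`, `component_index`, `F`, `W`, `A`,
#'   `rms_residual`, `converged`.
#' @export
fitDataset <- function(dir, manifest, config = fitConfig(), verbose = FALSE) {
  out <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, , drop = FALSE]
    sp <- readSpectrum(file.path(dir, row$file), meta = row)
    fit <- fitSpectrum(sp, seeds = NULL, config = config)
    cm <- components(fit)
    if (verbose)
      message(sprintf("%s: %d components, rms %.3g", row$file, nrow(cm),
                      fit@rms_residual))
    if (!nrow(cm)) { out[[i]] <- NULL; next }
    out[[i]] <- data.frame(file = row$file, organ = row$organ,
                           animal_id = row$animal_id, clutch_id = row$clutch_id,
                           stage_hpf = row$stage_hpf, replicate = row$replicate,
                           component_index = seq_len(nrow(cm)),
                           F = cm$F, W = cm$W, A = cm$A,
                           rms_residual = fit@rms_residual,
                           converged = fit@converged, row.names = NULL)
  }
  do.call(rbind, out)
}
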