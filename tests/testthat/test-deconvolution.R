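test_that("DHO profile limits and closed-form values", {
  expect_equal(dhoProfile(0, 1000, 20, 3), 0)
  # on resonance the profile equals amplitude * F / W
  expect_equal(dhoProfile(1000, 1000, 20, 1), 50)
  expect_equal(dhoProfile(1603, 1603, 30, 2), 2 * 1603 / 30)
  # vanishes at both ends, never negative
  nu <- seq(0, 8000, 0.5)
  v <- dhoProfile(nu, 1000, 200, 1)
  expect_true(all(v >= 0))
  expect_lt(v[length(v)], v[which.max(v)] / 100)
  # strong damping shifts the argmax below the natural frequency
  expect_lt(nu[which.max(v)], 1000)
  # amplitude 0 contributes nothing (identity property)
  expect_equal(dhoProfile(nu, 1000, 20, 0), rep(0, length(nu)))
  expect_error(dhoProfile(100, -5, 20, 1), "F")
  expect_error(dhoProfile(100, 1000, 0, 1), "W")
})

test_that("baseline estimation recovers smooth backgrounds", {
  g <- seq(100, 4000, 2)
  flat <- new("RamanSpectrum", wavenumbers = g,
              intensities = rep(120, length(g)), sample = data.frame())
  bg <- estimateBackground(flat)
  expect_lt(max(abs(evalBackground(bg, g) - 120)), 1e-6 * 120)
  # pure cubic baseline, no bands, no noise: recovered within 1% RMS
  x <- (g - 2050) / 1950
  truth <- 200 - 90 * x + 35 * x^2 - 15 * x^3
  sp <- new("RamanSpectrum", wavenumbers = g, intensities = truth,
            sample = data.frame())
  est <- evalBackground(estimateBackground(sp), g)
  expect_lt(sqrt(mean((est - truth)^2)) / sqrt(mean(truth^2)), 0.01)
  # baseline + one strong band: deviation under the band < 5% of band height
  height <- 400
  withband <- truth + dhoProfile(g, 1409, 13, height * 13 / 1409)
  sp2 <- new("RamanSpectrum", wavenumbers = g, intensities = withband,
             sample = data.frame())
  est2 <- evalBackground(estimateBackground(sp2), g)
  under <- abs(g - 1409) < 30
  expect_lt(max(abs(est2[under] - truth[under])), 0.05 * height)
  # asymmetric-smooth variant behaves comparably on the band-free cubic
  cfgA <- fitConfig(background_kind = "asymmetric_smooth")
  estA <- evalBackground(estimateBackground(sp, cfgA), g)
  expect_lt(sqrt(mean((estA - truth)^2)) / sqrt(mean(truth^2)), 0.02)
})

test_that("peak seeding: detection, resolution limit and null behaviour", {
  g <- seq(100, 4000, 1)
  # two synthetic bands at 980 and 1409, SNR 50: exactly 2 seeds within 10 cm-1
  set.seed(21)
  sp <- makeSpectrum(data.frame(F = c(980, 1409), W = c(12, 13),
                                height = c(100, 100)),
                     noise_sd = 2, grid = g)
  seeds <- initialPeaks(sp)
  expect_equal(nrow(seeds), 2)
  expect_lt(max(abs(seeds$F - c(980, 1409))), 10)
  # two components 4 cm-1 apart are below the resolvable separation: 1 seed
  sp2 <- makeSpectrum(data.frame(F = c(1407, 1411), W = c(13, 13),
                                 height = c(60, 60)),
                      noise_sd = 2, grid = g)
  seeds2 <- initialPeaks(sp2)
  expect_equal(nrow(seeds2), 1)
  # pure noise with k = 5: empty seed list in >= 95% of replicates
  empty <- vapply(1:100, function(s) {
    set.seed(s)
    spn <- makeSpectrum(data.frame(F = numeric(), W = numeric(),
                                   height = numeric()),
                        noise_sd = 5, grid = seq(100, 4000, 2))
    nrow(initialPeaks(spn)) == 0L
  }, logical(1))
  expect_gte(mean(empty), 0.95)
})

test_that("noiseless single-band fits are recovered to high accuracy", {
  sp <- makeSpectrum(data.frame(F = 1603, W = 30, height = 100),
                     baseline = function(nu) rep(80, length(nu)))
  fit <- fitSpectrum(sp, seeds = data.frame(F = 1603, W = 30, height = 100))
  cm <- components(fit)
  expect_equal(nrow(cm), 1)
  expect_lt(abs(cm$F - 1603), 0.1)
  expect_lt(abs(cm$W - 30) / 30, 0.01)
  trueA <- zfRaman:::.componentArea(1603, 30, 100 * 30 / 1603, 100, 4000)
  expect_lt(abs(cm$A - trueA) / trueA, 0.01)
  expect_true(fit@converged)
})

test_that("area conservation: integral of (model - background) equals A", {
  sp <- makeSpectrum(data.frame(F = 1002, W = 10, height = 150),
                     baseline = function(nu) 120 + 0.002 * nu)
  fit <- fitSpectrum(sp, seeds = data.frame(F = 1002, W = 10, height = 150))
  cm <- components(fit)
  g <- seq(100, 4000, 0.5)
  resid <- dhoProfile(g, cm$F, cm$W, cm$amplitude)
  quad <- sum((resid[-1] + resid[-length(resid)]) / 2) * 0.5
  expect_lt(abs(quad - cm$A) / cm$A, 1e-6)
})

test_that("degenerate inputs: zero spectrum, no seeds", {
  g <- seq(100, 4000, 1)
  sp <- new("RamanSpectrum", wavenumbers = g,
            intensities = rep(0, length(g)), sample = data.frame())
  fit <- fitSpectrum(sp, seeds = data.frame(F = numeric(), W = numeric(),
                                            height = numeric()))
  expect_equal(nrow(components(fit)), 0)
  expect_equal(fit@rms_residual, 0, tolerance = 1e-10)
  sp@intensities[5] <- NA_real_
  expect_error(fitSpectrum(sp), "finite")
})

test_that("fit never degrades the seed-point residual and is deterministic", {
  set.seed(9)
  bands <- data.frame(F = c(980, 1409, 1603), W = c(12, 13, 12),
                      height = c(70, 80, 90))
  sp <- makeSpectrum(bands, noise_sd = 4)
  seeds <- data.frame(F = bands$F + c(3, -3, 2), W = bands$W * 1.3,
                      height = bands$height * 0.8)
  cfg <- fitConfig()
  # rms at the seed point (background from the pre-fit estimate)
  bg <- estimateBackground(sp, cfg)
  y0 <- evalBackground(bg, wavenumbers(sp))
  for (j in 1:3) y0 <- y0 + dhoProfile(wavenumbers(sp), seeds$F[j], seeds$W[j],
                                       seeds$height[j] * seeds$W[j] / seeds$F[j])
  rmsSeed <- sqrt(mean((intensities(sp) - y0)^2))
  fit1 <- fitSpectrum(sp, seeds, cfg)
  expect_lte(fit1@rms_residual, rmsSeed)
  fit2 <- fitSpectrum(sp, seeds, cfg)
  expect_identical(components(fit1), components(fit2))
})

test_that("multi-band recovery at SNR 20 keeps frequencies within 2 cm-1", {
  # iris-like 6-band spectrum, a handful of replicates (the fuller
  # Monte-Carlo lives in the acceptance suite)
  lib <- defaultBandLibrary()
  bands <- lib$bands[lib$bands$band %in% lib$organs$iris, ]
  errs <- c()
  for (s in 1:5) {
    set.seed(s)
    sp <- makeSpectrum(bands[, c("F", "W", "height")],
                       baseline = function(nu) 180 - 0.02 * nu + 2e-6 * nu^2,
                       noise_sd = max(bands$height) / 20)
    cm <- components(fitSpectrum(sp))
    matched <- vapply(bands$F, function(f) min(abs(cm$F - f)), numeric(1))
    errs <- c(errs, matched)
  }
  expect_lt(median(errs), 2)
})
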