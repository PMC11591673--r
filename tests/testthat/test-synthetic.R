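test_that("the default band library matches the published constraints", {
  lib <- defaultBandLibrary()
  expect_equal(nrow(lib$bands), 24)
  sizes <- lengths(lib$organs)
  expect_equal(sizes[["iris"]], 6)
  expect_equal(sizes[["swim_bladder"]], 8)
  expect_equal(sizes[["melanocytes"]], 9)
  expect_equal(sizes[["forebrain"]], 9)
  expect_equal(sizes[["heart"]], 12)
  expect_equal(sizes[["muscle"]], 17)
  # the three universal bands belong to every organ set — and only they do
  tab <- table(unlist(lib$organs))
  expect_setequal(names(tab)[tab == 6], c("1603", "2929", "3431"))
  # exclusive bands
  expect_setequal(names(tab)[tab == 1 & names(tab) %in%
                             c("1307", "1375", "1639")],
                  c("1307", "1375", "1639"))
  for (b in c("1307", "1375", "1639"))
    expect_true(b %in% lib$organs$heart)
  muscleOnly <- c("223", "621", "796", "845", "1199", "1450", "1584",
                  "2852", "2978", "3002")
  expect_true(all(muscleOnly %in% lib$organs$muscle))
  expect_true(all(tab[muscleOnly] == 1))
  # 980 and 1409 exactly in iris, melanocytes and swim bladder
  for (b in c("980", "1409")) {
    inOrgans <- names(lib$organs)[vapply(lib$organs, function(s) b %in% s,
                                         logical(1))]
    expect_setequal(inOrgans, c("iris", "melanocytes", "swim_bladder"))
  }
})

test_that("the design yields 36 spectra per animal (216 in total)", {
  # window counting only; no rendering needed
  stages <- seq(24L, 168L, 24L)
  perAnimal <- sum(vapply(names(defaultBandLibrary()$organs),
                          function(o) length(organStages(o, stages)),
                          integer(1)))
  expect_equal(perAnimal, 36)     # 2x7 + 3x6 + 1x4
  d <- withr::local_tempdir()
  res <- simulateDataset(d, organs = c("iris", "swim_bladder"), seed = 17)
  expect_equal(nrow(res$manifest), 6 * (7 + 4))
  expect_true(all(file.exists(file.path(d, res$manifest$file))))
})

test_that("identical seeds give byte-identical datasets, different seeds differ", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  simulateDataset(d1, organs = "iris", stages = c(24, 48), seed = 23)
  simulateDataset(d2, organs = "iris", stages = c(24, 48), seed = 23)
  simulateDataset(d3, organs = "iris", stages = c(24, 48), seed = 24)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  expect_false(identical(unname(tools::md5sum(file.path(d1, "a01_iris_024.txt"))),
                         unname(tools::md5sum(file.path(d3, "a01_iris_024.txt")))))
})

test_that("truth areas equal an independent quadrature of the planted profile", {
  d <- withr::local_tempdir()
  res <- simulateDataset(d, organs = "iris", stages = 24, seed = 29)
  tr <- res$truth
  for (i in sample(nrow(tr), 5)) {
    ref <- stats::integrate(function(nu)
      dhoProfile(nu, tr$F[i], tr$W[i], tr$amplitude[i]),
      lower = 100, upper = 4000, rel.tol = 1e-10)$value
    expect_equal(tr$A[i], ref, tolerance = 1e-5)
  }
})

test_that("zero-noise flat-trend spectra are recovered by the deconvolution", {
  d <- withr::local_tempdir()
  res <- simulateDataset(d, organs = "iris", stages = 24, seed = 31,
                         snr = 1e9, null = TRUE,
                         a_animal_sd = 0, a_resid_sd = 0, w_animal_sd = 0,
                         w_resid_sd = 0, f_animal_sd = 0, f_resid_sd = 0,
                         baseline_jitter_sd = 0)
  m <- res$manifest[1, ]
  sp <- readSpectrum(file.path(d, m$file), m)
  cm <- components(fitSpectrum(sp))
  tr <- res$truth[res$truth$file == m$file, ]
  tr <- tr[order(tr$F), ]
  expect_equal(nrow(cm), nrow(tr))
  expect_lt(max(abs(cm$F - tr$F) / tr$F), 0.005)
  expect_lt(max(abs(cm$W - tr$W) / tr$W), 0.005)
  expect_lt(max(abs(cm$A - tr$A) / tr$A), 0.005)
})

test_that("per-animal presence follows the planted probability", {
  # presence is drawn per (animal, band); over many seeds the count of
  # presenting animals is Binomial(6, p)
  p <- 0.5
  counts <- vapply(1:60, function(s) {
    tr <- simulateBandParameters(seed = 1000 + s, organs = "iris",
                                 stages = 24, presence = p)
    sum(tapply(tr$band == "980", tr$animal_id, any))
  }, numeric(1))
  expTotal <- 6 * p
  se <- sqrt(6 * p * (1 - p) / length(counts))
  expect_lt(abs(mean(counts) - expTotal), 3 * se)
  # a band absent for an animal is absent at every stage
  tr <- simulateBandParameters(seed = 77, organs = "iris", presence = 0.5)
  byAnimal <- tapply(tr$band, tr$animal_id, unique)
  full <- table(tr$animal_id, tr$band)
  perStage <- length(organStages("iris"))
  expect_true(all(full %in% c(0L, perStage)))
})

test_that("null datasets have flat trends but the same structure", {
  trN <- simulateBandParameters(seed = 55, organs = "heart", null = TRUE,
                                a_animal_sd = 0, a_resid_sd = 0,
                                w_animal_sd = 0, w_resid_sd = 0,
                                f_animal_sd = 0, f_resid_sd = 0)
  # with all noise off and null trends, every stage repeats the same values
  sdByBand <- tapply(trN$height, paste(trN$animal_id, trN$band), sd)
  expect_lt(max(sdByBand), 1e-12)
  tr <- simulateBandParameters(seed = 55, organs = "heart",
                               a_animal_sd = 0, a_resid_sd = 0,
                               w_animal_sd = 0, w_resid_sd = 0,
                               f_animal_sd = 0, f_resid_sd = 0)
  sdByBand2 <- tapply(tr$height, paste(tr$animal_id, tr$band), sd)
  expect_gt(max(sdByBand2), 0.1)  # planted heart trends move A1639 etc.
})

test_that("invalid generator settings are rejected", {
  expect_error(simulateBandParameters(seed = 1, a_resid_sd = -0.1), "sds")
  expect_error(simulateBandParameters(n_animals = 1, seed = 1))
})
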