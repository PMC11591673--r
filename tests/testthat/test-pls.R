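test_that("a perfectly predictive descriptor explains its class column", {
  y <- rep(c(24, 48, 72), each = 4)
  Y <- indicatorY(y)
  X <- cbind(D1 = Y[, 1])  # the centered indicator of stage 24 itself
  m <- fitPLS(X, y, ncomp = 1)
  # residual variance of that class column after one component
  pred <- predictPLS(m, X, 1)
  ssr <- sum((Y[, 1] - pred[, 1])^2)
  expect_lt(ssr / sum(Y[, 1]^2), 1e-10)
})

test_that("NIPALS scores are mutually orthogonal", {
  set.seed(31)
  X <- matrix(rnorm(12 * 9), 12, 9, dimnames = list(NULL, sprintf("A%d", 1:9)))
  X <- scale(X)
  y <- rep(c(24, 48, 72, 96), each = 3)
  m <- fitPLS(X, y, ncomp = 4)
  G <- crossprod(m@scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  # cumulative R2 non-decreasing
  expect_true(all(diff(m@r2) >= -1e-12))
})

test_that("NIPALS agrees with the SVD-based second implementation", {
  set.seed(32)
  for (rep in 1:10) {
    n <- sample(8:20, 1); p <- sample(4:30, 1)
    k <- sample(2:min(7, n - 1), 1)
    y <- sample(seq(24, by = 24, length.out = k), n, replace = TRUE)
    while (length(unique(y)) < 2) y <- sample(seq(24, by = 24, length.out = k),
                                              n, replace = TRUE)
    X <- scale(matrix(rnorm(n * p), n, p,
                      dimnames = list(NULL, sprintf("A%d", seq_len(p)))))
    a <- min(3, qr(X)$rank, length(unique(y)))
    m <- fitPLS(X, y, ncomp = a)
    a <- ncol(m@scores)
    oracle <- svdPLS2(X, indicatorY(y), a)
    rms <- sqrt(mean((predictPLS(m, X, a) - X %*% oracle$B)^2))
    expect_lt(rms, 1e-6)
  }
})

test_that("NIPALS predictions match an established PLS implementation", {
  suppressMessages(requireNamespace("mixOmics", quietly = TRUE))
  set.seed(33)
  X <- scale(matrix(rnorm(18 * 10), 18, 10,
                    dimnames = list(NULL, sprintf("A%d", 1:10))))
  y <- rep(c(24, 48, 72), each = 6)
  Y <- indicatorY(y)
  m <- fitPLS(X, y, ncomp = 2)
  ref <- mixOmics::pls(X, Y, ncomp = 2, scale = FALSE, mode = "regression")
  pref <- predict(ref, X)$predict[, , 2]
  rms <- sqrt(mean((predictPLS(m, X, 2) - pref)^2))
  expect_lt(rms, 1e-6)
})

test_that("single-stage input is rejected", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("A1", "A2")))
  expect_error(fitPLS(X, rep(24, 10)), "2 classes")
})

test_that("Q2: null data scores near zero, planted signal scores high", {
  set.seed(34)
  null <- makeClassData(p = 12, planted = integer(0), snr = 0)
  q2n <- crossValidateQ2(scale(null$X), null$y, null$animals, ncomp = 2)
  expect_lt(q2n[1], 0.1)
  # with a one-directional planted separation, a 4-class indicator caps the
  # share of Y variance one component can carry; use two stages so Q2(1)
  # reflects the planted signal alone
  strong <- makeClassData(stages = c(24, 120), p = 12, planted = 1:3, snr = 10)
  q2s <- crossValidateQ2(scale(strong$X), strong$y, strong$animals, ncomp = 2)
  expect_gt(q2s[1], 0.5)
})

test_that("Q2 never exceeds R2 on random instances", {
  set.seed(35)
  for (rep in 1:8) {
    d <- makeClassData(p = sample(6:15, 1), planted = 1:2,
                       snr = runif(1, 0, 6))
    Xs <- scale(d$X)
    a <- 3
    m <- fitPLS(Xs, d$y, ncomp = a)
    q2 <- crossValidateQ2(Xs, d$y, d$animals, ncomp = ncol(m@scores))
    expect_true(all(q2 <= m@r2[seq_along(q2)] + 1e-10))
  }
})

test_that("component selection follows the strict-gain rule with floor 1", {
  expect_equal(selectComponents(q2 = c(0.5, 0.6, 0.61)), 2L)
  expect_equal(selectComponents(q2 = c(-0.2)), 1L)
  expect_equal(selectComponents(q2 = c(0.3, 0.5, 0.8)), 3L)
  expect_equal(selectComponents(q2 = c(0.009)), 1L)
})

test_that("scalar projections satisfy their geometric identities", {
  set.seed(36)
  d <- makeClassData(p = 10, planted = 1:3, snr = 8)
  m <- fitPLS(scale(d$X), d$y, ncomp = 2)
  # default: descriptor loading projected on the stage direction
  S <- scalarProjections(m, 2)
  P <- m@loadings[, 1:2]; Q <- m@yloadings[, 1:2]
  for (k in 1:2) for (j in 1:3)
    expect_equal(S[k, j], sum(P[j, ] * Q[k, ]) / sqrt(sum(Q[k, ]^2)),
                 tolerance = 1e-12)
  # alternative: stage projected on the descriptor direction, cosine identity
  S2 <- scalarProjections(m, 2, direction = "descriptor")
  for (k in 1:2) for (j in 1:3) {
    qk <- Q[k, ]; pj <- P[j, ]
    cosang <- sum(qk * pj) / (sqrt(sum(qk^2)) * sqrt(sum(pj^2)))
    expect_equal(S2[k, j], sqrt(sum(qk^2)) * cosang, tolerance = 1e-12)
  }
  # orthogonal vectors project to zero (both conventions)
  m2 <- m
  m2@yloadings[1, ] <- c(1, 0); m2@loadings[1, ] <- c(0, 2)
  expect_equal(scalarProjections(m2, 2)[1, 1], 0)
  expect_equal(scalarProjections(m2, 2, direction = "descriptor")[1, 1], 0)
})

test_that("1-component stage-on-descriptor projection reduces to sign(p)*q", {
  m <- new("PLSModel", scores = matrix(1, 4, 1), weights = matrix(1, 1, 1),
           loadings = matrix(0.5, 1, 1, dimnames = list("A1", NULL)),
           yloadings = matrix(2, 1, 1, dimnames = list("24", NULL)),
           r2 = 0.5, q2 = numeric(), classes = 24L, ymeans = 0.5)
  expect_equal(scalarProjections(m, 1, direction = "descriptor")[1, 1], 2.0)
})

test_that("projections are invariant to the per-component sign ambiguity", {
  set.seed(37)
  d <- makeClassData(p = 8, planted = 1:2, snr = 6)
  m <- fitPLS(scale(d$X), d$y, ncomp = 2)
  flipped <- m
  flipped@weights[, 2] <- -flipped@weights[, 2]
  flipped@scores[, 2] <- -flipped@scores[, 2]
  flipped@loadings[, 2] <- -flipped@loadings[, 2]
  flipped@yloadings[, 2] <- -flipped@yloadings[, 2]
  expect_equal(scalarProjections(flipped, 2), scalarProjections(m, 2),
               tolerance = 1e-12)
})

test_that("vector modules: closed forms and stage-permutation invariance", {
  S <- matrix(c(3, 4, 0, 0), 2, 2,
              dimnames = list(c("24", "48"), c("A1", "A2")))
  expect_equal(unname(vectorModule(S)["A1"]), 5)
  expect_equal(unname(vectorModule(S, "abs_sum")["A1"]), 7)
  expect_equal(unname(vectorModule(S, "sum_abs")["A1"]), 7)
  expect_equal(unname(vectorModule(-S, "abs_sum")["A1"]), 7)
  expect_equal(unname(vectorModule(S)["A2"]), 0)
  expect_equal(unname(vectorModule(S, normalise = TRUE)["A1"]), 1)
  Sp <- S[c(2, 1), ]
  expect_equal(vectorModule(Sp), vectorModule(S))
})

test_that("fingerprint surfaces the planted swim-bladder bands on top", {
  # trends are planted on bands 1409/1603/1156/1002: descriptors of those
  # four bands must appear among the top-6 modules
  plantedBands <- c("1409", "1603", "1156", "1002")
  hits <- replicate(8, NA_real_)
  for (s in seq_along(hits)) {
    tr <- simulateBandParameters(seed = 100 + s, organs = "swim_bladder")
    fp <- fingerprint(truthFeatures(tr, "swim_bladder"))
    topBands <- unique(sub("^[AWF]", "", names(modules(fp))[1:6]))
    hits[s] <- mean(plantedBands %in% topBands)
  }
  expect_gt(mean(hits), 0.8)
})

test_that("no-effect data gives no spuriously dominant module", {
  set.seed(38)
  tr <- simulateBandParameters(seed = 99, organs = "swim_bladder", null = TRUE)
  fm <- truthFeatures(tr, "swim_bladder")
  fp <- fingerprint(fm)
  # permutation null for the maximum module
  Xs <- autoscale(fm)
  a <- fp@n_components
  mx <- replicate(30, {
    yp <- sample(Xs@stage_hpf)
    mp <- fitPLS(featureValues(Xs), yp, ncomp = max(a, 2L))
    max(vectorModule(scalarProjections(mp, min(a, ncol(mp@scores)))))
  })
  expect_lt(max(modules(fp)), quantile(mx, 0.95) * 1.5)
})

test_that("fingerprint is deterministic", {
  tr <- simulateBandParameters(seed = 41, organs = "iris")
  fm <- truthFeatures(tr, "iris")
  f1 <- as.data.frame(fingerprint(fm))
  f2 <- as.data.frame(fingerprint(fm))
  expect_identical(f1, f2)
})
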