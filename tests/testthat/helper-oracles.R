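# Independent oracles and small fixture builders shared across tests.

# SVD-based PLS2: at each step the weight vector is the first left singular
# vector of X'Y (no power iteration), followed by the same score/loading
# deflation. Serves as the second, independent PLS implementation.
svdPLS2 <- function(X, Y, ncomp) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  W <- P <- NULL; Q <- NULL
  for (k in seq_len(ncomp)) {
    w <- svd(crossprod(X, Y), nu = 1, nv = 0)$u[, 1]
    tt <- X %*% w
    tt2 <- drop(crossprod(tt))
    p <- crossprod(X, tt) / tt2
    q <- crossprod(Y, tt) / tt2
    X <- X - tcrossprod(tt, p)
    Y <- Y - tcrossprod(tt, q)
    W <- cbind(W, w); P <- cbind(P, p); Q <- cbind(Q, q)
  }
  list(W = W, P = P, Q = Q,
       B = W %*% solve(crossprod(P, W)) %*% t(Q))
}

# centered stage indicator matrix (kept deliberately separate from the
# package internals so tests do not depend on them)
indicatorY <- function(y) {
  cl <- sort(unique(y))
  Y <- outer(y, cl, `==`) * 1
  sweep(Y, 2, colMeans(Y), "-")
}

# render a spectrum from explicit band truth (F, W, height) + polynomial
# baseline + optional noise; returns a RamanSpectrum
makeSpectrum <- function(bands, baseline = function(nu) rep(100, length(nu)),
                         noise_sd = 0, grid = seq(100, 4000, 1)) {
  y <- baseline(grid)
  if (nrow(bands)) {
    for (j in seq_len(nrow(bands))) {
      amp <- bands$height[j] * bands$W[j] / bands$F[j]
      y <- y + dhoProfile(grid, bands$F[j], bands$W[j], amp)
    }
  }
  if (noise_sd > 0) y <- y + rnorm(length(grid), 0, noise_sd)
  new("RamanSpectrum", wavenumbers = grid, intensities = y,
      sample = data.frame())
}

# descriptor matrix with planted stage-separated columns:
# planted columns get class means spaced by `snr` noise sds across stages
makeClassData <- function(n_animals = 6, stages = c(96, 120, 144, 168),
                          p = 20, planted = 1:4, snr = 10, noise_sd = 1) {
  y <- rep(stages, times = n_animals)
  animals <- rep(sprintf("a%02d", seq_len(n_animals)), each = length(stages))
  X <- matrix(rnorm(length(y) * p, 0, noise_sd), length(y), p)
  sep <- snr * noise_sd
  shift <- scale(seq_along(stages), scale = FALSE)
  for (j in seq_along(planted)) {
    # alternate trend shapes so planted columns are not collinear
    pattern <- if (j %% 2L) shift else rev(shift)
    X[, planted[j]] <- X[, planted[j]] + pattern[match(y, stages)] * sep
  }
  colnames(X) <- sprintf("%s%d", rep(c("A", "W", "F"), length.out = p),
                         1000 + seq_len(p))
  list(X = X, y = y, animals = animals,
       planted = colnames(X)[planted])
}
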