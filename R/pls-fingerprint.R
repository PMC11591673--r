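#' Encode stages as a centered indicator matrix
#' @param y integer/factor stage labels.
#' @return list: `Y` centered indicator matrix, `classes` sorted stage values,
#'   `means` raw column means.
#' @keywords internal
.stageIndicator <- function(y) {
  classes <- sort(unique(as.integer(y)))
  Y0 <- outer(as.integer(y), classes, `==`) * 1
  colnames(Y0) <- as.character(classes)
  mns <- colMeans(Y0)
  list(Y = sweep(Y0, 2, mns, "-"), classes = classes, means = mns)
}

# core NIPALS PLS2 on centered X, Y; sign convention: largest-|w| element > 0
.nipals <- function(X, Y, ncomp, tol = 1e-12, maxit = 10000L) {
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  Tm <- matrix(0, n, ncomp); Wm <- matrix(0, p, ncomp)
  Pm <- matrix(0, p, ncomp); Qm <- matrix(0, m, ncomp)
  ssy0 <- sum(Y^2)
  r2 <- numeric(ncomp)
  a <- 0L
  for (k in seq_len(ncomp)) {
    if (sum(X^2) < 1e-24 || sum(Y^2) < 1e-24) break
    u <- Y[, which.max(colSums(Y^2))]
    w <- crossprod(X, u)
    w <- w / sqrt(sum(w^2))
    if (m > 1L) {
      for (it in seq_len(maxit)) {
        tt <- X %*% w
        qq <- crossprod(Y, tt) / drop(crossprod(tt))
        u <- Y %*% qq / drop(crossprod(qq))
        wnew <- crossprod(X, u)
        wnew <- wnew / sqrt(sum(wnew^2))
        if (sum((wnew - w)^2) < tol^2) { w <- wnew; break }
        w <- wnew
      }
    }
    tt <- X %*% w
    tt2 <- drop(crossprod(tt))
    if (tt2 < 1e-24) break
    pp <- crossprod(X, tt) / tt2
    qq <- crossprod(Y, tt) / tt2
    # sign convention: the weight element of largest magnitude is positive
    s <- sign(w[which.max(abs(w))])
    if (s < 0) { w <- -w; tt <- -tt; pp <- -pp; qq <- -qq }
    X <- X - tcrossprod(tt, pp)
    Y <- Y - tcrossprod(tt, qq)
    Tm[, k] <- tt; Wm[, k] <- w; Pm[, k] <- pp; Qm[, k] <- qq
    r2[k] <- 1 - sum(Y^2) / ssy0
    a <- k
  }
  list(T = Tm[, seq_len(a), drop = FALSE], W = Wm[, seq_len(a), drop = FALSE],
       P = Pm[, seq_len(a), drop = FALSE], Q = Qm[, seq_len(a), drop = FALSE],
       r2 = r2[seq_len(a)], ncomp = a)
}

#' Fit a PLS-DA model by NIPALS
#'
#' The developmental stages are encoded as a centered one-column-per-stage
#' indicator matrix and regressed on the (already autoscaled) descriptor
#' matrix by NIPALS PLS2: per component, alternate weight/score/loading
#' updates to convergence, then deflate X and Y by the extracted component.
#' Component signs follow the convention that each weight vector's
#' largest-magnitude element is positive, so fingerprints are reproducible
#' across runs and implementations.
#'
#' With `mode = "pls1"` the single numeric response hpf is used instead of the
#' indicator matrix (provided for comparison; the fingerprint statistics are
#' defined on the discriminant encoding).
#'
#' @param X either an autoscaled [FeatureMatrix-class] or a plain centered
#'   numeric matrix.
#' @param y stage labels (hpf), one per row of `X`; defaulted from the
#'   FeatureMatrix metadata.
#' @param ncomp maximum number of components; silently truncated when the
#'   data support fewer.
#' @param mode `"plsda"` (default) or `"pls1"`.
#' @return a [PLSModel-class].
#' @export
fitPLS <- function(X, y = NULL, ncomp = 7L, mode = c("plsda", "pls1")) {
  mode <- match.arg(mode)
  if (is(X, "FeatureMatrix")) {
    if (!X@scaled) stop("autoscale the feature matrix before fitting")
    if (is.null(y)) y <- X@stage_hpf
    X <- X@values
  }
  X <- as.matrix(X)
  if (length(unique(y)) < 2L)
    stop("discriminant analysis needs >= 2 classes")
  feasible <- min(nrow(X) - 1L, ncol(X))
  if (ncomp > feasible) {
    warning("ncomp truncated to ", feasible)
    ncomp <- feasible
  }
  if (mode == "plsda") {
    enc <- .stageIndicator(y)
  } else {
    yv <- as.numeric(y)
    enc <- list(Y = matrix(yv - mean(yv), ncol = 1,
                           dimnames = list(NULL, "hpf")),
                classes = sort(unique(as.integer(y))), means = mean(yv))
  }
  fit <- .nipals(X, enc$Y, ncomp)
  rownames(fit$W) <- rownames(fit$P) <- colnames(X)
  rownames(fit$Q) <- colnames(enc$Y)
  new("PLSModel", scores = fit$T, weights = fit$W, loadings = fit$P,
      yloadings = fit$Q, r2 = fit$r2, q2 = numeric(),
      classes = as.integer(enc$classes), ymeans = unname(enc$means))
}

#' Predict the (centered) indicator responses for new observations
#'
#' Uses the standard regression-coefficient form
#' `B = W (P'W)^-1 Q'` restricted to the first `ncomp` components.
#'
#' @param model a [PLSModel-class].
#' @param Xnew matrix in the same (scaled, centered) descriptor space.
#' @param ncomp number of components (default: all).
#' @return matrix of predicted centered responses (add `model@ymeans` for
#'   class-membership scale).
#' @export
predictPLS <- function(model, Xnew, ncomp = ncol(model@scores)) {
  a <- seq_len(ncomp)
  Wa <- model@weights[, a, drop = FALSE]
  Pa <- model@loadings[, a, drop = FALSE]
  Qa <- model@yloadings[, a, drop = FALSE]
  B <- Wa %*% solve(crossprod(Pa, Wa)) %*% t(Qa)
  as.matrix(Xnew) %*% B
}

#' Cross-validated Q2 per component count
#'
#' Leave-one-animal-out cross-validation: all rows of one animal are held out
#' together (rows of an animal are dependent). Within each fold X and Y are
#' re-centered on the training rows, a NIPALS model fitted, and held-out
#' responses predicted. `Q2(a) = 1 - PRESS(a)/SS` with PRESS accumulated over
#' held-out predictions of the stage indicator matrix and SS the total
#' centered Y sum of squares.
#'
#' @param X autoscaled [FeatureMatrix-class] or plain matrix.
#' @param y stage labels, defaulted from the FeatureMatrix.
#' @param animals fold unit per row, defaulted from the FeatureMatrix.
#' @param ncomp maximum component count to evaluate.
#' @return numeric vector `Q2[1..ncomp]`.
#' @export
crossValidateQ2 <- function(X, y = NULL, animals = NULL, ncomp = 7L) {
  if (is(X, "FeatureMatrix")) {
    if (!X@scaled) stop("autoscale the feature matrix first")
    if (is.null(y)) y <- X@stage_hpf
    if (is.null(animals)) animals <- X@animal_id
    X <- X@values
  }
  X <- as.matrix(X)
  folds <- unique(animals)
  if (length(folds) < 3L)
    stop("leave-one-animal-out needs >= 3 animals")
  enc <- .stageIndicator(y)
  Yfull <- enc$Y
  ncomp <- min(ncomp, ncol(X), nrow(X) - max(table(animals)) - 1L)
  ncomp <- max(ncomp, 1L)
  press <- matrix(0, length(folds), ncomp)
  for (fi in seq_along(folds)) {
    hold <- animals == folds[fi]
    Xtr <- X[!hold, , drop = FALSE]; Xte <- X[hold, , drop = FALSE]
    Ytr0 <- Yfull[!hold, , drop = FALSE]; Yte <- Yfull[hold, , drop = FALSE]
    xm <- colMeans(Xtr); ym <- colMeans(Ytr0)
    Xtr <- sweep(Xtr, 2, xm, "-"); Ytr <- sweep(Ytr0, 2, ym, "-")
    Xte <- sweep(Xte, 2, xm, "-")
    fit <- .nipals(Xtr, Ytr, ncomp)
    for (a in seq_len(ncomp)) {
      aa <- min(a, fit$ncomp)
      if (aa < 1L) { press[fi, a] <- sum(Yte^2); next }
      idx <- seq_len(aa)
      Wa <- fit$W[, idx, drop = FALSE]; Pa <- fit$P[, idx, drop = FALSE]
      Qa <- fit$Q[, idx, drop = FALSE]
      B <- Wa %*% solve(crossprod(Pa, Wa)) %*% t(Qa)
      pred <- sweep(Xte %*% B, 2, ym, "+")
      press[fi, a] <- sum((Yte - pred)^2)
    }
  }
  ss <- sum(Yfull^2)
  1 - colSums(press) / ss
}

#' Choose the number of significant components
#'
#' `A*` is the largest `a` such that every incremental Q2 gain
#' `Q2(i) - Q2(i-1)` for `i <= a` strictly exceeds `gain` (with `Q2(0) = 0`);
#' at least one component is always retained.
#'
#' @param r2 cumulative R2 trace (unused by the default rule, kept for
#'   reporting symmetry).
#' @param q2 Q2 trace from [crossValidateQ2()].
#' @param gain minimum incremental Q2 per retained component (default 0.01).
#' @return integer `A*`.
#' @examples
#' selectComponents(q2 = c(0.5, 0.6, 0.61))  # 2
#' @export
selectComponents <- function(r2 = NULL, q2, gain = 0.01) {
  gains <- diff(c(0, q2))
  # strict inequality up to floating-point slack on the gain comparison
  ok <- gains - gain > 1e-9
  a <- if (all(ok)) length(q2) else which(!ok)[1] - 1L
  max(1L, as.integer(a))
}

#' Scalar projections between stages and descriptor loadings
#'
#' In the Cartesian space of the first `ncomp` PLS components, each stage
#' class `k` has a Y-loading vector `q_k` and each descriptor `j` an X-loading
#' vector `p_j`; the fingerprint entry `s_kj` is a signed scalar projection
#' between the two. Two conventions are provided:
#'
#' * `direction = "stage"` (default): project the descriptor loading onto the
#'   stage direction, `s_kj = (p_j . q_k) / ||q_k||`. The magnitude scales
#'   with the descriptor's loading, so the per-descriptor vector module acts
#'   as an importance measure (it tracks VIP); this is the convention the
#'   fingerprint tables use.
#' * `direction = "descriptor"`: project the stage Y-loading onto the
#'   descriptor direction, `s_kj = (q_k . p_j) / ||p_j|| =
#'   ||q_k|| cos(q_k, p_j)`. Purely directional — descriptors with tiny but
#'   aligned loadings score as high as dominant ones, so modules derived from
#'   it do not rank importance.
#'
#' Under both, positive values mean above-average descriptor values at that
#' stage, and the standard per-component PLS sign ambiguity cancels.
#'
#' @param model a [PLSModel-class].
#' @param ncomp number of significant components `A*`.
#' @param direction projection convention, see above.
#' @return matrix (stage classes x descriptors) of signed projections.
#' @export
scalarProjections <- function(model, ncomp = ncol(model@scores),
                              direction = c("stage", "descriptor")) {
  stopifnot(ncomp >= 1L, ncomp <= ncol(model@scores))
  direction <- match.arg(direction)
  a <- seq_len(ncomp)
  P <- model@loadings[, a, drop = FALSE]
  Q <- model@yloadings[, a, drop = FALSE]
  if (direction == "stage") {
    qn <- sqrt(rowSums(Q^2))
    zero <- qn < 1e-300
    if (any(zero)) {
      warning("stage Y-loading(s) with zero norm; projections set to 0: ",
              paste(rownames(Q)[zero], collapse = ", "))
      qn[zero] <- 1
    }
    S <- (Q / qn) %*% t(P)
    if (any(zero)) S[zero, ] <- 0
  } else {
    pn <- sqrt(rowSums(P^2))
    zero <- pn < 1e-300
    if (any(zero)) {
      warning("descriptor loading(s) with zero norm; projections set to 0: ",
              paste(rownames(P)[zero], collapse = ", "))
      pn[zero] <- 1
    }
    S <- Q %*% t(P / pn)
    if (any(zero)) S[, zero] <- 0
  }
  rownames(S) <- as.character(model@classes)
  colnames(S) <- rownames(P)
  S
}

#' Vector module of a descriptor's stage projections
#'
#' Aggregates each descriptor's scalar projections across stages into one
#' non-negative importance value. The default `"norm"` is the Euclidean
#' length of the stage-projection vector, `sqrt(sum(s_kj^2))`; alternatives
#' are `"abs_sum"` (`|sum_k s_kj|`, the literal length of the summed
#' projections, which lets opposite-signed stages cancel) and `"sum_abs"`
#' (`sum_k |s_kj|`). Optionally normalised to a maximum of 1.
#'
#' @param projections matrix from [scalarProjections()] (stages x
#'   descriptors).
#' @param method `"norm"` (default), `"abs_sum"` or `"sum_abs"`.
#' @param normalise divide by the largest module.
#' @return named numeric vector, sorted decreasing.
#' @export
vectorModule <- function(projections, method = c("norm", "abs_sum", "sum_abs"),
                         normalise = FALSE) {
  method <- match.arg(method)
  m <- switch(method,
              norm = sqrt(colSums(projections^2)),
              abs_sum = abs(colSums(projections)),
              sum_abs = colSums(abs(projections)))
  if (normalise && max(m) > 0) m <- m / max(m)
  sort(m, decreasing = TRUE)
}

#' Variable importance in projection (VIP)
#'
#' Standard VIP scores, used as the independent importance reference for the
#' vector module:
#' `VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a )` with unit-norm
#' weight vectors and `SSY_a` the Y sum of squares explained by component `a`.
#'
#' @param model a [PLSModel-class].
#' @param ncomp number of components.
#' @return named numeric vector of VIP scores.
#' @export
plsVIP <- function(model, ncomp = ncol(model@scores)) {
  a <- seq_len(ncomp)
  Wm <- model@weights[, a, drop = FALSE]
  ssy <- vapply(a, function(k)
    drop(crossprod(model@scores[, k])) * drop(crossprod(model@yloadings[, k])),
    numeric(1))
  p <- nrow(Wm)
  vip <- sqrt(p * colSums(t(Wm^2) * ssy) / sum(ssy))
  names(vip) <- rownames(Wm)
  vip
}

#' Per-organ fingerprint: projections and vector modules
#'
#' Composes the whole chemometric chain for one organ: autoscaling (when
#' given a raw matrix), NIPALS PLS-DA, leave-one-animal-out Q2,
#' component selection, scalar projections and vector modules.
#'
#' @param fm a [FeatureMatrix-class] (raw or autoscaled).
#' @param ncomp_max maximum components examined (default 7).
#' @param q2_gain component-selection gain threshold.
#' @param module_method,normalise passed to [vectorModule()].
#' @param direction projection convention, see [scalarProjections()].
#' @return a [FingerprintTable-class].
#' @export
fingerprint <- function(fm, ncomp_max = 7L, q2_gain = 0.01,
                        module_method = "norm", normalise = FALSE,
                        direction = "stage") {
  stopifnot(is(fm, "FeatureMatrix"))
  if (!fm@scaled) fm <- autoscale(fm)
  ncomp_max <- min(ncomp_max, ncol(fm@values), nrow(fm@values) - 1L)
  model <- fitPLS(fm, ncomp = ncomp_max)
  q2 <- crossValidateQ2(fm, ncomp = ncol(model@scores))
  astar <- min(selectComponents(model@r2, q2, gain = q2_gain),
               ncol(model@scores))
  S <- scalarProjections(model, astar, direction = direction)
  m <- vectorModule(S, method = module_method, normalise = normalise)
  new("FingerprintTable", projections = S, modules = m, organ = fm@organ,
      n_components = as.integer(astar), r2 = model@r2,
      q2 = q2[seq_len(ncol(model@scores))], module_method = module_method)
}
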