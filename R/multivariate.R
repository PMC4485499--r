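#' Column scaling for projection models
#'
#' Centers every column and optionally divides by the column standard
#' deviation (\code{"uv"}, unit variance) or its square root
#' (\code{"pareto"}). Constant columns always receive divisor 1 and are
#' flagged. The default for all models in this package is centering only,
#' so that back-scaled covariance loadings retain the spectral shape.
#'
#' @param X numeric matrix, samples in rows.
#' @param method \code{"center"}, \code{"pareto"} or \code{"uv"}.
#' @return list with \code{X} (the scaled matrix) and \code{params}
#'   (a \linkS4class{ScalingParams}).
#' @seealso \code{\link{applyScaling}}, \code{\link{unscaleColumns}}
#' @examples
#' s <- scaleColumns(matrix(rnorm(20), 5), "uv")
#' colMeans(s$X)
#' @export
scaleColumns <- function(X, method = c("center", "pareto", "uv")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  ctr <- colMeans(X)
  sds <- colSds(X)
  constant <- !is.finite(sds) | sds < .Machine$double.eps^0.5
  scl <- switch(method, center = rep(1, ncol(X)), uv = sds,
                pareto = sqrt(sds))
  scl[constant | scl == 0] <- 1
  params <- new("ScalingParams", method = method, center = ctr,
                scale = scl, constant = constant)
  list(X = applyScaling(X, params), params = params)
}

#' Apply previously fitted scaling parameters
#'
#' @param X numeric matrix with the same columns the parameters were
#'   fitted on.
#' @param params a \linkS4class{ScalingParams}.
#' @return the scaled matrix.
#' @rdname scaleColumns
#' @export
applyScaling <- function(X, params) {
  sweep(sweep(as.matrix(X), 2L, params@center), 2L, params@scale, "/")
}

#' Invert column scaling
#'
#' @param Xs a scaled matrix.
#' @rdname scaleColumns
#' @export
unscaleColumns <- function(Xs, params) {
  sweep(sweep(as.matrix(Xs), 2L, params@scale, "*"), 2L, params@center, "+")
}

# 0/1 (binary) or one-hot (multiclass) class coding; columns follow factor
# level order.
codeClasses <- function(labels) {
  f <- factor(labels)
  lv <- levels(f)
  if (length(lv) < 2L) stop("at least two classes are required")
  if (length(lv) == 2L) {
    Y <- matrix(as.numeric(f) - 1, ncol = 1L,
                dimnames = list(NULL, lv[2L]))
  } else {
    Y <- matrix(0, length(f), length(lv), dimnames = list(NULL, lv))
    Y[cbind(seq_along(f), as.integer(f))] <- 1
  }
  list(Y = Y, levels = lv, labels = as.character(f))
}

# Core NIPALS PLS on pre-scaled X and centered Y. Returns weights W,
# loadings P, scores T, y-weights C and residual sums of squares.
nipalsPls <- function(Xs, Yc, nComponents, tol = 1e-10, maxIter = 500L) {
  n <- nrow(Xs); p <- ncol(Xs); q <- ncol(Yc)
  ssX0 <- ssq(Xs); ssY0 <- ssq(Yc)
  if (ssX0 == 0) stop("X has zero variance after scaling")
  W <- matrix(0, p, nComponents); P <- matrix(0, p, nComponents)
  Tm <- matrix(0, n, nComponents); C <- matrix(0, q, nComponents)
  X <- Xs; Y <- Yc
  for (k in seq_len(nComponents)) {
    u <- Y[, which.max(colSds(Y)), drop = TRUE]
    tOld <- rep(Inf, n)
    for (iter in seq_len(maxIter)) {
      w <- drop(crossprod(X, u))
      nw <- sqrt(sum(w * w))
      if (nw == 0) stop("zero weight vector in component ", k,
                        ": no residual X variation")
      w <- w / nw
      tt <- drop(X %*% w)
      cc <- drop(crossprod(Y, tt)) / sum(tt * tt)
      u <- drop(Y %*% cc) / sum(cc * cc)
      if (sqrt(sum((tt - tOld)^2)) <= tol * sqrt(sum(tt * tt))) break
      tOld <- tt
      if (iter == maxIter)
        stop("NIPALS did not converge after ", maxIter,
             " iterations in component ", k)
    }
    pp <- drop(crossprod(X, tt)) / sum(tt * tt)
    X <- X - tcrossprod(tt, pp)
    Y <- Y - tcrossprod(tt, cc)
    W[, k] <- w; P[, k] <- pp; Tm[, k] <- tt; C[, k] <- cc
  }
  list(W = W, P = P, T = Tm, C = C,
       R2X = 1 - ssq(X) / ssX0,
       R2Y = if (ssY0 > 0) 1 - ssq(Y) / ssY0 else NA_real_)
}

#' Fit a PLS-DA model by NIPALS
#'
#' Partial least squares regression of a class-membership coding on the
#' (scaled) spectral matrix, computed one component at a time by the
#' NIPALS algorithm: the weight vector is proportional to \eqn{X'u} (unit
#' norm), scores \eqn{t = Xw}, y-weights \eqn{c = Y't/t't}, iterated to a
#' relative tolerance of 1e-10, then X and Y are deflated by the
#' component. Binary problems use centered 0/1 coding; three or more
#' classes use one-hot coding.
#'
#' @param X numeric matrix (samples x variables) or a
#'   \linkS4class{BinnedDataset}.
#' @param labels class label per sample.
#' @param nComponents number of components (<= min(n-1, p)).
#' @param scaling \code{"center"} (default), \code{"pareto"} or
#'   \code{"uv"}.
#' @param tol relative convergence tolerance of the NIPALS inner loop.
#' @param maxIter iteration cap per component; multi-class fits on weakly
#'   structured data may need more than the default 500 because the inner
#'   power iteration converges at the rate of the eigenvalue gap.
#' @return A \linkS4class{PlsModel}.
#' @examples
#' X <- matrix(rnorm(200), 20)
#' X[1:10, 1] <- X[1:10, 1] + 4
#' m <- fitPLSDA(X, rep(c("a", "b"), each = 10), nComponents = 2)
#' m
#' @export
fitPLSDA <- function(X, labels, nComponents = 2L,
                     scaling = c("center", "pareto", "uv"),
                     tol = 1e-10, maxIter = 500L) {
  if (is(X, "BinnedDataset")) X <- intensityMatrix(X)
  X <- as.matrix(X)
  nComponents <- as.integer(nComponents)
  if (nComponents < 1L) stop("nComponents must be >= 1")
  if (nComponents > min(nrow(X) - 1L, ncol(X)))
    stop("nComponents exceeds the rank bound min(n-1, p)")
  cod <- codeClasses(labels)
  sc <- scaleColumns(X, match.arg(scaling))
  yMeans <- colMeans(cod$Y)
  Yc <- sweep(cod$Y, 2L, yMeans)
  fit <- nipalsPls(sc$X, Yc, nComponents, tol = tol,
                   maxIter = as.integer(maxIter))
  new("PlsModel", scores = fit$T, loadings = fit$P, weights = fit$W,
      yWeights = fit$C, nComponents = nComponents,
      R2X = fit$R2X, R2Y = fit$R2Y, scaling = sc$params,
      yMeans = yMeans, classLevels = cod$levels, labels = cod$labels)
}

# Predict class-coding values for new raw rows from a fitted PlsModel.
predictPls <- function(model, Xnew) {
  Xs <- applyScaling(as.matrix(Xnew), model@scaling)
  Wstar <- model@weights %*%
    solve(crossprod(model@loadings, model@weights))
  Tnew <- Xs %*% Wstar
  sweep(Tnew %*% t(model@yWeights), 2L, model@yMeans, "+")
}

#' Predicted scores and class coding for new samples
#'
#' @param object a \linkS4class{PlsModel}.
#' @param newdata numeric matrix of raw (unscaled) rows.
#' @param ... unused.
#' @return matrix of predicted class-coding values (samples x classes).
#' @export
setMethod("predict", "PlsModel", function(object, newdata, ...)
  predictPls(object, newdata))

# Deterministic stratified fold assignment: per class, seeded shuffle then
# round-robin over folds.
assignFolds <- function(labels, nFolds, seed) {
  f <- factor(labels)
  if (any(table(f) < nFolds))
    warning("some class has fewer than ", nFolds,
            " members: stratification relaxed")
  folds <- integer(length(f))
  withSeed(as.integer(seed), {
    for (lv in levels(f)) {
      idx <- sample(which(f == lv))
      folds[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  folds
}

#' Cross-validated predictive ability Q2
#'
#' Eightfold (by default) stratified cross-validation of a PLS-DA model:
#' fold assignment is deterministic given the seed, scaling and the class
#' coding means are refit inside every training fold, and
#' \eqn{Q^2 = 1 - PRESS/TSS} with the total sum of squares taken about the
#' training-fold means of the class coding.
#'
#' @inheritParams fitPLSDA
#' @param nFolds number of folds (default 8).
#' @param seed integer seed controlling fold assignment.
#' @return A \linkS4class{ValidationReport} with the Q2 part filled in
#'   (no permutations).
#' @examples
#' X <- matrix(rnorm(400), 40)
#' X[1:20, 1:3] <- X[1:20, 1:3] + 3
#' crossValidatedQ2(X, rep(c("a", "b"), each = 20), seed = 1)
#' @export
crossValidatedQ2 <- function(X, labels, nFolds = 8L, nComponents = 2L,
                             scaling = c("center", "pareto", "uv"),
                             seed = 1L) {
  if (is(X, "BinnedDataset")) X <- intensityMatrix(X)
  X <- as.matrix(X)
  scaling <- match.arg(scaling)
  cod <- codeClasses(labels)
  folds <- assignFolds(cod$labels, nFolds, seed)
  press <- numeric(nFolds); tss <- numeric(nFolds)
  for (k in seq_len(nFolds)) {
    test <- which(folds == k)
    if (!length(test)) next
    train <- which(folds != k)
    if (length(unique(cod$labels[train])) < 2L)
      stop("training fold ", k, " contains a single class; ",
           "use fewer folds")
    m <- fitPLSDA(X[train, , drop = FALSE], cod$labels[train],
                  nComponents = nComponents, scaling = scaling)
    yhat <- predictPls(m, X[test, , drop = FALSE])
    Ytest <- codeClasses(factor(cod$labels,
                                levels = cod$levels))$Y[test, , drop = FALSE]
    press[k] <- sum((Ytest - yhat)^2)
    tss[k] <- sum(sweep(Ytest, 2L, m@yMeans)^2)
  }
  full <- fitPLSDA(X, cod$labels, nComponents = nComponents,
                   scaling = scaling)
  new("ValidationReport", Q2 = 1 - sum(press) / sum(tss), press = press,
      R2Y = full@R2Y, permQ2 = numeric(), permR2Y = numeric(),
      pQ2 = NA_real_, pR2Y = NA_real_, nFolds = as.integer(nFolds),
      nPermutations = 0L, seed = as.integer(seed), folds = folds)
}

#' Permutation validation of a PLS-DA model
#'
#' Builds null distributions of R2Y and Q2 by refitting (and
#' cross-validating) the model after uniformly permuting the class labels,
#' and reports empirical p-values
#' \eqn{p = (1 + \#\{null \ge observed\}) / (1 + n_{perm})}.
#'
#' @inheritParams crossValidatedQ2
#' @param nPermutations number of label permutations (>= 20; default 999).
#' @return A \linkS4class{ValidationReport}.
#' @examples
#' X <- matrix(rnorm(200), 20)
#' X[1:10, 1:3] <- X[1:10, 1:3] + 3
#' permutationValidate(X, rep(c("a", "b"), each = 10),
#'                     nPermutations = 49, seed = 1)
#' @export
permutationValidate <- function(X, labels, nPermutations = 999L,
                                nComponents = 2L, nFolds = 8L,
                                scaling = c("center", "pareto", "uv"),
                                seed = 1L) {
  if (is(X, "BinnedDataset")) X <- intensityMatrix(X)
  X <- as.matrix(X)
  scaling <- match.arg(scaling)
  nPermutations <- as.integer(nPermutations)
  if (nPermutations < 20L) stop("nPermutations must be >= 20")
  if (nrow(X) < 4L)
    stop("too few samples for a meaningful permutation test ",
         "(fewer than 4 gives at most 2 distinct label assignments)")
  obs <- crossValidatedQ2(X, labels, nFolds = nFolds,
                          nComponents = nComponents, scaling = scaling,
                          seed = seed)
  permQ2 <- numeric(nPermutations); permR2Y <- numeric(nPermutations)
  for (i in seq_len(nPermutations)) {
    perm <- withSeed(childSeed(seed, i), sample(as.character(labels)))
    v <- crossValidatedQ2(X, perm, nFolds = nFolds,
                          nComponents = nComponents, scaling = scaling,
                          seed = childSeed(seed, i))
    permQ2[i] <- v@Q2; permR2Y[i] <- v@R2Y
  }
  new("ValidationReport", Q2 = obs@Q2, press = obs@press, R2Y = obs@R2Y,
      permQ2 = permQ2, permR2Y = permR2Y,
      pQ2 = (1 + sum(permQ2 >= obs@Q2)) / (1 + nPermutations),
      pR2Y = (1 + sum(permR2Y >= obs@R2Y)) / (1 + nPermutations),
      nFolds = as.integer(nFolds), nPermutations = nPermutations,
      seed = as.integer(seed), folds = obs@folds)
}

#' Fit an OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis for a
#' two-class problem: variation uncorrelated with the class coding is
#' peeled off into orthogonal components before a single predictive
#' component is fitted. Per orthogonal round, with \eqn{w \propto X'y}
#' (unit norm), \eqn{t = Xw}, \eqn{p = X't/t't}, the orthogonal weight is
#' \eqn{w_o \propto p - (w'p)w}; X is deflated by \eqn{t_o p_o'}. The
#' orthogonal scores are exactly uncorrelated with the class coding by
#' construction.
#'
#' @inheritParams fitPLSDA
#' @param nOrthogonal number of orthogonal components to extract (>= 0).
#' @return An \linkS4class{OplsModel}; per-variable correlation (\code{r})
#'   and covariance of the scaled variables with the centered class coding
#'   are stored for loading plots.
#' @examples
#' X <- matrix(rnorm(300), 30)
#' X[1:15, 1:2] <- X[1:15, 1:2] + 3
#' fitOPLSDA(X, rep(c("a", "b"), each = 15))
#' @export
fitOPLSDA <- function(X, labels, nOrthogonal = 1L,
                      scaling = c("center", "pareto", "uv")) {
  if (is(X, "BinnedDataset")) X <- intensityMatrix(X)
  X <- as.matrix(X)
  cod <- codeClasses(labels)
  if (length(cod$levels) != 2L)
    stop("OPLS-DA requires exactly 2 classes (got ",
         length(cod$levels), "); use fitPLSDA for multi-class problems")
  sc <- scaleColumns(X, match.arg(scaling))
  yMean <- mean(cod$Y[, 1L])
  y <- cod$Y[, 1L] - yMean
  Xs <- sc$X
  ssX0 <- ssq(Xs); ssY0 <- ssq(y)
  n <- nrow(Xs); p <- ncol(Xs)
  nOrthogonal <- as.integer(nOrthogonal)
  To <- matrix(0, n, nOrthogonal); Po <- matrix(0, p, nOrthogonal)
  Wo <- matrix(0, p, nOrthogonal)
  Xf <- Xs
  ssOrtho <- numeric(nOrthogonal)
  j <- 0L
  while (j < nOrthogonal) {
    w <- drop(crossprod(Xf, y)); w <- w / sqrt(sum(w * w))
    tt <- drop(Xf %*% w)
    pp <- drop(crossprod(Xf, tt)) / sum(tt * tt)
    wo <- pp - sum(w * pp) * w
    nwo <- sqrt(sum(wo * wo))
    if (nwo < 1e-10 * sqrt(sum(pp * pp)) || nwo == 0) {
      warning("no orthogonal variation left after ", j,
              " component(s); remaining orthogonal components are zero")
      break
    }
    wo <- wo / nwo
    to <- drop(Xf %*% wo)
    po <- drop(crossprod(Xf, to)) / sum(to * to)
    Xf <- Xf - tcrossprod(to, po)
    j <- j + 1L
    To[, j] <- to; Po[, j] <- po; Wo[, j] <- wo
    ssOrtho[j] <- ssq(tcrossprod(to, po))
  }
  w <- drop(crossprod(Xf, y)); w <- w / sqrt(sum(w * w))
  tp <- drop(Xf %*% w)
  pp <- drop(crossprod(Xf, tp)) / sum(tp * tp)
  cc <- sum(y * tp) / sum(tp * tp)
  ssPred <- ssq(tcrossprod(tp, pp))
  R2X <- c(predictive = ssPred / ssX0,
           setNames(ssOrtho / ssX0,
                    if (nOrthogonal > 0)
                      paste0("orthogonal", seq_len(nOrthogonal)) else
                      character()),
           residual = ssq(Xf - tcrossprod(tp, pp)) / ssX0)
  R2Y <- if (ssY0 > 0) 1 - ssq(y - tp * cc) / ssY0 else NA_real_
  sds <- colSds(Xs)
  constant <- sds < .Machine$double.eps^0.5
  r <- numeric(p); cv <- numeric(p)
  ok <- !constant & sd(y) > 0
  if (any(ok)) {
    cv[ok] <- drop(crossprod(Xs[, ok, drop = FALSE], y)) / (n - 1)
    r[ok] <- cv[ok] / (sds[ok] * sd(y))
  }
  new("OplsModel", predScores = tp, predLoadings = pp, predWeights = w,
      orthoScores = To, orthoLoadings = Po, orthoWeights = Wo,
      yWeight = cc, R2X = R2X, R2Y = R2Y, correlation = r,
      covariance = cv, zeroed = constant, scaling = sc$params,
      yMean = yMean, classLevels = cod$levels, labels = cod$labels)
}

#' Correlation-coefficient loading profile
#'
#' For every variable, the Pearson correlation \eqn{r} and the covariance
#' between its intensities and the binary class coding, as used to
#' color-code OPLS-DA loading plots by \eqn{|r|}. Variables inside
#' declared noise regions have covariance and \eqn{r} set to zero and are
#' flagged, as are constant columns.
#'
#' @param X numeric matrix (samples x variables) or
#'   \linkS4class{BinnedDataset}; raw or scaled (\eqn{r} is invariant,
#'   the covariance is on the supplied scale).
#' @param labels two-level class label per sample.
#' @param noiseRegions optional list of (lo, hi) ppm intervals whose
#'   variables are zeroed.
#' @param binCenters ppm positions of the columns; taken from the dataset
#'   when \code{X} is a \linkS4class{BinnedDataset}.
#' @return data.frame with columns \code{bin_center}, \code{covariance},
#'   \code{r}, \code{zeroed}.
#' @examples
#' X <- matrix(rnorm(100), 20)
#' y <- rep(c("a", "b"), each = 10)
#' head(correlationLoadings(X, y))
#' @export
correlationLoadings <- function(X, labels, noiseRegions = NULL,
                                binCenters = NULL) {
  if (is(X, "BinnedDataset")) {
    if (is.null(binCenters)) binCenters <- binCenters(X)
    X <- intensityMatrix(X)
  }
  X <- as.matrix(X)
  if (is.null(binCenters)) binCenters <- as.numeric(seq_len(ncol(X)))
  cod <- codeClasses(labels)
  if (length(cod$levels) != 2L)
    stop("correlation loadings require a binary class coding")
  y <- cod$Y[, 1L]
  n <- nrow(X)
  cv <- drop(crossprod(X, y - mean(y))) / (n - 1)
  sds <- colSds(X)
  constant <- sds < .Machine$double.eps^0.5
  r <- numeric(ncol(X))
  r[!constant] <- cv[!constant] / (sds[!constant] * sd(y))
  zeroed <- constant
  if (!is.null(noiseRegions)) {
    for (reg in noiseRegions) {
      inside <- binCenters >= reg[1L] & binCenters <= reg[2L]
      zeroed <- zeroed | inside
    }
  }
  cv[zeroed] <- 0; r[zeroed] <- 0
  data.frame(bin_center = binCenters, covariance = cv, r = r,
             zeroed = zeroed)
}

#' Principal components by NIPALS
#'
#' The PCA mode of the NIPALS algorithm (scores/loadings extracted one at
#' a time with deflation), used mainly to check the iterative machinery
#' against a spectral decomposition.
#'
#' @param X numeric matrix, samples in rows; columns are centered.
#' @param nComponents number of components.
#' @param tol relative convergence tolerance.
#' @param maxIter iteration cap per component.
#' @return list with \code{scores}, \code{loadings} (unit-norm columns)
#'   and \code{center}.
#' @export
nipalsPca <- function(X, nComponents = 2L, tol = 1e-12,
                      maxIter = 200000L) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  n <- nrow(Xc); p <- ncol(Xc)
  Tm <- matrix(0, n, nComponents); P <- matrix(0, p, nComponents)
  for (k in seq_len(nComponents)) {
    tt <- Xc[, which.max(colSds(Xc))]
    iter <- 0L
    repeat {
      pp <- drop(crossprod(Xc, tt)) / sum(tt * tt)
      pp <- pp / sqrt(sum(pp * pp))
      tNew <- drop(Xc %*% pp)
      if (sqrt(sum((tNew - tt)^2)) <= tol * sqrt(sum(tNew * tNew))) {
        tt <- tNew; break
      }
      tt <- tNew
      iter <- iter + 1L
      # the power iteration contracts at the component eigenvalue ratio,
      # so near-degenerate pairs need a long leash
      if (iter >= maxIter)
        stop("NIPALS PCA did not converge in component ", k)
    }
    Xc <- Xc - tcrossprod(tt, pp)
    Tm[, k] <- tt; P[, k] <- pp
  }
  list(scores = Tm, loadings = P, center = ctr)
}

#' Suggest a PLS-DA component count
#'
#' Adds components while the cross-validated Q2 improves by at least
#' \code{minGain} (a SIMCA-like stopping convention).
#'
#' @inheritParams crossValidatedQ2
#' @param maxComponents upper bound to consider.
#' @param minGain minimum Q2 improvement to accept another component
#'   (default 0.05).
#' @return list with \code{k} (suggested count) and \code{Q2} (per count).
#' @export
suggestComponents <- function(X, labels, maxComponents = 5L, nFolds = 8L,
                              scaling = c("center", "pareto", "uv"),
                              seed = 1L, minGain = 0.05) {
  if (is(X, "BinnedDataset")) X <- intensityMatrix(X)
  X <- as.matrix(X)
  scaling <- match.arg(scaling)
  maxComponents <- min(maxComponents, nrow(X) - 1L, ncol(X))
  q2 <- numeric(maxComponents)
  for (k in seq_len(maxComponents))
    q2[k] <- crossValidatedQ2(X, labels, nFolds = nFolds,
                              nComponents = k, scaling = scaling,
                              seed = seed)@Q2
  k <- 1L
  while (k < maxComponents && q2[k + 1L] - q2[k] >= minGain) k <- k + 1L
  list(k = k, Q2 = q2[seq_len(maxComponents)])
}
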