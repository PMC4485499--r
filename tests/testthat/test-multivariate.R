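test_that("column scaling obeys its contracts and inverts exactly", {
  set.seed(1)
  X <- matrix(rnorm(60, sd = 2), 12, 5)
  X[, 5L] <- 3  # constant column
  for (m in c("center", "pareto", "uv")) {
    s <- scaleColumns(X, m)
    expect_lt(max(abs(colMeans(s$X))), 1e-10)
    expect_lt(max(abs(unscaleColumns(s$X, s$params) - X)), 1e-10)
    expect_true(s$params@constant[5L])
    expect_equal(s$params@scale[5L], 1)
  }
  su <- scaleColumns(X[, 1:4], "uv")
  expect_equal(apply(su$X, 2L, sd), rep(1, 4), ignore_attr = TRUE)
  sp <- scaleColumns(X[, 1:4], "pareto")
  expect_equal(sp$params@scale, sqrt(apply(X[, 1:4], 2L, sd)),
               ignore_attr = TRUE)
})

test_that("PLS-DA separates a planted signal on the first component", {
  d <- plantedMatrix(nPerClass = 10, p = 10, effectCols = 1L, shift = 5,
                     seed = 2)
  m <- fitPLSDA(d$X, d$labels, nComponents = 2)
  t1a <- m@scores[d$labels == "a", 1L]
  t1b <- m@scores[d$labels == "b", 1L]
  expect_true(max(t1a) < min(t1b) || max(t1b) < min(t1a))
  expect_equal(which.max(abs(m@weights[, 1L])), 1L)
  expect_true(m@R2X >= 0 && m@R2X <= 1)
  expect_true(m@R2Y >= 0 && m@R2Y <= 1)
})

test_that("first PLS weight equals the single-y closed form", {
  set.seed(7)
  X <- matrix(rnorm(15 * 8), 15, 8)
  labels <- rep(c("a", "b"), c(7, 8))
  m <- fitPLSDA(X, labels, nComponents = 1)
  y <- as.numeric(factor(labels)) - 1
  w <- drop(crossprod(scale(X, scale = FALSE), y - mean(y)))
  w <- w / sqrt(sum(w^2))
  expect_lt(max(abs(m@weights[, 1L] - w)), 1e-8)
})

test_that("multi-class PLS-DA uses one-hot coding with k components", {
  set.seed(9)
  X <- matrix(rnorm(30 * 12), 30, 12)
  X[1:10, 1] <- X[1:10, 1] + 4
  X[11:20, 2] <- X[11:20, 2] + 4
  labels <- rep(c("ctl", "gml", "gml-sm"), each = 10L)
  m <- fitPLSDA(X, labels, nComponents = 3)
  expect_equal(ncol(m@scores), 3L)
  expect_equal(nrow(m@yWeights), 3L)
  expect_setequal(m@classLevels, unique(labels))
  expect_error(fitPLSDA(X, labels, nComponents = 40), "rank bound")
})

test_that("weights are unit norm and scores mutually orthogonal", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(20 * 15), 20, 15)
    labels <- rep(c("a", "b"), each = 10L)
    m <- fitPLSDA(X, labels, nComponents = 4)
    expect_equal(sqrt(colSums(m@weights^2)), rep(1, 4),
                 tolerance = 1e-8, ignore_attr = TRUE)
    G <- crossprod(m@scores)
    offDiag <- G - diag(diag(G))
    expect_lt(max(abs(offDiag)) / max(diag(G)), 1e-8)
  }
})

test_that("NIPALS PCA matches the spectral-decomposition oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(rnorm(40), 8, 5)
    fit <- nipalsPca(X, nComponents = 3)
    sv <- svd(scale(X, scale = FALSE))
    for (k in 1:3) {
      cosine <- abs(sum(fit$loadings[, k] * sv$v[, k]))
      expect_gt(cosine, 1 - 1e-8)
    }
  }
})

test_that("Q2 is high for planted effects and low for noise", {
  d <- plantedMatrix(nPerClass = 20, p = 30, effectCols = 1:5, shift = 5,
                     seed = 3)
  v <- crossValidatedQ2(d$X, d$labels, nFolds = 8, nComponents = 2,
                        seed = 1)
  expect_gt(v@Q2, 0.9)
  expect_lte(v@Q2, 1)

  nullQ2 <- vapply(1:20, function(s) {
    set.seed(s + 500)
    Xn <- matrix(rnorm(40 * 30), 40, 30)
    crossValidatedQ2(Xn, rep(c("a", "b"), each = 20L), nFolds = 8,
                     nComponents = 2, seed = s)@Q2
  }, numeric(1L))
  expect_true(all(nullQ2 <= 0.1))
  expect_lt(median(nullQ2), 0)
})

test_that("Q2 never exceeds R2Y on matched data and settings", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(24 * 10), 24, 10)
    if (seed %% 2) X[1:12, 1:2] <- X[1:12, 1:2] + seed / 2
    labels <- rep(c("a", "b"), each = 12L)
    v <- crossValidatedQ2(X, labels, nFolds = 6, nComponents = 2,
                          seed = seed)
    expect_lte(v@Q2, v@R2Y)
  }
})

test_that("degenerate fold layouts are rejected with guidance", {
  X <- matrix(rnorm(7 * 5), 7, 5)
  labels <- c(rep("a", 6), "b")
  expect_warning(
    expect_error(crossValidatedQ2(X, labels, nFolds = 2, seed = 1),
                 "single class"),
    "stratification relaxed")
})

test_that("permutation testing flags planted effects and guards inputs", {
  d <- plantedMatrix(nPerClass = 12, p = 15, effectCols = 1:4, shift = 4,
                     seed = 5)
  v <- permutationValidate(d$X, d$labels, nPermutations = 199,
                           nComponents = 2, nFolds = 8, seed = 1)
  expect_lte(v@pQ2, 0.01)
  expect_lte(v@pR2Y, 0.01)
  expect_length(v@permQ2, 199L)
  expect_true(all(v@pQ2 > 0 & v@pQ2 <= 1))

  expect_error(permutationValidate(d$X, d$labels, nPermutations = 5),
               ">= 20")
  expect_error(permutationValidate(matrix(rnorm(4), 2, 2), c("a", "b"),
                                   nPermutations = 20),
               "too few samples")
})

test_that("OPLS leaves nothing orthogonal when X is pure class signal", {
  set.seed(11)
  y <- rep(c(-0.5, 0.5), each = 10L)
  p <- rnorm(12)
  X <- outer(y, p)
  expect_warning(m <- fitOPLSDA(X, rep(c("a", "b"), each = 10L),
                                nOrthogonal = 1),
                 "no orthogonal variation")
  expect_lt(sum(m@R2X[grepl("orthogonal", names(m@R2X))]), 1e-10)
})

test_that("OPLS recovers a constructed predictive/orthogonal split", {
  set.seed(12)
  n <- 30
  y <- rep(c(-0.5, 0.5), each = n / 2)
  to <- rnorm(n)
  to <- to - mean(to) - y * sum(to * y) / sum(y * y)  # orthogonal to y
  p <- rnorm(20); po <- rnorm(20)
  X <- outer(y, p) + outer(to, po)
  m <- fitOPLSDA(X, rep(c("a", "b"), each = n / 2), nOrthogonal = 1)
  cosine <- abs(sum(m@predLoadings * p)) /
    sqrt(sum(m@predLoadings^2) * sum(p^2))
  expect_gt(cosine, 0.999)
  expect_lt(abs(abs(cor(m@predScores, y)) - 1), 1e-6)
  expect_lt(abs(cor(m@orthoScores[, 1L], y)), 1e-6)
  expect_equal(sum(m@R2X), 1, tolerance = 1e-6)
})

test_that("orthogonal scores are uncorrelated with the class on any fit", {
  for (seed in 1:5) {
    set.seed(seed + 30)
    X <- matrix(rnorm(26 * 18), 26, 18)
    X[1:13, 1:3] <- X[1:13, 1:3] + 2
    labels <- rep(c("a", "b"), each = 13L)
    m <- fitOPLSDA(X, labels, nOrthogonal = 2)
    y <- as.numeric(factor(labels)) - 1
    for (j in seq_len(ncol(m@orthoScores)))
      expect_lt(abs(cor(m@orthoScores[, j], y)), 1e-6)
    expect_equal(sum(m@R2X), 1, tolerance = 1e-6)
  }
})

test_that("OPLS with no orthogonal rounds reduces to first-component PLS", {
  d <- plantedMatrix(nPerClass = 8, p = 12, effectCols = 1:2, shift = 3,
                     seed = 6)
  m0 <- fitOPLSDA(d$X, d$labels, nOrthogonal = 0)
  pls <- fitPLSDA(d$X, d$labels, nComponents = 1)
  expect_equal(m0@predScores, pls@scores[, 1L], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(m0@predWeights, pls@weights[, 1L], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(fitOPLSDA(d$X, rep(c("a", "b", "c"), length.out = 16)),
               "fitPLSDA")
})

test_that("correlation loadings code class association and zero noise", {
  set.seed(13)
  n <- 20
  labels <- rep(c("a", "b"), each = n / 2)
  y <- as.numeric(factor(labels)) - 1
  X <- matrix(rnorm(n * 6), n, 6)
  X[, 1L] <- y          # exact class column
  X[, 2L] <- 4          # constant
  X[, 3L] <- y + rnorm(n, sd = 0.1)  # strong but inside a noise region
  cl <- correlationLoadings(X, labels,
                            noiseRegions = list(c(0.25, 0.35)),
                            binCenters = (1:6) / 10)
  expect_equal(cl$r[1L], 1)
  expect_equal(cl$r[2L], 0)
  expect_true(cl$zeroed[2L])
  expect_equal(cl$r[3L], 0)
  expect_equal(cl$covariance[3L], 0)
  expect_true(cl$zeroed[3L])
  expect_false(cl$zeroed[1L])
})

test_that("planted discriminant bins dominate the |r| ranking", {
  set.seed(14)
  n <- 30; p <- 200
  truthBins <- sample(p, 20)
  X <- matrix(rnorm(n * p), n, p)
  labels <- rep(c("a", "b"), each = 15L)
  X[labels == "b", truthBins] <- X[labels == "b", truthBins] + 3
  cl <- correlationLoadings(X, labels)
  top <- order(abs(cl$r), decreasing = TRUE)[1:40]
  expect_gte(length(intersect(truthBins, top)), 18L)
})

test_that("suggestComponents stops when Q2 stops improving", {
  d <- plantedMatrix(nPerClass = 12, p = 20, effectCols = 1:3, shift = 4,
                     seed = 15)
  s <- suggestComponents(d$X, d$labels, maxComponents = 4, seed = 1)
  expect_gte(s$k, 1L)
  expect_length(s$Q2, 4L)
  expect_gt(s$Q2[s$k], 0.5)
})
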