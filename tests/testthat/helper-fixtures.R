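# Shared fixtures: all synthetic, generated in code at test time.

# Two-class matrix with a mean shift planted in selected columns.
plantedMatrix <- function(nPerClass = 10, p = 20, effectCols = 1:3,
                          shift = 3, noiseSd = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * nPerClass * p, sd = noiseSd), 2 * nPerClass, p)
  X[seq_len(nPerClass), effectCols] <-
    X[seq_len(nPerClass), effectCols] + shift
  list(X = X, labels = rep(c("a", "b"), each = nPerClass))
}

# Independent loop-based oracle for the unweighted-cell-means two-way
# decomposition; deliberately naive.
bruteForceDecompose <- function(X, fa, fb) {
  fa <- as.character(fa); fb <- as.character(fb)
  la <- sort(unique(fa)); lb <- sort(unique(fb))
  p <- ncol(X); n <- nrow(X)
  cm <- array(NA_real_, c(length(la), length(lb), p))
  for (i in seq_along(la)) for (j in seq_along(lb)) {
    rows <- which(fa == la[i] & fb == lb[j])
    for (k in seq_len(p)) cm[i, j, k] <- mean(X[rows, k])
  }
  grand <- numeric(p)
  for (k in seq_len(p)) grand[k] <- mean(cm[, , k])
  A <- B <- AB <- R <- matrix(0, n, p)
  for (r in seq_len(n)) {
    i <- match(fa[r], la); j <- match(fb[r], lb)
    for (k in seq_len(p)) {
      ai <- mean(cm[i, , k]) - grand[k]
      bj <- mean(cm[, j, k]) - grand[k]
      A[r, k] <- ai
      B[r, k] <- bj
      AB[r, k] <- cm[i, j, k] - grand[k] - ai - bj
      R[r, k] <- X[r, k] - cm[i, j, k]
    }
  }
  list(grand = grand, A = A, B = B, AB = AB, residual = R)
}

# Random unbalanced two-factor dataset (matrix + factor labels).
randomTwoWay <- function(seed, p = 6, counts = NULL) {
  set.seed(seed)
  if (is.null(counts)) {
    a <- sample(2:3, 1); b <- sample(2:3, 1)
    counts <- matrix(sample(1:5, a * b, replace = TRUE), a, b)
  }
  fa <- character(); fb <- character()
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    fa <- c(fa, rep(paste0("a", i), counts[i, j]))
    fb <- c(fb, rep(paste0("b", j), counts[i, j]))
  }
  list(X = matrix(rnorm(length(fa) * p), length(fa), p), fa = fa, fb = fb)
}

# 2x2 toy designs used throughout (one sample per cell, one variable).
toyDesign <- function(values) {
  list(X = matrix(values, 4, 1),
       md = data.frame(disease = c("a1", "a1", "a2", "a2"),
                       ea = c("b1", "b2", "b1", "b2"),
                       stringsAsFactors = FALSE))
}

# Tiny BinnedDataset wrapper.
makeDataset <- function(X, centers = NULL, width = NULL, md = NULL) {
  if (is.null(centers)) centers <- seq_len(ncol(X)) * 0.1 + 0.05
  if (is.null(width)) width <- 0.1
  if (is.null(md))
    md <- data.frame(sample_id = paste0("S", seq_len(nrow(X))))
  BinnedDataset(X, centers, width, md)
}
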