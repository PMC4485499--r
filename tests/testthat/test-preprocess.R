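test_that("peak referencing shifts the apex onto the target", {
  grid <- seq(1.0, 2.0, by = 0.002)
  peak <- function(center) 1 / ((grid - center)^2 + 1e-4)
  sp <- Spectrum(grid, peak(1.340), "S1")
  res <- referenceToPeak(sp, 1.33, c(1.2, 1.5))
  expect_equal(res$shift, -0.010)
  expect_equal(res$spectrum@ppm[which.max(res$spectrum@intensity)], 1.33)

  already <- Spectrum(grid, peak(1.330), "S2")
  res0 <- referenceToPeak(already, 1.33, c(1.2, 1.5))
  expect_equal(res0$shift, 0)
  expect_identical(res0$spectrum@ppm, already@ppm)

  # two equal maxima: the lower-ppm one wins
  y <- numeric(length(grid)); y[c(100L, 300L)] <- 5
  tie <- referenceToPeak(Spectrum(grid, y, "S3"), 1.33, c(1.0, 2.0))
  expect_equal(tie$shift, 1.33 - grid[100L])

  expect_error(referenceToPeak(sp, 1.33, c(5, 6)), "does not overlap")
})

test_that("binning yields the documented bin counts", {
  grid <- seq(0.4, 10.1, by = 0.002)
  sp <- Spectrum(grid, runif(length(grid)), "U1")
  urine <- binSpectra(list(sp), binWidth = 0.002, ppmRange = c(0.5, 10.0))
  expect_equal(nrow(urine), 4750L)
  serum <- binSpectra(list(sp), binWidth = 0.002, ppmRange = c(0.5, 9.0))
  expect_equal(nrow(serum), 4250L)
})

test_that("binning sums point intensities and conserves total signal", {
  # one point exactly per bin, constant intensity
  centers <- 0.5 + (1:100 - 0.5) * 0.01
  sp <- Spectrum(centers, rep(1, 100), "S1")
  bd <- binSpectra(list(sp), binWidth = 0.01, ppmRange = c(0.5, 1.5))
  expect_true(all(intensityMatrix(bd) == 1))

  set.seed(3)
  grid <- seq(0, 11, by = 0.0007)
  y <- runif(length(grid))
  sp2 <- Spectrum(grid, y, "S2")
  bd2 <- binSpectra(list(sp2), binWidth = 0.013, ppmRange = c(0.5, 10.0))
  inRange <- grid >= 0.5 & grid <= 10.0
  expect_equal(sum(intensityMatrix(bd2)), sum(y[inRange]), tolerance = 1e-12)

  short <- Spectrum(seq(1, 2, by = 0.01), rep(1, 101), "tooShort")
  expect_error(binSpectra(list(short), binWidth = 0.01,
                          ppmRange = c(0.5, 10.0)), "tooShort")
})

test_that("exclusion drops exactly the bins inside the regions", {
  X <- matrix(runif(30), 3, 10)
  bd <- makeDataset(X, centers = (1:10) / 10, width = 0.1)
  expect_identical(excludeRegions(bd, list()), bd)

  # one region covering exactly 3 of 10 centers
  out <- excludeRegions(bd, list(c(0.35, 0.65)))
  expect_equal(nrow(out), 7L)
  expect_equal(binCenters(out), c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9, 1.0))
  expect_equal(nrow(excludedRegions(out)), 1L)

  expect_error(excludeRegions(bd, list(c(0, 2))), "every bin")

  sim <- simulateDataset(generateDesign(biofluid = "urine"),
                         binWidth = 0.05, seed = 1)
  ur <- excludeRegions(sim$dataset, list(c(4.5, 6.0)))
  expect_false(any(binCenters(ur) >= 4.5 & binCenters(ur) <= 6.0))
})

test_that("PQN reproduces the hand-worked quotient example", {
  X <- rbind(A = c(1, 1, 1, 1), B = c(2, 1, 1, 1))
  bd <- makeDataset(X, md = data.frame(sample_id = c("A", "B")))
  res <- pqnNormalize(bd, referenceMethod = "index", referenceIndex = 1L)
  out <- intensityMatrix(res$dataset)
  expect_equal(unname(out["A", ]), c(25, 25, 25, 25))
  expect_equal(unname(out["B", ]), c(50, 25, 25, 25))
  # total divisors: A = 4/100 * 1, B = 5/100 * 0.8
  expect_equal(unname(res$quotients), c(0.04, 0.04))
})

test_that("PQN leaves identical rows alone with unit quotients", {
  row <- c(40, 30, 20, 10)  # sums to 100 so the integral step is a no-op
  X <- rbind(row, row, row)
  bd <- makeDataset(X)
  res <- pqnNormalize(bd)
  expect_equal(unname(res$quotients), rep(1, 3))
  expect_equal(unname(intensityMatrix(res$dataset)), unname(X))
})

test_that("PQN is idempotent and scale-equivariant", {
  set.seed(8)
  X <- matrix(rexp(200, rate = 0.5), 10, 20)
  bd <- makeDataset(X, centers = (1:20) / 10, width = 0.1)
  first <- pqnNormalize(bd)
  second <- pqnNormalize(first$dataset)
  expect_lt(max(abs(intensityMatrix(second$dataset) -
                    intensityMatrix(first$dataset))), 1e-9)
  expect_lt(max(abs(second$quotients - 1)), 1e-9)

  X2 <- X; X2[3L, ] <- 7 * X2[3L, ]
  res2 <- pqnNormalize(makeDataset(X2, centers = (1:20) / 10, width = 0.1))
  expect_equal(intensityMatrix(res2$dataset)[3L, ],
               intensityMatrix(first$dataset)[3L, ], tolerance = 1e-12)
})

test_that("PQN recovers planted dilution factors", {
  set.seed(21)
  p <- 200; n <- 30
  profile <- runif(p, 0.05, 1)
  dil <- exp(rnorm(n, 0, 0.3))
  X <- matrix(0, n, p)
  for (i in seq_len(n)) {
    row <- dil[i] * profile
    perturb <- sample(p, size = p %/% 10)   # <= 10% of bins
    row[perturb] <- row[perturb] * runif(length(perturb), 0.5, 1.5)
    X[i, ] <- row
  }
  res <- pqnNormalize(makeDataset(X, centers = (1:p) / 20, width = 0.05))
  q <- res$quotients / median(res$quotients)
  d <- dil / median(dil)
  expect_gt(cor(q, d), 0.95)
  expect_lt(median(abs(q - d) / d), 0.05)
})

test_that("PQN input contracts are enforced", {
  X <- rbind(c(1, 2), c(0, 0))
  expect_error(pqnNormalize(makeDataset(X)), "all-zero")
  expect_error(pqnNormalize(makeDataset(matrix(1, 1, 3))), "two samples")
  bd <- makeDataset(matrix(runif(12), 3, 4),
                    md = data.frame(sample_id = c("a", "b", "c"),
                                    disease = c("x", "x", "y")))
  expect_error(pqnNormalize(bd, referenceMethod = "group"),
               "referenceGroup")
  expect_silent(pqnNormalize(bd, referenceMethod = "group",
                             referenceGroup = "x"))
})
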