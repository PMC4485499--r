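test_that("design expansion yields one record per animal with stable ids", {
  d <- generateDesign()
  expect_equal(nrow(d), 46L)
  counts <- as.data.frame(table(d$disease, d$ea))
  expect_equal(sort(counts$Freq), c(7L, 7L, 8L, 8L, 8L, 8L))
  expect_false(anyDuplicated(d$sample_id) > 0)
  expect_identical(d, generateDesign())

  mini <- generateDesign(data.frame(disease = c("control", "GML"),
                                    ea = "none", n = 2L))
  expect_equal(nrow(mini), 4L)
  expect_equal(as.integer(table(mini$disease)), c(2L, 2L))

  expect_error(generateDesign(data.frame(disease = "control", ea = "none",
                                         n = 0L)), "empty design")
  expect_error(generateDesign(data.frame(disease = "healthy", ea = "none",
                                         n = 2L)), "unknown disease")
})

test_that("metabolite library covers the spectral range with multiplets", {
  lib <- defaultMetaboliteLibrary()
  expect_gte(length(lib), 10L)
  pos <- unlist(lapply(lib, `[[`, "positions"))
  expect_true(all(pos >= 0.5 & pos <= 10.0))
  expect_true(any(abs(lib$lactate$positions - 1.33) < 1e-12))
  expect_true(any(vapply(lib, function(t) length(t$positions) > 1L,
                         logical(1L))))
  expect_identical(lib, defaultMetaboliteLibrary())
})

test_that("rendered templates are nonnegative and peak at stated positions", {
  lib <- defaultMetaboliteLibrary()
  grid <- seq(0.4, 10.1, by = 0.001)
  for (tm in lib) {
    y <- renderTemplate(tm, grid)
    expect_true(all(y >= 0))
    for (k in seq_along(tm$positions)) {
      win <- which(abs(grid - tm$positions[k]) <= 2 * tm$linewidth)
      apex <- grid[win[which.max(y[win])]]
      expect_lte(abs(apex - tm$positions[k]), 0.001 + 1e-12)
    }
  }
})

test_that("degenerate simulation collapses to identical rows", {
  lib <- defaultMetaboliteLibrary()
  sp <- effectSpec(baselines = c(lactate = 5, acetate = 2))
  sim <- simulateDataset(generateDesign(), lib, sp, binWidth = 0.05,
                         seed = 4)
  X <- intensityMatrix(sim$dataset)
  expect_lt(max(abs(sweep(X, 2L, X[1L, ]))), 1e-12)
  expect_length(sim$truth@affectedBins$disease, 0L)
})

test_that("planted fractional change appears as the group-mean ratio", {
  lib <- list(a = peakTemplate("a", 2.0, 1), b = peakTemplate("b", 6.0, 1))
  sp <- effectSpec(baselines = c(a = 4, b = 3),
                   diseaseEffect = c(a = 0.5), noiseSd = 0.01)
  des <- generateDesign(data.frame(disease = c("control", "GML"),
                                   ea = "none", n = c(20L, 20L)))
  sim <- simulateDataset(des, lib, sp, binWidth = 0.01, seed = 2)
  tb <- sim$truth@affectedBins$disease
  expect_gt(length(tb), 0L)
  X <- intensityMatrix(sim$dataset)
  g <- sampleData(sim$dataset)$disease
  ratio <- colMeans(X[g == "GML", tb, drop = FALSE]) /
    colMeans(X[g == "control", tb, drop = FALSE])
  expect_true(all(abs(ratio - 1.5) < 0.03))
})

test_that("simulation is bit-reproducible given the seed", {
  d <- generateDesign()
  s1 <- simulateDataset(d, binWidth = 0.05, seed = 9)
  s2 <- simulateDataset(d, binWidth = 0.05, seed = 9)
  expect_identical(intensityMatrix(s1$dataset),
                   intensityMatrix(s2$dataset))
  expect_identical(s1$truth@dilutionFactors, s2$truth@dilutionFactors)
  s3 <- simulateDataset(d, binWidth = 0.05, seed = 10)
  expect_false(identical(intensityMatrix(s1$dataset),
                         intensityMatrix(s3$dataset)))
})

test_that("noise-free samples equal dilution times their cell profile", {
  lib <- defaultMetaboliteLibrary()
  sp <- effectSpec(baselines = defaultEffectSpec()$baselines,
                   diseaseEffect = c(lactate = -0.3),
                   dilutionSd = 0.4)
  sim <- simulateDataset(generateDesign(), lib, sp, binWidth = 0.05,
                         seed = 5)
  X <- intensityMatrix(sim$dataset)
  d <- sim$truth@dilutionFactors
  md <- sampleData(sim$dataset)
  cell <- paste(md$disease, md$ea)
  undiluted <- X / d
  for (cl in unique(cell)) {
    rows <- which(cell == cl)
    ref <- undiluted[rows[1L], ]
    for (r in rows[-1L])
      expect_lt(max(abs(undiluted[r, ] - ref)), 1e-10)
  }
})

test_that("truth flags exactly the bins carrying a generative effect", {
  lib <- list(a = peakTemplate("a", 2.0, 1, linewidth = 0.01))
  sp <- effectSpec(baselines = c(a = 3), diseaseEffect = c(a = 0.5))
  des <- generateDesign(data.frame(disease = c("control", "GML"),
                                   ea = "none", n = c(2L, 2L)))
  sim <- simulateDataset(des, lib, sp, binWidth = 0.01, seed = 1)
  bc <- binCenters(sim$dataset)
  curve <- renderTemplate(lib$a, bc)
  expect_identical(sim$truth@affectedBins$disease,
                   which(curve >= 0.2))
  X <- intensityMatrix(sim$dataset)
  diff <- abs(X[3L, ] - X[1L, ])  # GML minus control, zero noise
  expect_true(all(diff[sim$truth@affectedBins$disease] > 0))
})

test_that("impossible effect composition is rejected naming the metabolite", {
  lib <- list(a = peakTemplate("a", 2.0, 1))
  sp <- effectSpec(baselines = c(a = 1), diseaseEffect = c(a = -1.2))
  des <- generateDesign(data.frame(disease = c("control", "GML"),
                                   ea = "none", n = c(2L, 2L)))
  expect_error(simulateDataset(des, lib, sp, binWidth = 0.1, seed = 1),
               "metabolite 'a'")
})

test_that("generator variance fractions agree with an analytic target", {
  # disease-only effects: the decomposition's disease percentage should
  # approach SS_disease(noiseless) / (SS_disease + n p sigma^2)
  lib <- defaultMetaboliteLibrary()
  base <- defaultEffectSpec()
  spec0 <- effectSpec(baselines = base$baselines,
                      diseaseEffect = base$diseaseEffect)
  d <- generateDesign()
  clean <- simulateDataset(d, lib, spec0, binWidth = 0.04, seed = 1)
  ssA0 <- sumSquares(decomposeTwoWay(clean$dataset))[["disease"]]
  sigma <- 0.05
  n <- nrow(intensityMatrix(clean$dataset))
  p <- ncol(intensityMatrix(clean$dataset))
  target <- 100 * ssA0 / (ssA0 + n * p * sigma^2)
  spec1 <- effectSpec(baselines = base$baselines,
                      diseaseEffect = base$diseaseEffect, noiseSd = sigma)
  pct <- vapply(1:20, function(s) {
    sim <- simulateDataset(d, lib, spec1, binWidth = 0.04, seed = s)
    vt <- varianceTable(decomposeTwoWay(sim$dataset))
    vt$percentage[vt$component == "disease"]
  }, numeric(1L))
  expect_lt(abs(mean(pct) - target), 5)
})
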