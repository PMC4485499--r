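#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats median sd cor cov var pt quantile rnorm runif setNames
#' @importFrom stats predict
#' @importFrom utils read.csv write.csv head
NULL

#' Spectrum: a single 1D NMR spectrum
#'
#' A one-dimensional \eqn{^1}H NMR spectrum after phasing and baseline
#' correction: a strictly increasing chemical-shift axis (ppm) with one real
#' intensity per point.
#'
#' @slot ppm numeric, strictly increasing chemical shifts in ppm.
#' @slot intensity numeric, same length as \code{ppm}.
#' @slot sampleId single character identifier.
#' @export
setClass("Spectrum",
  slots = c(ppm = "numeric", intensity = "numeric", sampleId = "character"))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@ppm) != length(object@intensity))
    msg <- c(msg, "ppm and intensity must have equal length")
  if (anyNA(object@ppm) || anyNA(object@intensity))
    msg <- c(msg, "ppm/intensity must not contain missing values")
  if (length(object@ppm) > 1L && any(diff(object@ppm) <= 0))
    msg <- c(msg, "ppm must be strictly increasing")
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' @param ppm strictly increasing numeric vector of chemical shifts (ppm).
#' @param intensity numeric vector of intensities, same length as \code{ppm}.
#' @param sampleId sample identifier.
#' @return A \linkS4class{Spectrum}.
#' @examples
#' sp <- Spectrum(seq(0, 10, by = 0.01), rnorm(1001), "S1")
#' @export
Spectrum <- function(ppm, intensity, sampleId = "sample") {
  new("Spectrum", ppm = as.numeric(ppm), intensity = as.numeric(intensity),
      sampleId = as.character(sampleId))
}

#' BinnedDataset: sample-by-bin spectral intensity matrix
#'
#' The pipeline's central exchange object: a
#' \linkS4class{SummarizedExperiment} whose single assay holds binned
#' intensities (bins in rows, samples in columns), with bin centers in
#' \code{rowData(x)$bin_center}, per-sample factor metadata in
#' \code{colData}, the constant bin width, and a record of the ppm regions
#' already excluded (water/urea windows).
#'
#' @slot binWidth single positive numeric, bin width in ppm.
#' @slot excludedRegions two-column numeric matrix of (lo, hi) ppm intervals
#'   whose bins have been removed.
#' @export
setClass("BinnedDataset",
  contains = "SummarizedExperiment",
  slots = c(binWidth = "numeric", excludedRegions = "matrix"))

setValidity("BinnedDataset", function(object) {
  msg <- character()
  if (length(object@binWidth) != 1L || !is.finite(object@binWidth) ||
      object@binWidth <= 0)
    msg <- c(msg, "binWidth must be a single positive number")
  bc <- SummarizedExperiment::rowData(object)$bin_center
  if (is.null(bc))
    msg <- c(msg, "rowData must contain a bin_center column")
  else {
    if (length(bc) > 1L && any(diff(bc) <= 0))
      msg <- c(msg, "bin centers must be strictly increasing")
    er <- object@excludedRegions
    if (ncol(er) != 2L)
      msg <- c(msg, "excludedRegions must have two columns (lo, hi)")
    else if (nrow(er) > 0L) {
      inside <- vapply(seq_len(nrow(er)), function(i)
        any(bc >= er[i, 1L] & bc <= er[i, 2L]), logical(1L))
      if (any(inside))
        msg <- c(msg, "no bin center may lie inside an excluded region")
    }
  }
  m <- SummarizedExperiment::assay(object)
  if (anyNA(m)) msg <- c(msg, "intensity matrix must not contain NA")
  ids <- colnames(object)
  if (anyDuplicated(ids)) msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a BinnedDataset
#'
#' @param intensities numeric matrix, samples in rows and bins in columns
#'   (the user-facing orientation; stored transposed in the assay).
#' @param binCenters strictly increasing numeric vector of bin-center ppm
#'   values, one per column of \code{intensities}.
#' @param binWidth single positive bin width in ppm.
#' @param metadata data.frame of per-sample metadata with a
#'   \code{sample_id} column (typically also \code{disease}, \code{ea},
#'   \code{biofluid}), one row per row of \code{intensities}.
#' @param excludedRegions optional two-column matrix of already removed
#'   (lo, hi) ppm intervals.
#' @return A \linkS4class{BinnedDataset}.
#' @examples
#' m <- matrix(runif(20), nrow = 4)
#' md <- data.frame(sample_id = paste0("S", 1:4))
#' bd <- BinnedDataset(m, binCenters = seq(1, 1.8, by = 0.2) + 0.1,
#'                     binWidth = 0.2, metadata = md)
#' @export
BinnedDataset <- function(intensities, binCenters, binWidth, metadata,
                          excludedRegions = NULL) {
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != nrow(metadata))
    stop("metadata must have one row per sample row of the matrix")
  if (ncol(intensities) != length(binCenters))
    stop("binCenters length must equal the number of matrix columns")
  if (is.null(metadata$sample_id))
    stop("metadata must contain a sample_id column")
  if (is.null(excludedRegions))
    excludedRegions <- matrix(numeric(0), ncol = 2L,
                              dimnames = list(NULL, c("lo", "hi")))
  excludedRegions <- as.matrix(excludedRegions)
  assay <- t(intensities)
  rownames(assay) <- formatBinNames(binCenters)
  colnames(assay) <- as.character(metadata$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = assay),
    rowData = S4Vectors::DataFrame(bin_center = as.numeric(binCenters)),
    colData = S4Vectors::DataFrame(metadata,
                                   row.names = as.character(metadata$sample_id)))
  new("BinnedDataset", se, binWidth = as.numeric(binWidth),
      excludedRegions = excludedRegions)
}

formatBinNames <- function(binCenters) sprintf("%.4f", binCenters)

#' AnovaDecomposition: two-way effect-matrix decomposition
#'
#' Result of decomposing a sample-by-bin matrix X under a two-factor crossed
#' design into \deqn{X = 1\mu' + X_A + X_B + X_{AB} + E,} where the effect
#' submatrices are cell-constant (identical rows within a factor level or
#' cell) and E is the residual. Effects use the unweighted cell-means
#' parameterization so unbalanced groups are treated symmetrically.
#'
#' @slot grandMean numeric length-p row of unweighted cell-mean averages.
#' @slot effects named list of three n-by-p matrices: one per main factor
#'   (named by the factor) plus \code{"interaction"}.
#' @slot residual n-by-p residual matrix.
#' @slot factorNames character(2): names of factors A and B.
#' @slot factors data.frame with the two factor columns, one row per sample.
#' @slot sumSquares named numeric: sum of squared entries per component
#'   (two factors, interaction, residual).
#' @slot binCenters numeric bin centers for the p columns.
#' @slot sampleIds character sample identifiers for the n rows.
#' @export
setClass("AnovaDecomposition",
  slots = c(grandMean = "numeric", effects = "list", residual = "matrix",
            factorNames = "character", factors = "data.frame",
            sumSquares = "numeric", binCenters = "numeric",
            sampleIds = "character"))

#' ScalingParams: column scaling used by projection models
#'
#' @slot method one of \code{"center"}, \code{"pareto"}, \code{"uv"}.
#' @slot center column means subtracted.
#' @slot scale column divisors applied after centering (1 under
#'   \code{"center"}; constant columns always get divisor 1 and are flagged).
#' @slot constant logical flag per column: TRUE where the column had zero
#'   variance.
#' @export
setClass("ScalingParams",
  slots = c(method = "character", center = "numeric", scale = "numeric",
            constant = "logical"))

#' PlsModel: NIPALS PLS-DA fit
#'
#' @slot scores n-by-k score matrix T.
#' @slot loadings p-by-k X-loading matrix P.
#' @slot weights p-by-k weight matrix W (unit-norm columns).
#' @slot yWeights q-by-k Y-weight matrix C.
#' @slot nComponents number of components k.
#' @slot R2X,R2Y cumulative explained fractions of (scaled) X and of the
#'   centered class coding.
#' @slot scaling the \linkS4class{ScalingParams} fitted on X.
#' @slot yMeans column means of the class coding (subtracted before fitting).
#' @slot classLevels class labels in coding order.
#' @slot labels per-sample class labels.
#' @export
setClass("PlsModel",
  slots = c(scores = "matrix", loadings = "matrix", weights = "matrix",
            yWeights = "matrix", nComponents = "integer",
            R2X = "numeric", R2Y = "numeric", scaling = "ScalingParams",
            yMeans = "numeric", classLevels = "character",
            labels = "character"))

#' OplsModel: OPLS-DA fit with predictive/orthogonal separation
#'
#' @slot predScores,predLoadings,predWeights the single predictive
#'   component (t_p, p_p, w_p).
#' @slot orthoScores,orthoLoadings,orthoWeights orthogonal components
#'   (n-by-j and p-by-j; zero columns when no orthogonal variation exists).
#' @slot yWeight scalar regression weight of y on t_p.
#' @slot R2X named numeric: fractions of scaled-X variation explained by the
#'   predictive component, each orthogonal component, and the residual.
#' @slot R2Y fraction of centered class-coding variation explained.
#' @slot correlation,covariance per-variable Pearson r and covariance
#'   between the (scaled) variable and the centered class coding.
#' @slot zeroed logical per-variable flag: TRUE where loadings/r were set to
#'   zero (declared noise region or constant column).
#' @slot scaling the \linkS4class{ScalingParams} fitted on X.
#' @slot yMean mean of the 0/1 class coding.
#' @slot classLevels the two class labels, coding order (0 then 1).
#' @slot labels per-sample class labels.
#' @export
setClass("OplsModel",
  slots = c(predScores = "numeric", predLoadings = "numeric",
            predWeights = "numeric", orthoScores = "matrix",
            orthoLoadings = "matrix", orthoWeights = "matrix",
            yWeight = "numeric", R2X = "numeric", R2Y = "numeric",
            correlation = "numeric", covariance = "numeric",
            zeroed = "logical", scaling = "ScalingParams", yMean = "numeric",
            classLevels = "character", labels = "character"))

#' ValidationReport: cross-validation and permutation results
#'
#' @slot Q2 cross-validated predictive ability, 1 - PRESS/TSS.
#' @slot press per-fold PRESS values.
#' @slot R2Y explained Y-variation of the full-data model.
#' @slot permQ2,permR2Y permutation null distributions (length
#'   \code{nPermutations}; empty when only CV was run).
#' @slot pQ2,pR2Y empirical p-values, (1 + #\{null >= observed\}) / (1 + n).
#' @slot nFolds,nPermutations,seed settings used.
#' @slot folds integer fold assignment per sample.
#' @export
setClass("ValidationReport",
  slots = c(Q2 = "numeric", press = "numeric", R2Y = "numeric",
            permQ2 = "numeric", permR2Y = "numeric",
            pQ2 = "numeric", pR2Y = "numeric",
            nFolds = "integer", nPermutations = "integer", seed = "integer",
            folds = "integer"))

#' SyntheticTruth: ground truth of a simulated dataset
#'
#' @slot affectedBins named list mapping factor name (\code{disease},
#'   \code{ea}, \code{interaction}) to the integer indices of bins
#'   overlapping an effect-carrying peak (where the affected metabolite's
#'   unit-concentration curve is at least 20\% of a single peak height).
#' @slot effectSizes data.frame of realized fractional effects:
#'   metabolite, factor, level, fraction.
#' @slot dilutionFactors named positive numeric, true per-sample dilution.
#' @slot noiseSd additive noise standard deviation used.
#' @slot seed integer seed the dataset was generated with.
#' @export
setClass("SyntheticTruth",
  slots = c(affectedBins = "list", effectSizes = "data.frame",
            dilutionFactors = "numeric", noiseSd = "numeric",
            seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  if (any(object@dilutionFactors <= 0))
    "dilution factors must be positive" else TRUE
})

#' ReportBundle: results of a full pipeline run
#'
#' One entry per analysed biofluid: the normalized dataset, the variance
#' table, the exploratory all-group PLS-DA, the effect-filtered disease and
#' EA comparison models with their validation reports and loading tables,
#' and the univariate tables. The provenance block echoes the configuration
#' and seed so a run can be reproduced bit-identically.
#'
#' @slot datasets named list of normalized \linkS4class{BinnedDataset}s.
#' @slot varianceTables named list of variance-percentage data.frames.
#' @slot models nested named list of per-comparison results.
#' @slot univariate named list of univariate result tables.
#' @slot truth named list of \linkS4class{SyntheticTruth} (simulated runs).
#' @slot provenance list: config echo, seed, package version, timestamp.
#' @export
setClass("ReportBundle",
  slots = c(datasets = "list", varianceTables = "list", models = "list",
            univariate = "list", truth = "list", provenance = "list"))
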