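#' Accessors for BinnedDataset and related objects
#'
#' \code{intensityMatrix} returns the samples-by-bins matrix (the
#' user-facing orientation); \code{binCenters} the bin-center ppm vector;
#' \code{binWidth} the constant bin width; \code{sampleData} the per-sample
#' metadata as a base data.frame; \code{excludedRegions} the removed ppm
#' intervals.
#'
#' @param x a \linkS4class{BinnedDataset}.
#' @return See individual descriptions.
#' @name BinnedDataset-accessors
#' @aliases intensityMatrix binCenters binWidth sampleData excludedRegions
#' @examples
#' sim <- simulateDataset(generateDesign(), binWidth = 0.05, seed = 1)
#' dim(intensityMatrix(sim$dataset))
#' head(binCenters(sim$dataset))
NULL

#' @rdname BinnedDataset-accessors
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @rdname BinnedDataset-accessors
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname BinnedDataset-accessors
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname BinnedDataset-accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname BinnedDataset-accessors
#' @export
setGeneric("excludedRegions", function(x) standardGeneric("excludedRegions"))

#' @rdname BinnedDataset-accessors
#' @export
setMethod("intensityMatrix", "BinnedDataset", function(x)
  t(SummarizedExperiment::assay(x, "intensity")))

#' @rdname BinnedDataset-accessors
#' @export
setMethod("binCenters", "BinnedDataset", function(x)
  SummarizedExperiment::rowData(x)$bin_center)

#' @rdname BinnedDataset-accessors
#' @export
setMethod("binWidth", "BinnedDataset", function(x) x@binWidth)

#' @rdname BinnedDataset-accessors
#' @export
setMethod("sampleData", "BinnedDataset", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname BinnedDataset-accessors
#' @export
setMethod("excludedRegions", "BinnedDataset", function(x) x@excludedRegions)

#' Accessors for AnovaDecomposition
#'
#' \code{effectMatrix} extracts one n-by-p effect submatrix by name (a
#' factor name, \code{"interaction"}, or \code{"residual"});
#' \code{grandMean} the length-p grand-mean row; \code{sumSquares} the
#' named per-component sums of squares.
#'
#' @param x an \linkS4class{AnovaDecomposition}.
#' @param which component name.
#' @return A matrix, numeric vector, or named numeric respectively.
#' @name AnovaDecomposition-accessors
#' @aliases effectMatrix grandMean sumSquares
NULL

#' @rdname AnovaDecomposition-accessors
#' @export
setGeneric("effectMatrix", function(x, which) standardGeneric("effectMatrix"))

#' @rdname AnovaDecomposition-accessors
#' @export
setGeneric("grandMean", function(x) standardGeneric("grandMean"))

#' @rdname AnovaDecomposition-accessors
#' @export
setGeneric("sumSquares", function(x) standardGeneric("sumSquares"))

#' @rdname AnovaDecomposition-accessors
#' @export
setMethod("effectMatrix", "AnovaDecomposition", function(x, which) {
  if (identical(which, "residual")) return(x@residual)
  if (!which %in% names(x@effects))
    stop("unknown component '", which, "'; available: ",
         paste(c(names(x@effects), "residual"), collapse = ", "))
  x@effects[[which]]
})

#' @rdname AnovaDecomposition-accessors
#' @export
setMethod("grandMean", "AnovaDecomposition", function(x) x@grandMean)

#' @rdname AnovaDecomposition-accessors
#' @export
setMethod("sumSquares", "AnovaDecomposition", function(x) x@sumSquares)

setMethod("show", "Spectrum", function(object) {
  cat("Spectrum '", object@sampleId, "': ", length(object@ppm),
      " points, ppm ", sprintf("%.3f", min(object@ppm)), " .. ",
      sprintf("%.3f", max(object@ppm)), "\n", sep = "")
})

setMethod("show", "BinnedDataset", function(object) {
  cat("BinnedDataset: ", ncol(object), " samples x ", nrow(object),
      " bins (width ", object@binWidth, " ppm)\n", sep = "")
  bc <- binCenters(object)
  if (length(bc))
    cat("  ppm range: ", sprintf("%.3f", min(bc)), " .. ",
        sprintf("%.3f", max(bc)), "\n", sep = "")
  if (nrow(object@excludedRegions))
    cat("  excluded: ",
        paste(sprintf("%.2f-%.2f", object@excludedRegions[, 1L],
                      object@excludedRegions[, 2L]), collapse = ", "),
        " ppm\n", sep = "")
  md <- sampleData(object)
  for (f in intersect(c("disease", "ea", "biofluid"), names(md)))
    cat("  ", f, ": ", paste(sprintf("%s(%d)", names(table(md[[f]])),
        table(md[[f]])), collapse = " "), "\n", sep = "")
})

setMethod("show", "AnovaDecomposition", function(object) {
  cat("AnovaDecomposition (", length(object@sampleIds), " samples x ",
      length(object@grandMean), " variables)\n", sep = "")
  print(varianceTable(object), row.names = FALSE)
})

setMethod("show", "PlsModel", function(object) {
  cat("PlsModel: ", object@nComponents, " component(s), classes ",
      paste(object@classLevels, collapse = "/"), "\n",
      sprintf("  R2X = %.3f, R2Y = %.3f\n", object@R2X, object@R2Y),
      sep = "")
})

setMethod("show", "OplsModel", function(object) {
  cat("OplsModel: 1 predictive + ", ncol(object@orthoScores),
      " orthogonal component(s), classes ",
      paste(object@classLevels, collapse = " vs "), "\n",
      sprintf("  R2X(pred) = %.3f, R2Y = %.3f\n",
              object@R2X[["predictive"]], object@R2Y), sep = "")
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: Q2 = %.3f (%d-fold CV)\n",
              object@Q2, object@nFolds))
  if (object@nPermutations > 0L)
    cat(sprintf("  %d permutations: p(Q2) = %.4g, p(R2Y) = %.4g\n",
                object@nPermutations, object@pQ2, object@pR2Y))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth (seed ", object@seed, ")\n", sep = "")
  for (f in names(object@affectedBins))
    cat("  ", f, ": ", length(object@affectedBins[[f]]),
        " affected bins\n", sep = "")
})

setMethod("show", "ReportBundle", function(object) {
  cat("ReportBundle for biofluid(s): ",
      paste(names(object@datasets), collapse = ", "), "\n", sep = "")
  for (bf in names(object@models))
    cat("  ", bf, ": ", length(object@models[[bf]]),
        " comparison model(s)\n", sep = "")
})
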