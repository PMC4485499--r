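#' Reference a spectrum to a known peak position
#'
#' Uniformly shifts the ppm axis so that the maximum-intensity point inside
#' the search window sits exactly at \code{targetPpm} (e.g. the lactate CH3
#' doublet at 1.33 ppm for serum, TSP at 0.0 ppm for urine). Intensities
#' are untouched. If two points in the window share the maximum, the
#' lower-ppm one is used.
#'
#' @param spectrum a \linkS4class{Spectrum}.
#' @param targetPpm ppm value the apex is moved to.
#' @param searchWindow length-2 numeric (lo, hi) window in which to locate
#'   the apex; must overlap the spectrum's axis.
#' @return list with \code{spectrum} (the shifted \linkS4class{Spectrum})
#'   and \code{shift} (the ppm offset that was applied).
#' @examples
#' sp <- Spectrum(seq(1, 2, by = 0.001), dnorm(seq(1, 2, by = 0.001), 1.34,
#'                0.01), "S1")
#' referenceToPeak(sp, 1.33, c(1.2, 1.5))$shift
#' @export
referenceToPeak <- function(spectrum, targetPpm, searchWindow) {
  stopifnot(is(spectrum, "Spectrum"), length(searchWindow) == 2L)
  sel <- which(spectrum@ppm >= searchWindow[1L] &
               spectrum@ppm <= searchWindow[2L])
  if (!length(sel))
    stop("search window [", searchWindow[1L], ", ", searchWindow[2L],
         "] does not overlap the ppm axis of sample '",
         spectrum@sampleId, "'")
  apex <- sel[which.max(spectrum@intensity[sel])]
  shift <- targetPpm - spectrum@ppm[apex]
  out <- Spectrum(spectrum@ppm + shift, spectrum@intensity,
                  spectrum@sampleId)
  list(spectrum = out, shift = shift)
}

#' Bin spectra into a fixed-width bucket matrix
#'
#' Integrates each spectrum over contiguous half-open buckets
#' \eqn{[lo + k w,\ lo + (k+1) w)} (the last bucket is closed at \code{hi});
#' the bucket value is the sum of the intensities of the points falling in
#' it, so total signal inside the range is conserved. The bin count is
#' \code{floor((hi - lo) / w)}: 4750 bins for the urine range 0.5-10.0 ppm
#' at the default 0.002 ppm width, 4250 for the serum range 0.5-9.0 ppm.
#'
#' @param spectra list of \linkS4class{Spectrum} objects on a common
#'   nominal scale (already referenced); every spectrum must cover the
#'   requested range.
#' @param binWidth bucket width in ppm (> 0), default 0.002.
#' @param ppmRange length-2 numeric (lo, hi), lo < hi.
#' @param metadata data.frame of per-sample metadata with \code{sample_id}
#'   matching the spectra (in order); if NULL a minimal one is built.
#' @return A \linkS4class{BinnedDataset}.
#' @examples
#' sp <- Spectrum(seq(0, 10, by = 0.001), runif(10001), "S1")
#' bd <- binSpectra(list(sp, Spectrum(sp@ppm, runif(10001), "S2")),
#'                  binWidth = 0.01, ppmRange = c(0.5, 9.0))
#' @export
binSpectra <- function(spectra, binWidth = 0.002, ppmRange, metadata = NULL) {
  stopifnot(binWidth > 0, length(ppmRange) == 2L,
            ppmRange[1L] < ppmRange[2L])
  lo <- ppmRange[1L]; hi <- ppmRange[2L]
  nBins <- floor((hi - lo) / binWidth + 1e-9)
  centers <- lo + (seq_len(nBins) - 0.5) * binWidth
  mat <- matrix(0, length(spectra), nBins)
  ids <- character(length(spectra))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    stopifnot(is(sp, "Spectrum"))
    ids[i] <- sp@sampleId
    if (min(sp@ppm) > centers[1L] || max(sp@ppm) < centers[nBins])
      stop("spectrum '", sp@sampleId, "' does not cover the range [",
           lo, ", ", hi, "] ppm")
    sel <- sp@ppm >= lo & sp@ppm <= hi
    idx <- pmin(floor((sp@ppm[sel] - lo) / binWidth) + 1L, nBins)
    agg <- rowsum(sp@intensity[sel], idx)
    mat[i, as.integer(rownames(agg))] <- agg[, 1L]
  }
  if (is.null(metadata))
    metadata <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  if (!identical(as.character(metadata$sample_id), ids))
    stop("metadata sample_id must match the spectra ids in order")
  BinnedDataset(mat, centers, binWidth, metadata)
}

#' Remove ppm exclusion regions from a binned dataset
#'
#' Drops every bin whose center falls inside any of the given (lo, hi)
#' intervals — typically the water resonance (serum: 4.5-5.2 ppm) or the
#' water + urea window (urine: 4.5-6.0 ppm) — and records the intervals in
#' \code{excludedRegions}. Column order is otherwise preserved.
#'
#' @param dataset a \linkS4class{BinnedDataset}.
#' @param regions list of length-2 numeric vectors, or a two-column matrix,
#'   of (lo, hi) ppm intervals (closed).
#' @return A \linkS4class{BinnedDataset} without the excluded bins.
#' @examples
#' sim <- simulateDataset(generateDesign(), binWidth = 0.05, seed = 1)
#' excludeRegions(sim$dataset, list(c(4.5, 5.2)))
#' @export
excludeRegions <- function(dataset, regions) {
  stopifnot(is(dataset, "BinnedDataset"))
  if (is.matrix(regions))
    regions <- lapply(seq_len(nrow(regions)), function(i) regions[i, ])
  if (!length(regions)) return(dataset)
  bc <- binCenters(dataset)
  drop <- rep(FALSE, length(bc))
  for (r in regions) {
    stopifnot(length(r) == 2L, r[1L] <= r[2L])
    drop <- drop | (bc >= r[1L] & bc <= r[2L])
  }
  if (all(drop)) stop("exclusion regions would remove every bin")
  out <- dataset[!drop, ]
  out@excludedRegions <- rbind(dataset@excludedRegions,
    matrix(unlist(regions), ncol = 2L, byrow = TRUE,
           dimnames = list(NULL, c("lo", "hi"))))
  validObject(out)
  out
}

#' Probabilistic quotient normalization
#'
#' Removes per-sample dilution by the method of probabilistic quotients:
#' (1) each row is integral-normalized to a total of 100; (2) a reference
#' spectrum is formed (the median spectrum over all samples, over a named
#' reference group, or a single indexed sample); (3) per-variable quotients
#' row/reference are computed over bins where the reference is positive;
#' (4) each sample's quotient is the median of its per-variable quotients;
#' (5) the row is divided by it. The reported per-sample quotient is the
#' *total* divisor applied to the raw row (integral factor times median
#' quotient), i.e. the estimated dilution relative to a common scale;
#' re-running the normalization on its own output yields quotients of
#' exactly 1.
#'
#' @param dataset a \linkS4class{BinnedDataset} with >= 2 samples and no
#'   all-zero row.
#' @param referenceMethod \code{"median"} (median spectrum over all
#'   samples, the default), \code{"group"} (median over
#'   \code{referenceGroup}), or \code{"index"} (the single sample
#'   \code{referenceIndex}).
#' @param referenceGroup label selecting the reference samples when
#'   \code{referenceMethod = "group"}; matched against
#'   \code{referenceColumn} in the sample metadata.
#' @param referenceIndex row index of the reference sample when
#'   \code{referenceMethod = "index"}.
#' @param referenceColumn metadata column for \code{"group"} matching
#'   (default \code{"disease"}).
#' @return list with \code{dataset} (normalized
#'   \linkS4class{BinnedDataset}), \code{quotients} (named positive
#'   numeric, the per-sample divisors), \code{reference} (the reference
#'   spectrum on the integral-normalized scale) and
#'   \code{referenceMethod}.
#' @references Dieterle F, Ross A, Schlotterbeck G, Senn H (2006).
#'   Probabilistic quotient normalization as robust method to account for
#'   dilution of complex biological mixtures. Anal Chem 78:4281-90.
#' @examples
#' sim <- simulateDataset(generateDesign(), binWidth = 0.05, seed = 1)
#' res <- pqnNormalize(sim$dataset)
#' range(res$quotients)
#' @export
pqnNormalize <- function(dataset, referenceMethod = c("median", "group",
                                                      "index"),
                         referenceGroup = NULL, referenceIndex = NULL,
                         referenceColumn = "disease") {
  referenceMethod <- match.arg(referenceMethod)
  X <- intensityMatrix(dataset)
  if (nrow(X) < 2L) stop("PQN requires at least two samples")
  rs <- rowSums(X)
  if (any(rs == 0))
    stop("sample(s) with all-zero intensities: ",
         paste(rownames(X)[rs == 0], collapse = ", "))
  Xn <- 100 * X / rs
  ref <- switch(referenceMethod,
    median = apply(Xn, 2L, median),
    group = {
      if (is.null(referenceGroup))
        stop("referenceGroup is required for referenceMethod = 'group'")
      md <- sampleData(dataset)
      if (!referenceColumn %in% names(md))
        stop("metadata has no column '", referenceColumn, "'")
      sel <- md[[referenceColumn]] == referenceGroup
      if (!any(sel))
        stop("no samples with ", referenceColumn, " = '", referenceGroup,
             "'")
      apply(Xn[sel, , drop = FALSE], 2L, median)
    },
    index = {
      if (is.null(referenceIndex))
        stop("referenceIndex is required for referenceMethod = 'index'")
      Xn[referenceIndex, ]
    })
  if (all(ref == 0)) stop("reference spectrum is identically zero")
  pos <- ref > 0
  qmed <- apply(Xn[, pos, drop = FALSE], 1L, function(row)
    median(row / ref[pos]))
  if (any(qmed <= 0))
    stop("nonpositive quotient for sample(s): ",
         paste(rownames(X)[qmed <= 0], collapse = ", "))
  quotients <- (rs / 100) * qmed
  Xout <- X / quotients
  md <- sampleData(dataset)
  out <- BinnedDataset(Xout, binCenters(dataset), binWidth(dataset), md,
                       excludedRegions = dataset@excludedRegions)
  list(dataset = out, quotients = setNames(quotients, rownames(X)),
       reference = ref, referenceMethod = referenceMethod)
}
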