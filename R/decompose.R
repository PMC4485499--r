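#' Two-way ANOVA decomposition of a binned matrix
#'
#' Decomposes the sample-by-bin matrix under the crossed two-factor design
#' into grand mean, two main-effect submatrices, an interaction submatrix
#' and residuals, all of identical shape, following the general linear
#' model used in the ASCA/ANOVA-PCA family. The unweighted cell-means
#' parameterization is used throughout: the grand mean is the unweighted
#' average of cell means, the effect of level a of factor A is the
#' unweighted average over B of the cell means at a minus the grand mean,
#' and the interaction is the cell mean minus grand mean and both main
#' effects. The residual is defined as the remainder, so
#' \code{X = grandMean + A + B + AB + residual} holds exactly for balanced
#' and unbalanced designs alike.
#'
#' @param dataset a \linkS4class{BinnedDataset}, or a plain numeric matrix
#'   (samples in rows) together with \code{factors}.
#' @param factorA,factorB names of the metadata columns holding the two
#'   factors (defaults \code{"disease"} and \code{"ea"}).
#' @param factors optional data.frame with the two factor columns when
#'   \code{dataset} is a plain matrix.
#' @return An \linkS4class{AnovaDecomposition}.
#' @examples
#' sim <- simulateDataset(generateDesign(), binWidth = 0.05, seed = 1)
#' dec <- decomposeTwoWay(pqnNormalize(sim$dataset)$dataset)
#' varianceTable(dec)
#' @export
decomposeTwoWay <- function(dataset, factorA = "disease", factorB = "ea",
                            factors = NULL) {
  if (is(dataset, "BinnedDataset")) {
    X <- intensityMatrix(dataset)
    md <- sampleData(dataset)
    bc <- binCenters(dataset)
  } else {
    X <- as.matrix(dataset)
    md <- factors
    bc <- as.numeric(seq_len(ncol(X)))
  }
  if (is.null(md) || !all(c(factorA, factorB) %in% names(md)))
    stop("factor columns '", factorA, "' and '", factorB,
         "' must be present in the sample metadata")
  fa <- factor(md[[factorA]])
  fb <- factor(md[[factorB]])
  if (anyNA(fa) || anyNA(fb)) stop("every sample must have both labels")
  if (nlevels(fa) < 2L || nlevels(fb) < 2L)
    stop("both factors must have at least two observed levels")
  tab <- table(fa, fb)
  if (any(tab == 0L)) {
    empty <- which(tab == 0L, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(sprintf("(%s, %s)", rownames(tab)[empty[, 1L]],
                       colnames(tab)[empty[, 2L]]), collapse = ", "))
  }
  a <- nlevels(fa); b <- nlevels(fb); p <- ncol(X); n <- nrow(X)

  # cell means, stacked as an (a*b) x p matrix indexed by (level a, level b)
  # cell means as an (a*b) x p matrix; lex.order keys run a1.b1, a1.b2,
  # ..., so b varies fastest within a
  cellKey <- interaction(fa, fb, drop = FALSE, lex.order = TRUE)
  CM <- rowsum(X, cellKey)[levels(cellKey), , drop = FALSE] /
    as.vector(t(tab))
  gA <- rep(seq_len(a), each = b)   # factor-A level of each CM row
  gB <- rep(seq_len(b), times = a)
  mu <- colMeans(CM)                                # grand mean, length p
  mA <- rowsum(CM, gA) / b                          # a x p marginal means
  mB <- rowsum(CM, gB) / a                          # b x p marginal means
  effA <- sweep(mA, 2L, mu)                         # a x p
  effB <- sweep(mB, 2L, mu)                         # b x p
  effABcell <- CM - mA[gA, , drop = FALSE] - mB[gB, , drop = FALSE] +
    matrix(mu, a * b, p, byrow = TRUE)              # (a*b) x p

  ia <- as.integer(fa); ib <- as.integer(fb)
  cellIdx <- (ia - 1L) * b + ib
  A <- effA[ia, , drop = FALSE]
  B <- effB[ib, , drop = FALSE]
  AB <- effABcell[cellIdx, , drop = FALSE]
  resid <- X - CM[cellIdx, , drop = FALSE]
  rownames(A) <- rownames(B) <- rownames(AB) <- rownames(resid) <-
    rownames(X)

  effects <- setNames(list(A, B, AB), c(factorA, factorB, "interaction"))
  ssNames <- c(factorA, factorB, "interaction", "residual")
  ss <- setNames(c(ssq(A), ssq(B), ssq(AB), ssq(resid)), ssNames)
  new("AnovaDecomposition", grandMean = mu, effects = effects,
      residual = resid, factorNames = c(factorA, factorB),
      factors = data.frame(md[[factorA]], md[[factorB]],
                           stringsAsFactors = FALSE) |>
        setNames(c(factorA, factorB)),
      sumSquares = ss, binCenters = bc,
      sampleIds = if (is.null(rownames(X))) as.character(seq_len(n)) else
        rownames(X))
}

#' Variance-percentage table of a decomposition
#'
#' The sum of squares of each submatrix as a percentage of the
#' four-component total (grand mean excluded): the two main effects, the
#' interaction, and the residual, followed by a total row of exactly
#' 100.0. Using the four-component sum as the denominator keeps the total
#' at 100.0 even when unbalanced group sizes break the orthogonality of
#' the submatrices.
#'
#' @param decomposition an \linkS4class{AnovaDecomposition}.
#' @return data.frame with columns \code{component} and \code{percentage};
#'   rows ordered factor A, factor B, interaction, residual, total.
#' @export
varianceTable <- function(decomposition) {
  stopifnot(is(decomposition, "AnovaDecomposition"))
  ss <- decomposition@sumSquares
  tot <- sum(ss)
  if (tot == 0) {
    warning("constant data matrix: all variance assigned to residual")
    pct <- setNames(c(0, 0, 0, 100), names(ss))
  } else {
    pct <- 100 * ss / tot
  }
  data.frame(component = c(names(ss), "total"),
             percentage = c(unname(pct), 100.0),
             stringsAsFactors = FALSE)
}

#' Effect-filtered matrix reconstruction
#'
#' Rebuilds a sample-by-bin matrix from a chosen subset of the
#' decomposition's submatrices — e.g. the disease-related dataset is the
#' disease effect plus residuals, with the EA and interaction submatrices
#' discarded — so that a subsequent multivariate model sees one factor's
#' variation only.
#'
#' @param decomposition an \linkS4class{AnovaDecomposition}.
#' @param keep character vector of effect names to retain: any of the two
#'   factor names and \code{"interaction"}.
#' @param includeResidual keep the residual matrix (default TRUE).
#' @param addGrandMean add back the broadcast grand-mean row (default
#'   TRUE; irrelevant once the model centers columns).
#' @return numeric n-by-p matrix.
#' @examples
#' sim <- simulateDataset(generateDesign(), binWidth = 0.05, seed = 1)
#' dec <- decomposeTwoWay(sim$dataset)
#' Xd <- effectFilteredMatrix(dec, keep = "disease")
#' @export
effectFilteredMatrix <- function(decomposition, keep = character(),
                                 includeResidual = TRUE,
                                 addGrandMean = TRUE) {
  stopifnot(is(decomposition, "AnovaDecomposition"))
  keep <- as.character(keep)
  unknown <- setdiff(keep, names(decomposition@effects))
  if (length(unknown))
    stop("unknown effect name(s): ", paste(unknown, collapse = ", "),
         "; available: ",
         paste(names(decomposition@effects), collapse = ", "))
  if (!length(keep) && !includeResidual)
    stop("nothing to reconstruct: keep is empty and residual excluded")
  out <- matrix(0, nrow(decomposition@residual),
                ncol(decomposition@residual))
  for (k in keep) out <- out + decomposition@effects[[k]]
  if (includeResidual) out <- out + decomposition@residual
  if (addGrandMean) out <- sweep(out, 2L, decomposition@grandMean, "+")
  rownames(out) <- decomposition@sampleIds
  out
}
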