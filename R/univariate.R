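#' Per-bin group means and standard deviations
#'
#' One row per (variable, group): group mean and sample standard deviation
#' (n-1 denominator) of each selected bin, the summary underlying
#' mean/SD bar charts of selected differential metabolites across the
#' control, GML, GML-SM and GML-GM groups.
#'
#' @param dataset a \linkS4class{BinnedDataset} or numeric matrix
#'   (samples x variables).
#' @param groups group label per sample; for a \linkS4class{BinnedDataset}
#'   a metadata column name may be given (default: the interaction of
#'   \code{disease} and \code{ea} where present).
#' @param variables optional bin selection: integer indices or, for a
#'   \linkS4class{BinnedDataset}, ppm centers matched to the nearest bin.
#' @param groupLevels optional subset/order of group labels to report;
#'   unknown labels are an error.
#' @return data.frame with columns \code{bin_center}, \code{group},
#'   \code{n}, \code{mean}, \code{sd}, \code{degenerate} (TRUE for
#'   single-member groups, whose sd is reported as 0).
#' @examples
#' sim <- simulateDataset(generateDesign(), binWidth = 0.05, seed = 1)
#' head(groupSummary(sim$dataset, groups = "disease"))
#' @export
groupSummary <- function(dataset, groups = NULL, variables = NULL,
                         groupLevels = NULL) {
  prep <- resolveGroups(dataset, groups)
  X <- prep$X; g <- prep$groups; bc <- prep$binCenters
  if (!is.null(variables)) {
    idx <- resolveVariables(variables, bc)
    X <- X[, idx, drop = FALSE]; bc <- bc[idx]
  }
  lv <- if (is.null(groupLevels)) unique(g) else groupLevels
  unknown <- setdiff(lv, unique(g))
  if (length(unknown))
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  out <- lapply(lv, function(l) {
    rows <- X[g == l, , drop = FALSE]
    n <- nrow(rows)
    data.frame(bin_center = bc, group = l, n = n,
               mean = colMeans(rows),
               sd = if (n > 1L) colSds(rows) else 0,
               degenerate = n == 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

resolveGroups <- function(dataset, groups) {
  if (is(dataset, "BinnedDataset")) {
    X <- intensityMatrix(dataset)
    md <- sampleData(dataset)
    bc <- binCenters(dataset)
    if (is.null(groups)) {
      if (all(c("disease", "ea") %in% names(md)))
        g <- paste(md$disease, md$ea, sep = "-")
      else stop("specify 'groups' (metadata column or label vector)")
    } else if (length(groups) == 1L && groups %in% names(md)) {
      g <- as.character(md[[groups]])
    } else {
      g <- as.character(groups)
    }
  } else {
    X <- as.matrix(dataset)
    bc <- as.numeric(seq_len(ncol(X)))
    g <- as.character(groups)
  }
  if (length(g) != nrow(X))
    stop("group labels must match the number of samples")
  list(X = X, groups = g, binCenters = bc)
}

resolveVariables <- function(variables, binCenters) {
  if (is.numeric(variables) && all(variables == round(variables)) &&
      all(variables >= 1) && all(variables <= length(binCenters)))
    return(as.integer(variables))
  vapply(variables, function(v) which.min(abs(binCenters - v)),
         integer(1L))
}

#' Unpaired two-sample t-tests per bin
#'
#' Classical unpaired t-tests of every bin between two groups, vectorised
#' across bins. The default \code{"student"} variant uses the pooled
#' variance with \eqn{n_a + n_b - 2} degrees of freedom; \code{"welch"}
#' uses the Satterthwaite approximation. Significance is flagged at
#' \code{p < alpha} per bin, mirroring the per-metabolite p < 0.05
#' convention; Benjamini-Hochberg q-values are additionally emitted so a
#' false-discovery-rate criterion can be applied instead.
#'
#' Degenerate bins follow a documented convention: zero pooled variance
#' with equal means gives t = 0, p = 1; zero pooled variance with unequal
#' means gives p = 0 with the degenerate flag set.
#'
#' @param dataset a \linkS4class{BinnedDataset} or numeric matrix
#'   (samples x variables).
#' @param groupA,groupB the two group labels to compare (a vs b; the t
#'   statistic is mean(A) - mean(B) over its standard error).
#' @param groups group label per sample, or a metadata column name for a
#'   \linkS4class{BinnedDataset} (see \code{\link{groupSummary}}).
#' @param alpha significance threshold (default 0.05).
#' @param variant \code{"student"} (default) or \code{"welch"}.
#' @return data.frame with columns \code{bin_center}, \code{mean_a},
#'   \code{sd_a}, \code{mean_b}, \code{sd_b}, \code{t}, \code{df},
#'   \code{p}, \code{q}, \code{significant}, \code{degenerate}, and a
#'   \code{comparison} attribute-style column (\code{"A vs B"}).
#' @examples
#' unpairedTTest(rbind(matrix(1:6, 3), matrix(3:8, 3)),
#'               groupA = "a", groupB = "b",
#'               groups = rep(c("a", "b"), each = 3))
#' @export
unpairedTTest <- function(dataset, groupA, groupB, groups = NULL,
                          alpha = 0.05,
                          variant = c("student", "welch")) {
  variant <- match.arg(variant)
  prep <- resolveGroups(dataset, groups)
  selA <- prep$groups == groupA
  selB <- prep$groups == groupB
  if (!any(selA)) stop("unknown or empty group '", groupA, "'")
  if (!any(selB)) stop("unknown or empty group '", groupB, "'")
  na <- sum(selA); nb <- sum(selB)
  if (na < 2L || nb < 2L)
    stop("both groups need at least 2 samples (got ", na, " and ", nb, ")")
  A <- prep$X[selA, , drop = FALSE]
  B <- prep$X[selB, , drop = FALSE]
  ma <- colMeans(A); mb <- colMeans(B)
  va <- colSds(A)^2; vb <- colSds(B)^2
  if (variant == "student") {
    pooled <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(pooled * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tStat <- (ma - mb) / se
  degenerate <- se == 0
  tStat[degenerate & ma == mb] <- 0
  p <- 2 * pt(abs(tStat), df, lower.tail = FALSE)
  p[degenerate & ma == mb] <- 1
  p[degenerate & ma != mb] <- 0
  df[degenerate & !is.finite(df)] <- na + nb - 2
  out <- data.frame(bin_center = prep$binCenters,
                    mean_a = ma, sd_a = sqrt(va),
                    mean_b = mb, sd_b = sqrt(vb),
                    t = tStat, df = df, p = p,
                    q = stats::p.adjust(p, method = "BH"),
                    significant = p < alpha,
                    degenerate = degenerate,
                    comparison = paste(groupA, "vs", groupB),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
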