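#' Pipeline configuration
#'
#' Assembles and validates the configuration of a full study analysis.
#' Exactly one of \code{simulation} and \code{input} must be supplied:
#' either the synthetic generator's settings, or paths to a pre-binned
#' matrix CSV plus sample-metadata CSV.
#'
#' @param simulation list of generator settings: \code{groupSizes},
#'   \code{biofluids} (subset of \code{c("serum", "urine")}),
#'   \code{effectSpec}, \code{library}, \code{binWidth},
#'   \code{pointsPerBin}. Missing entries take the package defaults
#'   (the unbalanced 8/8/8/7/8/7 design at 0.002 ppm).
#' @param input list with \code{matrix} and \code{metadata} CSV paths
#'   (see \code{\link{loadDataset}}); samples are split by their
#'   \code{biofluid} column.
#' @param excludeRegions named list of per-biofluid exclusion intervals;
#'   defaults to the water window 4.5-5.2 ppm for serum and the
#'   water + urea window 4.5-6.0 ppm for urine.
#' @param pqn list: \code{referenceMethod}, \code{referenceGroup},
#'   \code{referenceColumn} (see \code{\link{pqnNormalize}}).
#' @param comparisons list of comparison specs, each a list with
#'   \code{name}, \code{predict} (factor modelled: \code{"disease"} or
#'   \code{"ea"}), \code{groups} (the two levels compared) and optional
#'   \code{subset} (named list of fixed other-factor levels). NULL gives
#'   the study's four comparisons: control vs GML on the disease-filtered
#'   matrix, and the three pairwise EA comparisons among GML rats on the
#'   EA-filtered matrix.
#' @param nComponents components of the PLS-DA models used for
#'   cross-validation and permutation testing (default 2).
#' @param exploratoryComponents components of the exploratory all-group
#'   PLS-DA (default 3).
#' @param nOrthogonal orthogonal components of the reported OPLS-DA
#'   models (default 1).
#' @param scaling column scaling for all models (default
#'   \code{"center"}).
#' @param nFolds cross-validation folds (default 8).
#' @param nPermutations label permutations per comparison model
#'   (default 199).
#' @param alpha significance threshold for the univariate tables.
#' @param noiseRegions optional list of (lo, hi) ppm intervals zeroed in
#'   loading tables.
#' @param seed master seed; every random draw in the run derives from it.
#' @return validated configuration list (class \code{PipelineConfig}).
#' @seealso \code{\link{runPipeline}}
#' @export
pipelineConfig <- function(simulation = list(), input = NULL,
                           excludeRegions = NULL, pqn = list(),
                           comparisons = NULL, nComponents = 2L,
                           exploratoryComponents = 3L, nOrthogonal = 1L,
                           scaling = "center", nFolds = 8L,
                           nPermutations = 199L, alpha = 0.05,
                           noiseRegions = NULL, seed = 1L) {
  simulate <- is.null(input)
  if (!simulate && length(simulation))
    stop("supply exactly one of 'simulation' and 'input'")
  if (!simulate && (is.null(input$matrix) || is.null(input$metadata)))
    stop("'input' needs elements matrix and metadata (CSV paths)")
  if (simulate) {
    defaults <- list(groupSizes = defaultGroupSizes(),
                     biofluids = c("serum", "urine"),
                     library = defaultMetaboliteLibrary(),
                     binWidth = 0.002, pointsPerBin = 1L)
    for (nm in names(defaults))
      if (is.null(simulation[[nm]])) simulation[[nm]] <- defaults[[nm]]
    if (is.null(simulation$effectSpec))
      simulation$effectSpec <- defaultEffectSpec(simulation$library)
  }
  if (is.null(excludeRegions))
    excludeRegions <- list(serum = list(c(4.5, 5.2)),
                           urine = list(c(4.5, 6.0)))
  pqnDefaults <- list(referenceMethod = "median", referenceGroup = NULL,
                      referenceColumn = "disease")
  for (nm in names(pqnDefaults))
    if (is.null(pqn[[nm]])) pqn[[nm]] <- pqnDefaults[[nm]]
  structure(list(simulation = if (simulate) simulation else NULL,
                 input = input, excludeRegions = excludeRegions,
                 pqn = pqn, comparisons = comparisons,
                 nComponents = as.integer(nComponents),
                 exploratoryComponents = as.integer(exploratoryComponents),
                 nOrthogonal = as.integer(nOrthogonal), scaling = scaling,
                 nFolds = as.integer(nFolds),
                 nPermutations = as.integer(nPermutations), alpha = alpha,
                 noiseRegions = noiseRegions, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto \code{\link{pipelineConfig}} arguments;
#' generator/PQN sub-settings nest under \code{simulation} and \code{pqn}.
#'
#' @param path YAML file.
#' @return A \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      names(formals(pipelineConfig)))]
  if (!is.null(args$excludeRegions))
    args$excludeRegions <- lapply(args$excludeRegions, function(rs)
      lapply(rs, as.numeric))
  do.call(pipelineConfig, args)
}

.defaultComparisons <- function() list(
  list(name = "GML_vs_control", predict = "disease",
       groups = c("control", "GML"), subset = NULL),
  list(name = "GML-SM_vs_GML", predict = "ea", groups = c("none", "SM"),
       subset = list(disease = "GML")),
  list(name = "GML-GM_vs_GML", predict = "ea", groups = c("none", "GM"),
       subset = list(disease = "GML")),
  list(name = "GML-SM_vs_GML-GM", predict = "ea", groups = c("SM", "GM"),
       subset = list(disease = "GML")))

# Effect row (length p) of `factorName` at `level` from a decomposition.
levelEffect <- function(dec, factorName, level) {
  idx <- match(level, dec@factors[[factorName]])
  if (is.na(idx)) return(numeric(length(dec@grandMean)))
  dec@effects[[factorName]][idx, ]
}

subsetRows <- function(md, comparison) {
  sel <- md[[comparison$predict]] %in% comparison$groups
  for (nm in names(comparison$subset))
    sel <- sel & md[[nm]] == comparison$subset[[nm]]
  which(sel)
}

# Decomposition-aware cross-validated Q2 of an effect-filtered comparison:
# the two-way decomposition is refit on every training fold; held-out rows
# are corrected with the training estimates of the grand mean and of the
# *other* factor's effect (the interaction correction is mean-zero when
# the predicted label is unknown and is therefore dropped).
filteredCvQ2 <- function(X, md, comparison, nComponents, scaling, nFolds,
                         seed) {
  pf <- comparison$predict
  of <- setdiff(c("disease", "ea"), pf)
  rows <- subsetRows(md, comparison)
  labels <- as.character(md[[pf]][rows])
  folds <- suppressWarnings(assignFolds(labels, nFolds, seed))
  press <- 0; tss <- 0
  lv <- sort(unique(labels))
  for (k in seq_len(nFolds)) {
    test <- rows[folds == k]
    if (!length(test)) next
    trainAll <- setdiff(seq_len(nrow(X)), test)
    dec <- decomposeTwoWay(X[trainAll, , drop = FALSE],
                           factorA = "disease", factorB = "ea",
                           factors = md[trainAll, , drop = FALSE])
    Xf <- effectFilteredMatrix(dec, keep = pf, includeResidual = TRUE,
                               addGrandMean = FALSE)
    mr <- setdiff(rows, test)
    pos <- match(mr, trainAll)
    trLab <- as.character(md[[pf]][mr])
    if (length(unique(trLab)) < 2L)
      stop("training fold ", k, " contains a single class; use fewer ",
           "folds")
    fit <- fitPLSDA(Xf[pos, , drop = FALSE], factor(trLab, levels = lv),
                    nComponents = nComponents, scaling = scaling)
    Xtest <- X[test, , drop = FALSE]
    corr <- vapply(test, function(i)
      dec@grandMean + levelEffect(dec, of, md[[of]][i]),
      numeric(ncol(X)))
    Xtest <- Xtest - t(corr)
    yhat <- predictPls(fit, Xtest)
    ytest <- as.numeric(factor(md[[pf]][test], levels = lv)) - 1
    press <- press + sum((ytest - yhat[, 1L])^2)
    tss <- tss + sum((ytest - fit@yMeans)^2)
  }
  1 - press / tss
}

# Permute the predicted factor's labels within strata of the other factor.
permuteWithinStrata <- function(md, pf, of, seed) {
  out <- md
  withSeed(seed, {
    for (lvl in unique(md[[of]])) {
      idx <- which(md[[of]] == lvl)
      out[[pf]][idx] <- md[[pf]][idx][sample(length(idx))]
    }
  })
  out
}

# Full validation of one effect-filtered comparison: decomposition-aware
# CV Q2 plus a permutation test in which labels are permuted *before* the
# decomposition, so the null distribution reflects the whole filtering
# procedure.
validateComparison <- function(X, md, comparison, nComponents, scaling,
                               nFolds, nPermutations, seed) {
  pf <- comparison$predict
  of <- setdiff(c("disease", "ea"), pf)
  fitR2Y <- function(mdUse) {
    dec <- decomposeTwoWay(X, factorA = "disease", factorB = "ea",
                           factors = mdUse)
    Xf <- effectFilteredMatrix(dec, keep = pf, includeResidual = TRUE,
                               addGrandMean = FALSE)
    rows <- subsetRows(mdUse, comparison)
    fitPLSDA(Xf[rows, , drop = FALSE],
             as.character(mdUse[[pf]][rows]),
             nComponents = nComponents, scaling = scaling)@R2Y
  }
  obsQ2 <- filteredCvQ2(X, md, comparison, nComponents, scaling, nFolds,
                        childSeed(seed, 0L))
  obsR2Y <- fitR2Y(md)
  permQ2 <- numeric(nPermutations); permR2Y <- numeric(nPermutations)
  for (i in seq_len(nPermutations)) {
    mdp <- permuteWithinStrata(md, pf, of, childSeed(seed, i))
    permR2Y[i] <- fitR2Y(mdp)
    permQ2[i] <- filteredCvQ2(X, mdp, comparison, nComponents, scaling,
                              nFolds, childSeed(seed, i))
  }
  new("ValidationReport", Q2 = obsQ2, press = numeric(), R2Y = obsR2Y,
      permQ2 = permQ2, permR2Y = permR2Y,
      pQ2 = (1 + sum(permQ2 >= obsQ2)) / (1 + nPermutations),
      pR2Y = (1 + sum(permR2Y >= obsR2Y)) / (1 + nPermutations),
      nFolds = as.integer(nFolds),
      nPermutations = as.integer(nPermutations),
      seed = as.integer(seed), folds = integer())
}

#' Run the full study analysis
#'
#' Executes, per biofluid: simulation (or loading), exclusion-region
#' removal, probabilistic quotient normalization, an exploratory
#' all-group PLS-DA, the two-way ANOVA decomposition with its variance
#' table, the effect-filtered comparison models (control vs GML on the
#' disease-filtered matrix; pairwise EA comparisons among GML samples on
#' the EA-filtered matrix) each as a reported OPLS-DA with
#' correlation-coefficient loadings plus a cross-validated and
#' permutation-tested PLS-DA, and the univariate group summaries and
#' t-tests for the control, GML, GML-SM and GML-GM groups. Fully
#' deterministic given the configuration seed.
#'
#' @param config a \code{PipelineConfig} from
#'   \code{\link{pipelineConfig}}.
#' @return A \linkS4class{ReportBundle}.
#' @examples
#' cfg <- pipelineConfig(
#'   simulation = list(biofluids = "serum", binWidth = 0.05),
#'   nPermutations = 24, seed = 7)
#' \donttest{bundle <- runPipeline(cfg)}
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  datasets <- list(); truths <- list()
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    for (i in seq_along(sim$biofluids)) {
      bf <- sim$biofluids[i]
      design <- generateDesign(sim$groupSizes, biofluid = bf)
      res <- simulateDataset(design, library = sim$library,
                             spec = sim$effectSpec,
                             binWidth = sim$binWidth,
                             pointsPerBin = sim$pointsPerBin,
                             seed = childSeed(config$seed, 1000L + i))
      datasets[[bf]] <- res$dataset
      truths[[bf]] <- res$truth
    }
  } else {
    full <- loadDataset(config$input$matrix, config$input$metadata)
    md <- sampleData(full)
    if (is.null(md$biofluid)) {
      datasets[["all"]] <- full
    } else {
      for (bf in unique(md$biofluid))
        datasets[[bf]] <- full[, md$biofluid == bf]
    }
  }
  comparisons <- if (is.null(config$comparisons)) .defaultComparisons()
                 else config$comparisons

  varianceTables <- list(); models <- list(); univariate <- list()
  for (bf in names(datasets)) {
    ds <- datasets[[bf]]
    regions <- config$excludeRegions[[bf]]
    if (!is.null(regions)) ds <- excludeRegions(ds, regions)
    norm <- pqnNormalize(ds,
      referenceMethod = config$pqn$referenceMethod,
      referenceGroup = config$pqn$referenceGroup,
      referenceColumn = config$pqn$referenceColumn)
    ds <- norm$dataset
    datasets[[bf]] <- ds
    X <- intensityMatrix(ds)
    md <- sampleData(ds)
    md$group <- paste(md$disease, md$ea, sep = "-")

    # six one-hot classes: allow the inner power iteration a loose
    # tolerance and long leash, since near-degenerate Y eigenvalues make
    # it converge slowly on weakly structured data
    exploratory <- fitPLSDA(X, md$group,
                            nComponents = config$exploratoryComponents,
                            scaling = config$scaling,
                            tol = 1e-8, maxIter = 20000L)

    dec <- decomposeTwoWay(ds)
    varianceTables[[bf]] <- varianceTable(dec)

    models[[bf]] <- list(
      exploratory = list(name = "all_groups", model = exploratory))
    for (cmp in comparisons) {
      rows <- subsetRows(md, cmp)
      labels <- as.character(md[[cmp$predict]][rows])
      Xf <- effectFilteredMatrix(dec, keep = cmp$predict,
                                 includeResidual = TRUE,
                                 addGrandMean = FALSE)
      opls <- fitOPLSDA(Xf[rows, , drop = FALSE],
                        factor(labels, levels = sort(unique(labels))),
                        nOrthogonal = config$nOrthogonal,
                        scaling = config$scaling)
      loadings <- correlationLoadings(Xf[rows, , drop = FALSE], labels,
                                      noiseRegions = config$noiseRegions,
                                      binCenters = binCenters(ds))
      validation <- validateComparison(X, md, cmp,
        nComponents = config$nComponents, scaling = config$scaling,
        nFolds = config$nFolds,
        nPermutations = config$nPermutations,
        seed = childSeed(config$seed, match(cmp$name,
          vapply(comparisons, `[[`, character(1L), "name"))))
      models[[bf]][[cmp$name]] <- list(name = cmp$name, model = opls,
                                       loadings = loadings,
                                       validation = validation,
                                       groups = cmp$groups,
                                       nSamples = length(rows))
    }

    fig4Groups <- intersect(c("control-none", "GML-none", "GML-SM",
                              "GML-GM"), unique(md$group))
    uv <- list()
    if (length(fig4Groups) > 1L)
      uv$summary <- groupSummary(ds, groups = md$group,
                                 groupLevels = fig4Groups)
    for (pair in list(c("GML-none", "control-none"),
                      c("GML-SM", "GML-none"),
                      c("GML-GM", "GML-none"))) {
      if (all(pair %in% md$group))
        uv[[paste(pair[1L], "vs", pair[2L])]] <-
          unpairedTTest(ds, pair[1L], pair[2L], groups = md$group,
                        alpha = config$alpha)
    }
    univariate[[bf]] <- uv
  }

  new("ReportBundle", datasets = datasets,
      varianceTables = varianceTables, models = models,
      univariate = univariate, truth = truths,
      provenance = list(
        seed = config$seed,
        config = config,
        package = as.character(utils::packageVersion("nmrASCA")),
        timestamp = format(Sys.time(), tz = "UTC")))
}

#' Write a binned dataset as matrix + metadata CSV
#'
#' The matrix CSV has a \code{sample_id} column followed by one column
#' per bin, headers the bin centers to four decimals; the metadata CSV
#' holds the sample table. Values round-trip through
#' \code{\link{loadDataset}} at full double precision.
#'
#' @param dataset a \linkS4class{BinnedDataset}.
#' @param matrixPath,metadataPath output CSV paths.
#' @return invisibly, the two paths.
#' @export
writeDataset <- function(dataset, matrixPath, metadataPath) {
  X <- intensityMatrix(dataset)
  df <- data.frame(sample_id = rownames(X),
                   format(X, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("sample_id", formatBinNames(binCenters(dataset)))
  write.csv(df, matrixPath, row.names = FALSE, quote = FALSE)
  write.csv(sampleData(dataset), metadataPath, row.names = FALSE,
            quote = FALSE)
  invisible(c(matrixPath, metadataPath))
}

#' Load a binned dataset from matrix + metadata CSV
#'
#' @param matrixPath CSV whose first column is \code{sample_id} and whose
#'   remaining headers are strictly increasing bin-center ppm values.
#' @param metadataPath CSV with a \code{sample_id} column matching the
#'   matrix rows one-to-one (any order) plus factor columns.
#' @return A \linkS4class{BinnedDataset} (bin width inferred from the
#'   median center spacing).
#' @export
loadDataset <- function(matrixPath, metadataPath) {
  raw <- read.csv(matrixPath, check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (names(raw)[1L] != "sample_id")
    stop("matrix CSV must start with a sample_id column")
  ids <- as.character(raw$sample_id)
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad))
      stop("non-numeric cell at row ", bad[1L], ", column '",
           names(vals)[j], "'")
    vals[[j]] <- v
  }
  centers <- suppressWarnings(as.numeric(names(vals)))
  if (anyNA(centers))
    stop("matrix headers must be numeric bin centers")
  if (length(centers) > 1L && any(diff(centers) <= 0))
    stop("bin centers in the matrix header must be strictly increasing")
  md <- read.csv(metadataPath, stringsAsFactors = FALSE)
  if (is.null(md$sample_id)) stop("metadata CSV needs a sample_id column")
  missing <- setdiff(ids, md$sample_id)
  extra <- setdiff(md$sample_id, ids)
  if (length(missing) || length(extra))
    stop("sample ids do not match 1:1; ",
         if (length(missing)) paste("missing from metadata:",
           paste(missing, collapse = ", ")) else "",
         if (length(extra)) paste(" absent from matrix:",
           paste(extra, collapse = ", ")) else "")
  md <- md[match(ids, md$sample_id), , drop = FALSE]
  w <- if (length(centers) > 1L) median(diff(centers)) else 1
  BinnedDataset(as.matrix(vals), centers, w, md)
}

#' Write a report bundle to disk
#'
#' Writes, per biofluid, the variance table, per-comparison score and
#' loading tables and univariate tables as CSV, and a deterministic
#' \code{report.json} summarising model statistics (R2X, R2Y, Q2,
#' permutation p-values) with a provenance block. The run timestamp is
#' kept out of \code{report.json} so identical configurations produce
#' byte-identical files; it is written to \code{run_info.txt} instead.
#'
#' @param bundle a \linkS4class{ReportBundle}.
#' @param dir output directory (created if needed).
#' @return invisibly, the path of \code{report.json}.
#' @export
writeReport <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(seed = bundle@provenance$seed,
                  package = bundle@provenance$package,
                  biofluids = names(bundle@datasets))
  for (bf in names(bundle@varianceTables)) {
    vt <- bundle@varianceTables[[bf]]
    write.csv(vt, file.path(dir, paste0("variance_table_", bf, ".csv")),
              row.names = FALSE)
    summary[[bf]] <- list(variance = setNames(as.list(vt$percentage),
                                              vt$component))
    for (nm in names(bundle@models[[bf]])) {
      entry <- bundle@models[[bf]][[nm]]
      if (nm == "exploratory") {
        m <- entry$model
        summary[[bf]]$exploratory <- list(R2X = m@R2X, R2Y = m@R2Y,
                                          k = m@nComponents)
        next
      }
      tag <- gsub("[^A-Za-z0-9_-]", "_", nm)
      write.csv(entry$loadings,
                file.path(dir, paste0("loadings_", bf, "_", tag, ".csv")),
                row.names = FALSE)
      m <- entry$model; v <- entry$validation
      write.csv(data.frame(sample_id = m@labels,
                           t_pred = m@predScores,
                           m@orthoScores |> as.data.frame() |>
                             setNames(paste0("t_ortho",
                               seq_len(ncol(m@orthoScores))))),
                file.path(dir, paste0("scores_", bf, "_", tag, ".csv")),
                row.names = FALSE)
      summary[[bf]][[nm]] <- list(
        groups = entry$groups, n = entry$nSamples,
        R2X_pred = unname(m@R2X[["predictive"]]), R2Y = m@R2Y,
        Q2 = v@Q2, p_Q2 = v@pQ2, p_R2Y = v@pR2Y,
        n_permutations = v@nPermutations)
    }
    for (nm in names(bundle@univariate[[bf]])) {
      tag <- gsub("[^A-Za-z0-9_-]", "_", nm)
      write.csv(bundle@univariate[[bf]][[nm]],
                file.path(dir, paste0("univariate_", bf, "_", tag,
                                      ".csv")),
                row.names = FALSE)
    }
  }
  path <- file.path(dir, "report.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(paste("run completed", bundle@provenance$timestamp),
             file.path(dir, "run_info.txt"))
  invisible(path)
}
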