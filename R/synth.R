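#' Default factorial group sizes
#'
#' The crossed two-level disease (control/GML) by three-level
#' electroacupuncture (none/SM/GM) design with the study's unbalanced group
#' sizes: 8/8/8 controls and 7/8/7 lesion-model animals, 46 samples total.
#'
#' @return data.frame with columns \code{disease}, \code{ea}, \code{n}.
#' @examples
#' defaultGroupSizes()
#' @export
defaultGroupSizes <- function() {
  data.frame(
    disease = rep(c("control", "GML"), each = 3L),
    ea = rep(c("none", "SM", "GM"), times = 2L),
    n = c(8L, 8L, 8L, 7L, 8L, 7L),
    stringsAsFactors = FALSE)
}

.diseaseLevels <- c("control", "GML")
.eaLevels <- c("none", "SM", "GM")
.biofluids <- c("serum", "urine")

#' Generate a factorial sample design
#'
#' Expands per-cell counts of the disease-by-EA design into one metadata
#' record per sample with stable, unique identifiers of the form
#' \code{<biofluid>_<disease>_<ea>_<k>}.
#'
#' @param groupSizes data.frame with columns \code{disease}, \code{ea},
#'   \code{n} (counts >= 0, at least one positive). Defaults to the
#'   unbalanced 8/8/8/7/8/7 design of \code{\link{defaultGroupSizes}}.
#' @param biofluid \code{"serum"} or \code{"urine"}.
#' @return data.frame with columns \code{sample_id}, \code{disease},
#'   \code{ea}, \code{biofluid}.
#' @examples
#' nrow(generateDesign())  # 46
#' @export
generateDesign <- function(groupSizes = defaultGroupSizes(),
                           biofluid = "serum") {
  biofluid <- match.arg(biofluid, .biofluids)
  if (!all(c("disease", "ea", "n") %in% names(groupSizes)))
    stop("groupSizes must have columns disease, ea, n")
  bad <- setdiff(unique(groupSizes$disease), .diseaseLevels)
  if (length(bad))
    stop("unknown disease level(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(groupSizes$ea), .eaLevels)
  if (length(bad))
    stop("unknown ea level(s): ", paste(bad, collapse = ", "))
  n <- as.integer(groupSizes$n)
  if (any(n < 0)) stop("group counts must be >= 0")
  if (all(n == 0L)) stop("empty design: all group counts are zero")
  rows <- lapply(seq_len(nrow(groupSizes)), function(i) {
    if (n[i] == 0L) return(NULL)
    data.frame(
      sample_id = sprintf("%s_%s_%s_%02d", biofluid,
                          groupSizes$disease[i], groupSizes$ea[i],
                          seq_len(n[i])),
      disease = groupSizes$disease[i],
      ea = groupSizes$ea[i],
      biofluid = biofluid,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Construct a metabolite peak template
#'
#' A metabolite is modelled as a sum of Lorentzian lines at fixed chemical
#' shifts with fixed relative intensities and a common half-width at half
#' maximum.
#'
#' @param name metabolite name.
#' @param positions peak positions in ppm.
#' @param intensities positive relative intensities, same length.
#' @param linewidth Lorentzian half-width at half maximum in ppm (> 0).
#' @return A list of class \code{PeakTemplate}.
#' @export
peakTemplate <- function(name, positions, intensities, linewidth = 0.005) {
  if (length(positions) != length(intensities))
    stop("positions and intensities must have the same length")
  if (any(intensities <= 0)) stop("relative intensities must be positive")
  if (linewidth <= 0) stop("linewidth must be positive")
  structure(list(name = name, positions = as.numeric(positions),
                 intensities = as.numeric(intensities),
                 linewidth = as.numeric(linewidth)),
            class = "PeakTemplate")
}

#' Built-in metabolite library
#'
#' A stable library of peak templates spanning 0.5-10.0 ppm, with positions
#' and multiplicities drawn from standard \eqn{^1}H assignments of common
#' serum/urine metabolites (e.g. the lactate CH3 doublet at 1.33 ppm, the
#' hippurate aromatic multiplets). Relative intensities are coarse
#' multiplet weights, not quantitative literature values.
#'
#' @return named list of \code{PeakTemplate}s.
#' @examples
#' names(defaultMetaboliteLibrary())
#' @export
defaultMetaboliteLibrary <- function() {
  tmpl <- list(
    peakTemplate("isoleucine", c(0.94, 1.01), c(1, 1)),
    peakTemplate("3-hydroxybutyrate", c(1.20, 2.31, 4.13), c(1, 0.5, 0.3)),
    peakTemplate("lactate", c(1.33, 4.11), c(1, 0.3)),
    peakTemplate("alanine", c(1.48, 3.78), c(1, 0.3)),
    peakTemplate("acetate", 1.92, 1),
    peakTemplate("N-acetylglutamate", c(2.04, 2.24), c(1, 0.6)),
    peakTemplate("succinate", 2.41, 1),
    peakTemplate("citrate", c(2.54, 2.66), c(1, 1)),
    peakTemplate("creatine", c(3.04, 3.93), c(1, 0.6)),
    peakTemplate("betaine", c(3.27, 3.90), c(1, 0.25)),
    peakTemplate("glycine", 3.56, 1),
    peakTemplate("creatinine", c(3.05, 4.06), c(1, 0.6)),
    peakTemplate("taurine", c(3.26, 3.43), c(1, 1)),
    peakTemplate("hippurate", c(3.97, 7.55, 7.64, 7.84), c(0.8, 0.8, 0.4, 1)),
    peakTemplate("benzoate", c(7.48, 7.87), c(1, 0.8)),
    peakTemplate("formate", 8.46, 1),
    peakTemplate("trigonelline", c(4.44, 8.08, 8.84, 9.12), c(0.6, 0.5, 0.8, 1)),
    peakTemplate("1-methylnicotinamide", c(4.48, 8.18, 8.90, 9.28),
                 c(0.6, 0.5, 0.8, 1)))
  names(tmpl) <- vapply(tmpl, `[[`, character(1L), "name")
  tmpl
}

#' Evaluate a peak template on a ppm grid
#'
#' Renders the template's Lorentzian sum
#' \eqn{\sum_k a_k \gamma^2 / ((x - x_k - s)^2 + \gamma^2)} (unit peak
#' height per line before the relative intensity \eqn{a_k}).
#'
#' @param template a \code{PeakTemplate}.
#' @param ppm numeric grid.
#' @param shift ppm offset applied to every peak position (shift jitter).
#' @return numeric vector of intensities.
#' @export
renderTemplate <- function(template, ppm, shift = 0) {
  g2 <- template$linewidth^2
  out <- numeric(length(ppm))
  for (k in seq_along(template$positions)) {
    d <- ppm - template$positions[k] - shift
    out <- out + template$intensities[k] * g2 / (d * d + g2)
  }
  out
}

#' Specify effects and noise for the simulator
#'
#' Effects are signed fractional concentration changes composed
#' multiplicatively: a sample in cell (disease, ea) expresses metabolite m
#' at \code{baseline[m] * (1 + disease[m])^[GML] * (1 + ea[[level]][m]) *
#' (1 + interaction[["disease:ea"]][m])}.
#'
#' @param baselines named positive numeric, baseline concentration per
#'   metabolite (names must exist in the peak library used).
#' @param diseaseEffect named numeric, fractional change under GML.
#' @param eaEffects list with optional elements \code{SM} and \code{GM},
#'   each a named numeric of fractional changes.
#' @param interactionEffects optional list keyed \code{"<disease>:<ea>"}
#'   (e.g. \code{"GML:SM"}), each a named numeric of fractional changes.
#' @param dilutionSd log-scale sd of the per-sample multiplicative dilution
#'   factor (log-normal with median 1).
#' @param noiseSd additive noise sd per spectral point.
#' @param shiftJitterSd ppm sd of per-sample, per-metabolite position
#'   jitter.
#' @return list of class \code{EffectSpec}.
#' @seealso \code{\link{defaultEffectSpec}}
#' @export
effectSpec <- function(baselines, diseaseEffect = numeric(),
                       eaEffects = list(), interactionEffects = list(),
                       dilutionSd = 0, noiseSd = 0, shiftJitterSd = 0) {
  if (any(baselines <= 0)) stop("baseline concentrations must be positive")
  if (dilutionSd < 0 || noiseSd < 0 || shiftJitterSd < 0)
    stop("standard deviations must be >= 0")
  structure(list(baselines = baselines, diseaseEffect = diseaseEffect,
                 eaEffects = eaEffects,
                 interactionEffects = interactionEffects,
                 dilutionSd = dilutionSd, noiseSd = noiseSd,
                 shiftJitterSd = shiftJitterSd),
            class = "EffectSpec")
}

#' Default illustrative effect specification
#'
#' Sparse metabolite-level effects qualitatively echoing the directions
#' reported for the gastric-lesion/electroacupuncture study (lesion raises
#' ketone-body and N-acetylglutamate signals and lowers lactate, alanine
#' and succinate; stimulation raises acetate, creatine and hippurate and
#' lowers N-acetylglutamate and trigonelline, more strongly on the stomach
#' meridian). Magnitudes are illustrative: the study reports no effect
#' sizes. Dilution sd 0.15 (log scale) and additive noise sd 0.05 give a
#' realistic dilution spread and peak signal-to-noise of order 40-160.
#'
#' @param library peak library the baselines refer to.
#' @return An \code{EffectSpec}.
#' @examples
#' str(defaultEffectSpec(), max.level = 1)
#' @export
defaultEffectSpec <- function(library = defaultMetaboliteLibrary()) {
  base <- c(isoleucine = 2, `3-hydroxybutyrate` = 3, lactate = 8,
            alanine = 3, acetate = 3, `N-acetylglutamate` = 3,
            succinate = 3, citrate = 4, creatine = 3, betaine = 4,
            glycine = 3, creatinine = 5, taurine = 4, hippurate = 4,
            benzoate = 2, formate = 2, trigonelline = 2,
            `1-methylnicotinamide` = 2)
  base <- base[intersect(names(base), names(library))]
  effectSpec(
    baselines = base,
    diseaseEffect = c(`3-hydroxybutyrate` = 0.40,
                      `N-acetylglutamate` = 0.35, hippurate = 0.30,
                      lactate = -0.25, alanine = -0.25, succinate = -0.30),
    eaEffects = list(
      SM = c(acetate = 0.30, creatine = 0.25, hippurate = 0.20,
             `N-acetylglutamate` = -0.25, trigonelline = -0.30),
      GM = c(acetate = 0.20, creatine = 0.15, hippurate = 0.12,
             `N-acetylglutamate` = -0.15, trigonelline = -0.18)),
    dilutionSd = 0.15, noiseSd = 0.05, shiftJitterSd = 0)
}

# Fractional multiplier for metabolite m in design cell (disease, ea).
.effectMultiplier <- function(spec, metabolite, disease, ea) {
  f <- 1
  if (disease == "GML" && metabolite %in% names(spec$diseaseEffect))
    f <- f * (1 + spec$diseaseEffect[[metabolite]])
  if (ea %in% names(spec$eaEffects) &&
      metabolite %in% names(spec$eaEffects[[ea]]))
    f <- f * (1 + spec$eaEffects[[ea]][[metabolite]])
  key <- paste(disease, ea, sep = ":")
  if (key %in% names(spec$interactionEffects) &&
      metabolite %in% names(spec$interactionEffects[[key]]))
    f <- f * (1 + spec$interactionEffects[[key]][[metabolite]])
  f
}

#' Simulate a factorial binned NMR dataset with ground truth
#'
#' Draws, for every sample in the design, a spectrum
#' \deqn{I_i(x) = d_i \sum_m c_m(\mathrm{cell}_i)\,L_m(x;\ \mathrm{jitter}_{im}) + \varepsilon(x)}
#' on a uniform grid of \code{pointsPerBin} points per bin, then bins it
#' with \code{\link{binSpectra}}. \eqn{d_i} is a log-normal dilution factor
#' with median 1, \eqn{L_m} the metabolite's Lorentzian sum, and
#' \eqn{\varepsilon} additive Gaussian noise. The returned
#' \linkS4class{SyntheticTruth} flags, per factor, every bin where an
#' effect-carrying metabolite's unit-concentration curve reaches at least
#' 20\% of a single peak's height, i.e. every bin whose planted absolute
#' change is at least \code{0.2 * baseline * |fraction|}.
#'
#' @param design data.frame from \code{\link{generateDesign}}.
#' @param library peak library, see \code{\link{defaultMetaboliteLibrary}}.
#' @param spec an \code{EffectSpec}; defaults to
#'   \code{\link{defaultEffectSpec}}.
#' @param ppmRange length-2 numeric; defaults to 0.5-9.0 ppm for serum and
#'   0.5-10.0 ppm for urine designs.
#' @param binWidth bin width in ppm (default 0.002, the study's bucket
#'   width).
#' @param pointsPerBin spectral grid points per bin (default 1: bin value =
#'   intensity at the bin center).
#' @param seed integer seed; output is bit-reproducible given
#'   (design, spec, seed).
#' @param returnSpectra also return the continuous \linkS4class{Spectrum}
#'   objects.
#' @return list with elements \code{dataset} (\linkS4class{BinnedDataset}),
#'   \code{truth} (\linkS4class{SyntheticTruth}) and, if requested,
#'   \code{spectra}.
#' @examples
#' sim <- simulateDataset(generateDesign(), binWidth = 0.02, seed = 7)
#' sim$dataset
#' sim$truth
#' @export
simulateDataset <- function(design, library = defaultMetaboliteLibrary(),
                            spec = defaultEffectSpec(library),
                            ppmRange = NULL, binWidth = 0.002,
                            pointsPerBin = 1L, seed = 1L,
                            returnSpectra = FALSE) {
  if (!nrow(design)) stop("design must contain at least one sample")
  if (is.null(ppmRange)) {
    bf <- design$biofluid[1L]
    ppmRange <- if (identical(bf, "urine")) c(0.5, 10.0) else c(0.5, 9.0)
  }
  mets <- names(spec$baselines)
  missing <- setdiff(mets, names(library))
  if (length(missing))
    stop("baselines name metabolites absent from the library: ",
         paste(missing, collapse = ", "))
  cells <- unique(design[, c("disease", "ea")])
  for (i in seq_len(nrow(cells))) for (m in mets) {
    f <- .effectMultiplier(spec, m, cells$disease[i], cells$ea[i])
    if (spec$baselines[[m]] * f <= 0)
      stop("effects produce nonpositive concentration for metabolite '",
           m, "' in cell (", cells$disease[i], ", ", cells$ea[i], ")")
  }
  nBins <- floor((ppmRange[2L] - ppmRange[1L]) / binWidth + 1e-9)
  centers <- ppmRange[1L] + (seq_len(nBins) - 0.5) * binWidth
  pointsPerBin <- as.integer(pointsPerBin)
  grid <- if (pointsPerBin == 1L) centers else
    ppmRange[1L] + (seq_len(nBins * pointsPerBin) - 0.5) *
      (binWidth / pointsPerBin)
  n <- nrow(design)
  nm <- length(mets)

  # concentration of each metabolite in each sample's design cell
  conc <- matrix(0, n, nm, dimnames = list(design$sample_id, mets))
  for (i in seq_len(n)) for (j in seq_len(nm))
    conc[i, j] <- spec$baselines[[mets[j]]] *
      .effectMultiplier(spec, mets[j], design$disease[i], design$ea[i])

  draws <- withSeed(as.integer(seed), {
    list(dilution = exp(rnorm(n, 0, spec$dilutionSd)),
         jitter = matrix(rnorm(n * nm, 0, spec$shiftJitterSd), n, nm),
         noise = matrix(rnorm(n * length(grid), 0, spec$noiseSd),
                        n, length(grid)))
  })

  intens <- draws$noise
  if (spec$shiftJitterSd == 0) {
    curves <- vapply(mets, function(m) renderTemplate(library[[m]], grid),
                     numeric(length(grid)))
    intens <- intens + draws$dilution * (conc %*% t(curves))
  } else {
    for (i in seq_len(n)) {
      row <- numeric(length(grid))
      for (j in seq_len(nm))
        row <- row + conc[i, j] *
          renderTemplate(library[[mets[j]]], grid, draws$jitter[i, j])
      intens[i, ] <- intens[i, ] + draws$dilution[i] * row
    }
  }

  spectra <- lapply(seq_len(n), function(i)
    Spectrum(grid, intens[i, ], design$sample_id[i]))
  dataset <- binSpectra(spectra, binWidth = binWidth, ppmRange = ppmRange,
                        metadata = design)

  affectedMets <- list(
    disease = names(spec$diseaseEffect)[
      vapply(spec$diseaseEffect, function(x) x != 0, logical(1L))],
    ea = unique(unlist(lapply(spec$eaEffects, function(e)
      names(e)[vapply(e, function(x) x != 0, logical(1L))]))),
    interaction = unique(unlist(lapply(spec$interactionEffects, function(e)
      names(e)[vapply(e, function(x) x != 0, logical(1L))]))))
  # a bin is effect-carrying when the metabolite's unit-concentration
  # curve reaches at least 20% of a single peak's height there, so every
  # flagged bin carries an absolute change >= 0.2 * baseline * |fraction|
  affectedBins <- lapply(affectedMets, function(ms) {
    if (!length(ms)) return(integer(0))
    hit <- rep(FALSE, nBins)
    for (m in ms)
      hit <- hit | renderTemplate(library[[m]], centers) >= 0.2
    which(hit)
  })
  eff <- list()
  for (m in names(spec$diseaseEffect))
    eff[[length(eff) + 1L]] <- data.frame(metabolite = m, factor = "disease",
      level = "GML", fraction = spec$diseaseEffect[[m]])
  for (lv in names(spec$eaEffects)) for (m in names(spec$eaEffects[[lv]]))
    eff[[length(eff) + 1L]] <- data.frame(metabolite = m, factor = "ea",
      level = lv, fraction = spec$eaEffects[[lv]][[m]])
  for (key in names(spec$interactionEffects))
    for (m in names(spec$interactionEffects[[key]]))
      eff[[length(eff) + 1L]] <- data.frame(metabolite = m,
        factor = "interaction", level = key,
        fraction = spec$interactionEffects[[key]][[m]])
  effectSizes <- if (length(eff)) do.call(rbind, eff) else
    data.frame(metabolite = character(), factor = character(),
               level = character(), fraction = numeric())
  truth <- new("SyntheticTruth", affectedBins = affectedBins,
               effectSizes = effectSizes,
               dilutionFactors = setNames(draws$dilution, design$sample_id),
               noiseSd = spec$noiseSd, seed = as.integer(seed))
  out <- list(dataset = dataset, truth = truth)
  if (returnSpectra) out$spectra <- spectra
  out
}
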