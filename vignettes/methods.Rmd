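---
title: "Methods: ANOVA decomposition and effect-filtered OPLS-DA for factorial NMR metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ANOVA decomposition and effect-filtered OPLS-DA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrASCA)
```

This vignette is the package's account of its statistical methodology:
the models, the parameters that matter, what the synthetic-data generator
does and does not emulate, the numerical conventions, and the design
choices made where the underlying workflow left them open.

## The analysis problem

A two-level disease factor (control vs gastric mucosal lesion, GML)
crossed with a three-level electroacupuncture factor (none, stomach
meridian SM, gallbladder meridian GM) yields six animal groups profiled
by 1D ¹H NMR. After binning, the data are a samples-by-bins intensity
matrix in which both factors, their interaction, and individual
variation are superimposed. Two-group projection models on raw data
confound these sources; the package separates them before modelling.

## Preprocessing

**Referencing.** `referenceToPeak()` shifts the ppm axis uniformly so
the maximum-intensity point inside a search window lands on a target
position (lactate CH₃ at 1.33 ppm for serum, TSP at 0.0 ppm for urine).
Ties between equal maxima resolve to the lower-ppm point — an explicit,
documented tie-break rather than an implementation accident.

**Binning.** `binSpectra()` integrates each spectrum over contiguous
half-open buckets `[lo + kw, lo + (k+1)w)` (last bucket closed), bucket
value = sum of point intensities, bin count = `floor((hi − lo)/w)`.
The default width is 0.002 ppm over 0.5–9.0 ppm (serum) or 0.5–10.0 ppm
(urine), i.e. 4250/4750 buckets. Summing (not averaging) makes binning
conserve total signal; overall scale is irrelevant after normalization.

**Exclusion regions.** Water (serum default 4.5–5.2 ppm) and water+urea
(urine default 4.5–6.0 ppm) windows are removed by dropping bins whose
centers fall inside. The original workflow removed these regions
manually without stating bounds; the defaults here are conventional
choices, configurable and recorded in the dataset object. Peak-free
region removal is deliberately *not* automated: it was a manual step,
so the package only applies regions the user states explicitly.

**Probabilistic quotient normalization.** Each row is first
integral-normalized to total 100 (an arbitrary documented constant), a
reference spectrum is formed (default: the median spectrum over all
samples; a named group or a single index are options — the original
method admits either and the workflow did not state which), per-variable
quotients row/reference are taken over bins with positive reference, and
the row is divided by the median quotient. The *reported* quotient is
the total divisor applied to the raw row — integral factor × median
quotient — which is the estimated per-sample dilution up to a common
scale. Two consequences, both tested: the procedure is idempotent (a
second pass returns quotients of exactly 1 and leaves the matrix fixed),
and on data generated as dilution × common profile the quotients recover
the true dilution factors after rescaling both sides by their medians.

## Two-way decomposition

`decomposeTwoWay()` computes

$$X = \mathbf{1}\mu' + X_A + X_B + X_{AB} + E$$

with the **unweighted cell-means parameterization**: μ is the unweighted
mean of the six cell-mean rows, the effect of level *a* of factor A is
the unweighted average over B-levels of the cell means at *a* minus μ,
and the interaction is the cell mean minus μ and both main effects. This
treats groups symmetrically when sizes are unequal (8/8/8/7/8/7 in the
default design) and keeps every effect submatrix cell-constant. The
residual is defined as the remainder, so additivity is exact by
construction on any design — the tests verify reconstruction to below
1e-9 relative error, and verify every component against an independent
brute-force oracle that computes cell and marginal means by explicit
looping.

**Variance table.** Each component's sum of squared entries is reported
as a percentage of the *four-component sum* (grand mean excluded — it is
level, not variation). Under unbalanced designs the submatrices are not
exactly orthogonal, so component SS need not sum to the total centered
SS; using the four-component sum as denominator keeps the printed total
at exactly 100.0 regardless. Degenerate input (a constant matrix) is
reported as 100% residual with a warning rather than an error.

**Effect filtering.** `effectFilteredMatrix()` rebuilds the matrix from
a chosen subset of submatrices — e.g. disease effect + residual for the
disease-related dataset. Whether the grand mean is added back is exposed
as a flag but is irrelevant in practice: every downstream model centers
columns, so comparison matrices are effectively re-centered after
filtering.

## Projection models

**Scaling.** The default is mean-centering only. Centered data keep the
covariance loading profile on the spectral intensity scale, so loading
plots look like spectra; unit-variance and Pareto scaling are available
by flag but are not assumed (the original software's defaults are
unknown). Constant columns always receive divisor 1 and a flag.

**PLS-DA.** Fitted by NIPALS: per component, weight `w ∝ X'u` (unit
norm), scores `t = Xw`, y-weights `c = Y't/t't`, iterated to a relative
tolerance of 1e-10 on the score vector, then X and Y are deflated. A
binary problem uses centered 0/1 coding (single y column: the inner loop
converges in one pass, and the first weight equals the normalized
`X_c'y_c` closed form — a test oracle). Three or more classes use
centered one-hot coding. Non-convergence after the iteration cap is an
error naming the component; the cap is 500 by default and is exposed
because multi-class fits on weakly structured data converge at the rate
of the Y-covariance eigenvalue gap, which can be near 1 (the pipeline's
exploratory six-group model therefore runs with a looser tolerance of
1e-8 and a cap of 20000).

**OPLS-DA.** Exactly two classes. Per orthogonal round, with
`w ∝ X'y`, `t = Xw`, `p = X't/t't`, the orthogonal weight is
`w_o ∝ p − (w'p)w`, and X is deflated by `t_o p_o'`; a single predictive
component is then fitted on the filtered matrix. By construction the
orthogonal scores are exactly uncorrelated with the class coding (tested
to 1e-6), and the explained-variation split
predictive + orthogonal + residual sums to 1 (tested to 1e-6). If no
orthogonal variation remains (`w_o ≈ 0`), the remaining components are
zero with a warning rather than an error. Per-variable Pearson `r` and
covariance with the class coding are stored for |r|-coded loading
plots; `correlationLoadings()` additionally zeroes (and flags) declared
noise regions — making explicit the manual zeroing step of the original
workflow — and constant columns (r defined as 0).

**Cross-validation.** `crossValidatedQ2()` uses stratified folds
(default 8, matching the workflow's eightfold validation): per class,
a seeded shuffle then round-robin assignment — deterministic and
class-balanced. Scaling and the class-coding means are refit inside
every training fold; `Q² = 1 − PRESS/TSS` with TSS about the
training-fold means (alternative centering conventions differ by
O(1/n)). Q² ≤ R²Y always holds on matched data. A fold whose training
half contains one class is an error suggesting fewer folds.

**Permutation testing.** `permutationValidate()` permutes labels
uniformly, refits and re-cross-validates per permutation, and reports
`p = (1 + #{null ≥ observed})/(1 + n_perm)` for both R²Y and Q². The
default count is 999; tiny datasets (< 4 samples), where only a couple
of distinct assignments exist, are rejected.

## Validating effect-filtered models: the pipeline's key design choice

Permuting labels on an *already filtered* matrix is invalid: the kept
effect submatrix was estimated from the very labels under test, so the
filtered matrix contains a label-aligned offset in every row and both
observed and null statistics saturate. `runPipeline()` therefore
validates each comparison with the decomposition inside the loop:

* **CV:** every training fold re-runs the two-way decomposition on the
  training samples only; held-out rows are corrected by subtracting the
  training estimates of the grand mean and of the *other* factor's
  effect (at the held-out sample's known level of that factor). The
  interaction correction would require the label being predicted; under
  the unweighted parameterization its average over the unknown level is
  exactly zero, so it is dropped.
* **Permutation:** the predicted factor's labels are permuted *within
  strata of the other factor* (preserving the design's cell structure),
  the decomposition, filtering, model and CV are recomputed per
  permutation, and the p-value compares like with like.

Under a null simulation this yields essentially uniform p-values (the
pipeline tests check that ≥ 90% of seeds give p > 0.05, and that
EA-only effects do not trigger the disease model), while planted disease
effects at the default settings give Q² > 0.9 and the minimum possible
p. The *reported* observed Q² is honest in the same sense (leakage-free
per fold); the displayed R²X/R²Y of the OPLS-DA model are fit on the
full filtered matrix, as is conventional for this model family.

## The synthetic-data generator

`simulateDataset()` draws, per sample,
`I(x) = d · Σ_m c_m(cell) · L_m(x) + ε(x)`:

* **Lineshape:** Lorentzian (Cauchy) peaks, the natural solution-NMR
  lineshape; half-width at half-maximum 0.005 ppm by default.
* **Effects:** signed fractional concentration changes composed
  multiplicatively per factor level — fold-change language, matching how
  metabolite perturbations are reported. Compositions driving a
  concentration non-positive are an error naming the metabolite.
* **Dilution** `d`: log-normal with median 1 (default log-sd 0.15) —
  multiplicative and positive, exactly the nuisance PQN removes.
* **Noise:** additive Gaussian per spectral point (default sd 0.05,
  giving peak signal-to-noise of order 40–160 for the default
  baselines).
* **Peak-shift jitter:** per-sample, per-metabolite position offsets
  mimicking pH-driven drift; default 0 so the decomposition tests are
  exact.
* **Group sizes:** default 8/8/8/7/8/7 to exercise the unbalanced-design
  code paths.
* **Default effects:** sparse and illustrative, echoing the reported
  *directions* for the lesion and stimulation factors (e.g. lesion
  raises 3-hydroxybutyrate, N-acetylglutamate and hippurate and lowers
  lactate, alanine and succinate); no effect magnitudes were reported
  for the original data, so the magnitudes here (|fraction| 0.12–0.40)
  are a designed choice, not a reconstruction.

**Ground truth.** A bin is recorded as effect-carrying for a factor when
an affected metabolite's unit-concentration curve reaches at least 20%
of a single peak's height there. This threshold makes the truth set
well-defined despite the Lorentzian's infinite tails, and under the
default baselines and effect sizes it guarantees every flagged bin
carries an absolute change of at least three noise standard deviations —
the regime in which the recovery properties (≥ 90% of truth bins in the
top-2×|truth| by |r|, ≥ 90% flagged at p < 0.05) are meaningful.

**What the generator does not emulate:** free-induction decay and
time-domain effects, phase and baseline errors, J-coupling physics,
water/urea signals (exclusion windows therefore remove only noise),
peak-shape heterogeneity, and correlated biological variation beyond the
factorial effects. Passing tests demonstrate the statistical machinery
is correct and calibrated on data with known structure — not that real
spectra meet these assumptions; in particular real data need the manual
alignment and baseline work the generator sidesteps.

## Numerical conventions and degenerate inputs

* NIPALS tolerances: PLS inner loop 1e-10 (relative, on scores), cap
  500; PCA mode 1e-12 with a much larger cap because the power iteration
  contracts at the eigenvalue ratio.
* t-tests: pooled-variance Student by default (the classical unpaired
  test; Welch by flag). Zero pooled variance with equal means gives
  t = 0, p = 1; with unequal means p = 0, flagged degenerate. BH
  q-values are always emitted alongside raw p-values; no correction is
  applied to the significance flag by default, mirroring the
  per-metabolite p < 0.05 convention.
* PQN: all-zero rows and identically zero references are errors, as are
  non-positive quotients.
* Decomposition: empty design cells are an error listing the cells;
  single-sample cells are allowed (zero residual rows).
* Fold assignment, permutations and simulations all derive from integer
  seeds; identical configuration and seed reproduce results
  bit-identically (`writeReport()` keeps the timestamp out of
  `report.json` so reports are byte-identical).

## Problem sizes used by the test-suite and acceptance script

The package's own checks run the pipeline at reduced spectral resolution
and permutation counts — 0.01–0.1 ppm buckets and 99–199 permutations,
rather than the 0.002 ppm/999-permutation analysis defaults — which
preserves every statistical property being tested while keeping a full
run of the suite in minutes. The acceptance script states each
quantity's problem size (`n`) next to its value. Null-calibration
checks (Q² on pure noise, permutation type-I rate) use 40×30 and 24×20
matrices over 20–50 seeds; the Q²-on-noise bound of 0.1 is a property of
that regime — the null Q² distribution has an upper tail, and single
seeds at smaller n can exceed it.

## Known limitations

* The decomposition supports exactly two crossed factors; no nested or
  three-way designs, and no significance testing of effect matrices
  beyond the percentage accounting (the workflow reported only
  percentages).
* Serum and urine are processed as independent datasets with their own
  ppm ranges; no cross-fluid modelling.
* Manual spectral curation (phasing, baseline, peak alignment beyond
  global referencing, peak-free-region choice) is out of scope; inputs
  are assumed curated.
* VIP scores, S-plots and figure rendering are intentionally absent: the
  outputs are plain tables (CSV/JSON) from which any plot can be made.
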