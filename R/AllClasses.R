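## Central S4 containers. Matrices are plain base matrices with dimnames;
## samples are always rows.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' One-dimensional proton NMR spectrum
#'
#' A 1D 1H-NMR spectrum as paired chemical-shift / intensity arrays. The ppm
#' axis is stored strictly ascending; descending input is reversed by the
#' constructor. Non-uniform sampling is allowed (all integrals are
#' trapezoidal).
#'
#' @slot ppm Numeric, strictly increasing chemical shifts (ppm).
#' @slot intensity Numeric, same length as \code{ppm}, finite.
#' @slot sampleId Length-one character identifier.
#' @export
setClass("Spectrum1D",
         representation(ppm = "numeric", intensity = "numeric",
                        sampleId = "character"))

setValidity("Spectrum1D", function(object) {
  if (length(object@ppm) != length(object@intensity))
    return("ppm and intensity must have equal length")
  if (length(object@ppm) < 2L)
    return("a spectrum needs at least 2 points")
  d <- diff(object@ppm)
  if (!all(is.finite(object@ppm)) || any(d <= 0))
    return("ppm axis must be finite and strictly monotone")
  if (!all(is.finite(object@intensity)))
    return("intensities must be finite")
  if (length(object@sampleId) != 1L)
    return("sampleId must be a single string")
  TRUE
})

#' Construct a Spectrum1D
#'
#' @param ppm Numeric chemical shifts, strictly monotone (either direction;
#'   descending axes are reversed on construction).
#' @param intensity Numeric intensities, same length.
#' @param sampleId Sample identifier.
#' @return A \linkS4class{Spectrum1D}.
#' @examples
#' s <- Spectrum1D(seq(0, 10, by = 0.01), rexp(1001), "S1")
#' @export
Spectrum1D <- function(ppm, intensity, sampleId = "spectrum") {
  ppm <- as.numeric(ppm); intensity <- as.numeric(intensity)
  if (length(ppm) >= 2L && all(diff(ppm) < 0)) {   # descending axis on read
    ppm <- rev(ppm); intensity <- rev(intensity)
  }
  new("Spectrum1D", ppm = ppm, intensity = intensity,
      sampleId = as.character(sampleId))
}

#' Fixed-width bucket (bin) lattice for NMR spectra
#'
#' Bins are half-open \code{[edge, edge + width)} with edges at
#' \code{lo + k * width}; a bucket's label is the bin midpoint ("median") ppm.
#' Exclusion intervals mark regions (typically residual water) whose bins are
#' dropped from the bucketed matrix.
#'
#' @slot lo,hi Numeric ppm bounds of the lattice.
#' @slot width Numeric bin width in ppm; \code{(hi - lo) / width} must be an
#'   integer.
#' @slot exclusions Numeric matrix with columns \code{lo}, \code{hi}; zero
#'   rows when nothing is excluded.
#' @export
setClass("BucketGrid",
         representation(lo = "numeric", hi = "numeric", width = "numeric",
                        exclusions = "matrix"))

setValidity("BucketGrid", function(object) {
  if (length(object@lo) != 1L || length(object@hi) != 1L ||
      length(object@width) != 1L)
    return("lo, hi, width must be scalars")
  if (!is.finite(object@width) || object@width <= 0)
    return("width must be positive")
  if (object@hi <= object@lo)
    return("hi must exceed lo")
  n <- (object@hi - object@lo) / object@width
  if (abs(n - round(n)) > 1e-8)
    return("(hi - lo) / width must be an integer number of bins")
  ex <- object@exclusions
  if (ncol(ex) != 2L)
    return("exclusions must have two columns (lo, hi)")
  if (nrow(ex)) {
    if (any(ex[, 1L] >= ex[, 2L]))
      return("each exclusion interval needs lo < hi")
    if (any(ex[, 1L] < object@lo - 1e-12) || any(ex[, 2L] > object@hi + 1e-12))
      return("exclusion intervals must lie within [lo, hi]")
  }
  TRUE
})

#' Construct a bucket grid
#'
#' @param lo,hi Grid bounds in ppm.
#' @param width Bin width in ppm.
#' @param exclusions List of length-2 numeric ppm intervals to exclude
#'   (e.g. \code{list(c(4.60, 5.00))}), or \code{NULL}.
#' @return A \linkS4class{BucketGrid}.
#' @examples
#' bucketGrid(0, 10, 0.04, exclusions = list(c(4.60, 5.00)))
#' @export
bucketGrid <- function(lo = 0, hi = 10, width = 0.04, exclusions = NULL) {
  ex <- if (is.null(exclusions) || !length(exclusions)) {
    matrix(numeric(0), ncol = 2L)
  } else {
    t(vapply(exclusions, function(iv) sort(as.numeric(iv)[1:2]), numeric(2)))
  }
  colnames(ex) <- c("lo", "hi")
  new("BucketGrid", lo = as.numeric(lo), hi = as.numeric(hi),
      width = as.numeric(width), exclusions = ex)
}

#' The default profiling grid
#'
#' 0.04 ppm bins over delta 0-10; with \code{water = TRUE} the residual-water
#' region delta 5.00-4.60 is pre-excluded, leaving the standard 240 buckets.
#'
#' @param water Exclude the water region delta 4.60-5.00? Default \code{TRUE}.
#' @return A \linkS4class{BucketGrid}.
#' @examples
#' nBuckets(defaultBucketGrid())        # 240
#' nBuckets(defaultBucketGrid(FALSE))   # 250
#' @export
defaultBucketGrid <- function(water = TRUE) {
  bucketGrid(0, 10, 0.04,
             exclusions = if (water) list(c(4.60, 5.00)) else NULL)
}

#' Bucketed NMR data matrix (X block)
#'
#' Samples by buckets matrix of per-bin trapezoidal integrals. Bucket columns
#' are ordered by descending ppm, the orientation NMR spectra are drawn in.
#'
#' @slot values Numeric matrix, samples x buckets.
#' @slot sampleIds Character, row identifiers.
#' @slot bucketLabels Numeric bin-midpoint ppm per column, descending.
#' @slot grid The \linkS4class{BucketGrid} the matrix was built on.
#' @export
setClass("BucketMatrix",
         representation(values = "matrix", sampleIds = "character",
                        bucketLabels = "numeric", grid = "BucketGrid"))

setValidity("BucketMatrix", function(object) {
  if (nrow(object@values) != length(object@sampleIds))
    return("row count must match sampleIds")
  if (ncol(object@values) != length(object@bucketLabels))
    return("column count must match bucketLabels")
  if (!all(is.finite(object@values)))
    return("bucket values must be finite")
  if (is.unsorted(rev(object@bucketLabels), strictly = TRUE))
    return("bucketLabels must be strictly descending")
  ex <- object@grid@exclusions
  if (nrow(ex)) {
    for (i in seq_len(nrow(ex)))
      if (any(object@bucketLabels > ex[i, 1L] & object@bucketLabels < ex[i, 2L]))
        return("a bucket label falls inside an exclusion interval")
  }
  TRUE
})

#' Construct a BucketMatrix
#'
#' @param values Samples x buckets numeric matrix.
#' @param sampleIds Character row ids.
#' @param bucketLabels Numeric ppm labels per column (any order; columns are
#'   re-sorted to descending ppm).
#' @param grid The originating \linkS4class{BucketGrid}.
#' @return A \linkS4class{BucketMatrix}.
#' @export
BucketMatrix <- function(values, sampleIds, bucketLabels,
                         grid = defaultBucketGrid()) {
  values <- as.matrix(values)
  o <- order(bucketLabels, decreasing = TRUE)
  values <- values[, o, drop = FALSE]
  bucketLabels <- as.numeric(bucketLabels)[o]
  dimnames(values) <- list(sampleIds, formatBucketLabel(bucketLabels))
  new("BucketMatrix", values = values, sampleIds = as.character(sampleIds),
      bucketLabels = bucketLabels, grid = grid)
}

#' NMR multiplet definition
#'
#' A literature-style multiplet: either a centre chemical shift with a
#' multiplicity pattern and coupling constants, or (for multiplets reported
#' as a range) an explicit ppm range.
#'
#' @slot center Numeric ppm centre, or \code{NULL} when a range is given.
#' @slot range Numeric length-2 ppm range, or \code{NULL}.
#' @slot pattern Multiplicity code: one of s, d, t, q, dd, dt, m, brs, brt,
#'   sext.
#' @slot J Numeric coupling constants in Hz (possibly empty).
#' @slot field Spectrometer frequency in MHz.
#' @slot nProtons Number of protons carried by the multiplet.
#' @export
setClass("Multiplet",
         representation(center = "numericOrNULL", range = "numericOrNULL",
                        pattern = "character", J = "numeric",
                        field = "numeric", nProtons = "numeric"))

.multipletPatterns <- c("s", "d", "t", "q", "dd", "dt", "m", "brs", "brt",
                        "sext")

setValidity("Multiplet", function(object) {
  if (is.null(object@center) == is.null(object@range))
    return("exactly one of center/range must be given")
  if (!object@pattern %in% .multipletPatterns)
    return(paste0("unknown multiplicity pattern '", object@pattern, "'"))
  if (any(object@J < 0)) return("coupling constants must be non-negative")
  if (length(object@field) != 1L || object@field <= 0)
    return("field (MHz) must be a positive scalar")
  if (!is.null(object@range) && object@pattern != "m")
    return("a ppm range is only meaningful for pattern 'm'")
  if (!is.null(object@range) &&
      (length(object@range) != 2L || diff(object@range) <= 0))
    return("range must be an increasing length-2 interval")
  if (length(object@nProtons) != 1L || object@nProtons <= 0)
    return("nProtons must be a positive scalar")
  TRUE
})

#' Construct a Multiplet
#'
#' @param center Centre ppm (omit when \code{range} is given).
#' @param pattern Multiplicity code (s, d, t, q, dd, dt, m, brs, brt, sext).
#' @param J Coupling constants in Hz, in the conventional reporting order.
#' @param field Spectrometer frequency in MHz (default 400).
#' @param nProtons Proton count (default 1).
#' @param range Explicit ppm range for multiplets reported as ranges
#'   (pattern \code{"m"}), any order.
#' @return A \linkS4class{Multiplet}.
#' @examples
#' multiplet(2.27, "t", J = 7.4, field = 400, nProtons = 2)
#' multiplet(range = c(2.45, 2.59), pattern = "m", nProtons = 2)
#' @export
multiplet <- function(center = NULL, pattern, J = numeric(), field = 400,
                      nProtons = 1, range = NULL) {
  if (!is.null(range)) range <- sort(as.numeric(range))
  new("Multiplet", center = if (is.null(center)) NULL else as.numeric(center),
      range = range, pattern = as.character(pattern), J = as.numeric(J),
      field = as.numeric(field), nProtons = as.numeric(nProtons))
}

#' GC-MS / GC-FID peak table (Y block)
#'
#' Samples by compounds matrix of peak areas, plus per-sample
#' internal-standard (IS) areas. \code{\link{isStandardize}} divides all
#' areas by the IS area; \code{\link{annotateRI}} attaches linear retention
#' indices.
#'
#' @slot areas Numeric matrix, samples x compounds, non-negative.
#' @slot sampleIds Character row ids.
#' @slot compounds data.frame with columns \code{name}, \code{rt_min} and
#'   optionally \code{ri}, \code{ri_flag}, \code{missing_flag}.
#' @slot isAreas Positive numeric, IS peak area per sample (all 1 after
#'   standardization).
#' @slot standardized Logical flag.
#' @export
setClass("PeakTable",
         representation(areas = "matrix", sampleIds = "character",
                        compounds = "data.frame", isAreas = "numeric",
                        standardized = "logical"))

setValidity("PeakTable", function(object) {
  if (nrow(object@areas) != length(object@sampleIds))
    return("row count must match sampleIds")
  if (ncol(object@areas) != nrow(object@compounds))
    return("column count must match compound table")
  if (!all(c("name", "rt_min") %in% names(object@compounds)))
    return("compounds needs columns name and rt_min")
  if (anyDuplicated(object@compounds$name))
    return("compound names must be unique")
  if (any(!is.finite(object@areas)) || any(object@areas < 0))
    return("areas must be finite and non-negative")
  if (length(object@isAreas) != length(object@sampleIds))
    return("one IS area per sample required")
  if (any(!is.finite(object@isAreas)) || any(object@isAreas <= 0))
    return("IS areas must be positive")
  TRUE
})

#' Construct a PeakTable
#'
#' @param areas Samples x compounds matrix of peak areas.
#' @param sampleIds Character row ids.
#' @param compounds data.frame with at least \code{name} and \code{rt_min};
#'   or a character vector of names (rt set to \code{NA}).
#' @param isAreas Per-sample internal-standard areas (default 1, i.e.
#'   already standardized input).
#' @param standardized Has IS division already been applied?
#' @return A \linkS4class{PeakTable}.
#' @export
PeakTable <- function(areas, sampleIds, compounds, isAreas = NULL,
                      standardized = is.null(isAreas)) {
  areas <- as.matrix(areas)
  if (is.character(compounds))
    compounds <- data.frame(name = compounds, rt_min = NA_real_)
  if (is.null(isAreas)) isAreas <- rep(1, nrow(areas))
  dimnames(areas) <- list(sampleIds, compounds$name)
  new("PeakTable", areas = areas, sampleIds = as.character(sampleIds),
      compounds = compounds, isAreas = as.numeric(isAreas),
      standardized = isTRUE(standardized))
}

#' n-Alkane retention ladder
#'
#' Retention times of a homologous n-alkane series used to compute linear
#' (temperature-programmed) retention indices.
#'
#' @slot carbons Integer carbon numbers, strictly increasing, within 9-40.
#' @slot rts Numeric retention times (minutes), strictly increasing.
#' @export
setClass("AlkaneLadder",
         representation(carbons = "integer", rts = "numeric"))

setValidity("AlkaneLadder", function(object) {
  if (length(object@carbons) != length(object@rts))
    return("carbons and rts must have equal length")
  if (length(object@carbons) < 2L)
    return("ladder needs at least 2 alkanes")
  if (is.unsorted(object@carbons, strictly = TRUE) ||
      is.unsorted(object@rts, strictly = TRUE))
    return("carbons and rts must be strictly increasing")
  if (min(object@carbons) < 9L || max(object@carbons) > 40L)
    return("carbon numbers must lie within [9, 40]")
  TRUE
})

#' Construct an alkane ladder
#'
#' @param carbons Integer carbon numbers (C9-C40).
#' @param rts Retention times in minutes.
#' @return An \linkS4class{AlkaneLadder}.
#' @examples
#' alkaneLadder(9:12, c(5.0, 6.0, 7.2, 8.6))
#' @export
alkaneLadder <- function(carbons, rts) {
  new("AlkaneLadder", carbons = as.integer(carbons), rts = as.numeric(rts))
}

#' Column-scaled data matrix
#'
#' A samples x variables matrix after mean-centering and column scaling,
#' retaining the statistics needed to reconstruct or to scale new data
#' consistently. Pareto scaling divides each centered column by the square
#' root of its sample standard deviation.
#'
#' @slot values Scaled numeric matrix.
#' @slot means,scales Per-column centering means and division factors.
#' @slot scaling One of \code{"none"}, \code{"center"}, \code{"pareto"},
#'   \code{"unit"}.
#' @slot constantCols Logical flag per column: constant columns are centered
#'   but not divided.
#' @export
setClass("ScaledMatrix",
         representation(values = "matrix", means = "numeric",
                        scales = "numeric", scaling = "character",
                        constantCols = "logical"))

setValidity("ScaledMatrix", function(object) {
  if (ncol(object@values) != length(object@means) ||
      ncol(object@values) != length(object@scales) ||
      ncol(object@values) != length(object@constantCols))
    return("per-column statistics must match column count")
  if (!object@scaling %in% c("none", "center", "pareto", "unit"))
    return("unknown scaling mode")
  TRUE
})

#' Principal component model
#'
#' @slot scores Samples x k score matrix.
#' @slot loadings Variables x k orthonormal loading matrix.
#' @slot explainedFraction Fraction of total variance per component,
#'   non-increasing.
#' @slot totalVariance Total variance of the input matrix.
#' @export
setClass("PcaModel",
         representation(scores = "matrix", loadings = "matrix",
                        explainedFraction = "numeric",
                        totalVariance = "numeric"))

setValidity("PcaModel", function(object) {
  k <- ncol(object@scores)
  if (ncol(object@loadings) != k ||
      length(object@explainedFraction) != k)
    return("component counts disagree across slots")
  ef <- object@explainedFraction
  if (any(ef < -1e-12) || any(ef > 1 + 1e-12) || sum(ef) > 1 + 1e-8)
    return("explained fractions must lie in [0,1] and sum to at most 1")
  if (k > 1 && any(diff(ef) > 1e-10))
    return("explained fractions must be non-increasing")
  TRUE
})

#' Fitted OPLS / OPLS-DA / PLS model
#'
#' NIPALS-based orthogonal projections to latent structures. Component
#' counts follow the "a + b + c" convention: \code{nPredictive} predictive,
#' \code{nOrthX} X-orthogonal and \code{nOrthY} Y-orthogonal components
#' (the last unsupported and always 0 here). With \code{nOrthX = 0} the
#' model is an ordinary NIPALS PLS.
#'
#' @slot nPredictive,nOrthX,nOrthY Component counts.
#' @slot weights,loadings,scores Predictive w (vars x a), p (vars x a),
#'   t (samples x a).
#' @slot yLoadings Y-loadings c (responses x a).
#' @slot orthWeights,orthLoadings,orthScores Orthogonal w_o, p_o, t_o.
#' @slot R2Y Fraction of (centered) Y variance explained in training.
#' @slot Q2 Cross-validated predictive fraction (NA unless computed).
#' @slot residuals X residual matrix after all components.
#' @slot yMeans Centering means of Y (used by \code{predict}).
#' @slot da Logical: was the model fit as two-class discriminant analysis?
#' @slot classes For DA models, the two class labels (negative, positive).
#' @export
setClass("OplsModel",
         representation(nPredictive = "integer", nOrthX = "integer",
                        nOrthY = "integer",
                        weights = "matrix", loadings = "matrix",
                        scores = "matrix", yLoadings = "matrix",
                        orthWeights = "matrix", orthLoadings = "matrix",
                        orthScores = "matrix",
                        R2Y = "numeric", Q2 = "numeric",
                        residuals = "matrix", yMeans = "numeric",
                        da = "logical", classes = "character"))

setValidity("OplsModel", function(object) {
  if (ncol(object@scores) != object@nPredictive)
    return("predictive score count must equal nPredictive")
  if (ncol(object@orthScores) != object@nOrthX)
    return("orthogonal score count must equal nOrthX")
  if (object@nOrthY != 0L)
    return("Y-orthogonal components are not supported (nOrthY must be 0)")
  if (length(object@R2Y) != 1L ||
      object@R2Y < -1e-10 || object@R2Y > 1 + 1e-10)
    return("R2Y must lie in [0, 1]")
  TRUE
})

#' Permutation-test summary for an OPLS-DA model
#'
#' Random-relabeling validation: the class vector is permuted
#' \code{nPermutations} times, the model refit with identical settings, and
#' intercepts of the R2Y and Q2 regression lines on the permutation/original
#' label correlation are compared against the standard validity thresholds
#' (R2 intercept < 0.3 and Q2 intercept < 0.05).
#'
#' @slot nPermutations Number of permutations.
#' @slot permuted data.frame with columns \code{correlation}, \code{R2Y},
#'   \code{Q2}, one row per permutation.
#' @slot originalR2Y,originalQ2 Metrics of the unpermuted model.
#' @slot R2Intercept,Q2Intercept OLS intercepts of R2Y resp. Q2 on
#'   |correlation|, including the unpermuted point at correlation 1.
#' @slot valid Logical validity flag per the 0.3 / 0.05 thresholds.
#' @export
setClass("PermutationSummary",
         representation(nPermutations = "integer", permuted = "data.frame",
                        originalR2Y = "numeric", originalQ2 = "numeric",
                        R2Intercept = "numeric", Q2Intercept = "numeric",
                        valid = "logical"))

setValidity("PermutationSummary", function(object) {
  if (object@nPermutations < 1L) return("need at least one permutation")
  if (!all(c("correlation", "R2Y", "Q2") %in% names(object@permuted)))
    return("permuted table needs correlation, R2Y, Q2 columns")
  want <- object@R2Intercept < 0.3 && object@Q2Intercept < 0.05
  if (!identical(object@valid, want))
    return("valid flag inconsistent with intercept thresholds")
  TRUE
})

#' Bucket x compound correlation heatmap
#'
#' Correlation coefficients between every NMR bucket and every GC-MS
#' compound across samples: the statistical-fusion table used to assign
#' unidentified NMR signals to chromatographically identified compounds.
#'
#' @slot r Buckets x compounds correlation matrix in [-1, 1].
#' @slot bucketLabels Numeric ppm labels (rows), descending.
#' @slot compoundNames Character (columns).
#' @slot mode \code{"raw"} (plain Pearson) or \code{"opls_filtered"}
#'   (Pearson after removing the model's Y-orthogonal X variation).
#' @slot flags Logical matrix marking cells involving a zero-variance
#'   column (r set to 0 there).
#' @export
setClass("CorrelationHeatmap",
         representation(r = "matrix", bucketLabels = "numeric",
                        compoundNames = "character", mode = "character",
                        flags = "matrix"))

setValidity("CorrelationHeatmap", function(object) {
  if (nrow(object@r) != length(object@bucketLabels) ||
      ncol(object@r) != length(object@compoundNames))
    return("r matrix dimensions must match labels")
  if (any(abs(object@r) > 1 + 1e-12))
    return("correlations must lie in [-1, 1]")
  if (!object@mode %in% c("raw", "opls_filtered"))
    return("mode must be raw or opls_filtered")
  TRUE
})

#' Calibration curve for GC-FID quantification
#'
#' Ordinary least squares of peak area on concentration over an external
#' standard dilution series.
#'
#' @slot analyte Analyte name.
#' @slot slope Area per (mg/mL).
#' @slot intercept Area at zero concentration.
#' @slot rSquared Coefficient of determination.
#' @slot range Calibrated concentration range (mg/mL).
#' @slot n Number of calibration points.
#' @export
setClass("CalibrationCurve",
         representation(analyte = "character", slope = "numeric",
                        intercept = "numeric", rSquared = "numeric",
                        range = "numeric", n = "integer"))

setValidity("CalibrationCurve", function(object) {
  if (object@n < 3L) return("calibration needs at least 3 points")
  if (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
    return("r_squared must lie in [0, 1]")
  TRUE
})

#' Compound profile for the cohort simulator
#'
#' Stated world of one compound: its NMR multiplets (projected onto the
#' bucket lattice when spectra are simulated), its GC response factor, and
#' its class-dependent mean concentration.
#'
#' @slot name Compound name.
#' @slot multiplets List of \linkS4class{Multiplet}.
#' @slot gcResponse Peak area per unit concentration; \code{NA} for
#'   compounds invisible to GC (e.g. sugars in a hexane extract).
#' @slot rtMin GC retention time in minutes (NA when not GC-detectable).
#' @slot classMeans Named numeric mean concentration per class.
#' @slot cv Relative (log-normal) biological noise.
#' @export
setClass("CompoundProfile",
         representation(name = "character", multiplets = "list",
                        gcResponse = "numeric", rtMin = "numeric",
                        classMeans = "numeric", cv = "numeric"))

setValidity("CompoundProfile", function(object) {
  if (!length(object@multiplets) ||
      !all(vapply(object@multiplets, is, logical(1), "Multiplet")))
    return("multiplets must be a non-empty list of Multiplet")
  if (any(object@classMeans < 0)) return("class means must be non-negative")
  if (!is.na(object@gcResponse) && object@gcResponse <= 0)
    return("gcResponse must be positive (or NA)")
  if (object@cv < 0) return("cv must be non-negative")
  TRUE
})

#' Construct a CompoundProfile
#'
#' @param name Compound name.
#' @param multiplets List of \linkS4class{Multiplet} objects.
#' @param classMeans Named numeric vector of per-class mean concentrations.
#' @param gcResponse GC peak area per unit concentration (\code{NA} = not in
#'   the GC block).
#' @param rtMin GC retention time (minutes).
#' @param cv Relative log-normal concentration noise (default 0.2).
#' @return A \linkS4class{CompoundProfile}.
#' @export
compoundProfile <- function(name, multiplets, classMeans, gcResponse = NA_real_,
                            rtMin = NA_real_, cv = 0.2) {
  new("CompoundProfile", name = as.character(name), multiplets = multiplets,
      gcResponse = as.numeric(gcResponse), rtMin = as.numeric(rtMin),
      classMeans = classMeans, cv = as.numeric(cv))
}

## two-decimal ppm label used in all delimited output
formatBucketLabel <- function(x) sprintf("%.2f", x)
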