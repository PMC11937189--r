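#' @include AllClasses.R
NULL

#' Sample identifiers of a container
#'
#' @param x A \linkS4class{Spectrum1D}, \linkS4class{BucketMatrix} or
#'   \linkS4class{PeakTable}.
#' @return Character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Bucket labels (bin-midpoint ppm, descending)
#'
#' @param x A \linkS4class{BucketGrid}, \linkS4class{BucketMatrix} or
#'   \linkS4class{CorrelationHeatmap}.
#' @param ... Further arguments passed to methods.
#' @return Numeric vector of bucket labels in descending ppm order.
#' @export
setGeneric("bucketLabels", function(x, ...) standardGeneric("bucketLabels"))

#' Values matrix of a bucketed NMR data set
#'
#' @param x A \linkS4class{BucketMatrix}.
#' @return Numeric matrix, samples in rows, buckets in columns.
#' @export
setGeneric("bucketValues", function(x) standardGeneric("bucketValues"))

#' Peak-area matrix of a GC peak table
#'
#' @param x A \linkS4class{PeakTable}.
#' @return Numeric matrix, samples in rows, compounds in columns.
#' @export
setGeneric("peakAreas", function(x) standardGeneric("peakAreas"))

#' Compound metadata of a GC peak table
#'
#' @param x A \linkS4class{PeakTable} or \linkS4class{CorrelationHeatmap}.
#' @return For a \code{PeakTable}, a data.frame with columns \code{name},
#'   \code{rt_min} and (after \code{\link{annotateRI}}) \code{ri},
#'   \code{ri_flag}; for a heatmap, the compound names.
#' @export
setGeneric("compounds", function(x) standardGeneric("compounds"))

#' Score matrix of a fitted latent-variable model
#'
#' @param x A \linkS4class{PcaModel} or \linkS4class{OplsModel}.
#' @param part For OPLS models, \code{"predictive"} or \code{"orthogonal"}.
#' @param ... Further arguments passed to methods.
#' @return Numeric matrix of component scores (samples in rows).
#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))

#' Loading matrix of a fitted latent-variable model
#'
#' @inheritParams scores
#' @return Numeric matrix of loadings (variables in rows).
#' @export
setGeneric("loadings", function(x, ...) standardGeneric("loadings"))

#' Drop buckets overlapping an exclusion interval
#'
#' Removes every bin with positive-measure overlap with \code{interval} from a
#' bucket grid or a bucketed matrix. The canonical use is removal of the
#' residual water signal at delta 5.00-4.60 before multivariate analysis;
#' with the default 0.04 ppm grid over delta 0-10 this drops the ten bins
#' labelled 4.62...4.98 and leaves 240 buckets.
#'
#' @param x A \linkS4class{BucketGrid} or \linkS4class{BucketMatrix}.
#' @param interval Numeric length-2 ppm interval (any order).
#' @return Object of the same class with the overlapped bins removed. An
#'   empty intersection is a no-op.
#' @examples
#' g <- bucketGrid(0, 10, 0.04)
#' nBuckets(excludeWater(g))  # 240
#' @export
setGeneric("excludeWater",
           function(x, interval = c(4.60, 5.00)) standardGeneric("excludeWater"))
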