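#' @include AllClasses.R
NULL

#' Column scaling for multivariate analysis
#'
#' Mean-centers each column and divides by a scaling factor: 1
#' (\code{"center"}), the square root of the sample standard deviation
#' (\code{"pareto"}) or the standard deviation itself (\code{"unit"});
#' \code{"none"} leaves the matrix untouched. Standard deviations use the
#' n-1 denominator. Constant columns are centered but not divided, and
#' flagged.
#'
#' @param X Numeric matrix (samples x variables), a
#'   \linkS4class{BucketMatrix} or a \linkS4class{PeakTable} (uses its
#'   area matrix).
#' @param scaling One of \code{"pareto"}, \code{"center"}, \code{"unit"},
#'   \code{"none"}.
#' @return A \linkS4class{ScaledMatrix}.
#' @examples
#' scaleColumns(matrix(c(1, 2, 3, 5, 5, 5), 3), "pareto")
#' @export
scaleColumns <- function(X, scaling = c("pareto", "center", "unit", "none")) {
  scaling <- match.arg(scaling)
  X <- .asValuesMatrix(X)
  if (nrow(X) < 2L) stop("scaling needs at least 2 samples")
  mu <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  const <- sds < .Machine$double.eps^0.5 * pmax(1, abs(mu))
  if (any(const) && scaling %in% c("pareto", "unit"))
    warning(sum(const), " constant column(s) centered but not divided")
  fac <- switch(scaling,
                none = rep(1, ncol(X)),
                center = rep(1, ncol(X)),
                pareto = sqrt(sds),
                unit = sds)
  fac[const | fac == 0] <- 1
  vals <- if (scaling == "none") X else
    sweep(sweep(X, 2L, mu), 2L, fac, "/")
  if (scaling == "none") { mu <- rep(0, ncol(X)); fac <- rep(1, ncol(X)) }
  new("ScaledMatrix", values = vals, means = mu, scales = fac,
      scaling = scaling, constantCols = const)
}

#' Pareto scaling
#'
#' Convenience wrapper: \code{scaleColumns(X, "pareto")}. After Pareto
#' scaling each (non-constant) column's variance equals its original
#' standard deviation -- the usual compromise between no scaling and unit
#' variance for spectroscopic intensities.
#'
#' @inheritParams scaleColumns
#' @return A \linkS4class{ScaledMatrix}.
#' @export
paretoScale <- function(X) scaleColumns(X, "pareto")

.asValuesMatrix <- function(X) {
  if (is(X, "BucketMatrix")) return(X@values)
  if (is(X, "PeakTable")) return(X@areas)
  if (is(X, "ScaledMatrix")) return(X@values)
  as.matrix(X)
}

#' Undo column scaling
#'
#' @param x A \linkS4class{ScaledMatrix}.
#' @return The original data matrix, reconstructed exactly from the stored
#'   means and scale factors.
#' @export
unscale <- function(x) {
  sweep(sweep(x@values, 2L, x@scales, "*"), 2L, x@means, "+")
}

#' Apply an existing scaling to new data
#'
#' @param x A \linkS4class{ScaledMatrix} fitted on training data.
#' @param newX New samples x variables matrix with matching columns.
#' @return Scaled numeric matrix.
#' @export
applyScaling <- function(x, newX) {
  newX <- .asValuesMatrix(newX)
  sweep(sweep(newX, 2L, x@means), 2L, x@scales, "/")
}
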