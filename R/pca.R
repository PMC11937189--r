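#' @include AllClasses.R scaling.R
NULL

#' Principal component analysis
#'
#' Thin SVD of the (scaled) data matrix. Component variances are the squared
#' singular values; explained fractions are relative to the total variance
#' of the input matrix, so they match the "PC contribution" percentages
#' reported by standard chemometrics software.
#'
#' @param X A \linkS4class{ScaledMatrix} (or plain matrix, taken as already
#'   centered/scaled).
#' @param k Number of components; must satisfy
#'   \code{k <= min(nrow - 1, ncol)}.
#' @return A \linkS4class{PcaModel}.
#' @examples
#' sm <- paretoScale(matrix(rnorm(40), 8))
#' fitPca(sm, 2)
#' @export
fitPca <- function(X, k = 3) {
  V <- .asValuesMatrix(X)
  if (k > min(nrow(V) - 1L, ncol(V)))
    stop("k must not exceed min(samples - 1, variables)")
  sv <- svd(V, nu = k, nv = k)
  total <- sum(V^2)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v
  ## sign convention: largest-|.| loading element positive
  for (a in seq_len(k)) {
    s <- sign(loadings[which.max(abs(loadings[, a])), a])
    if (s < 0) { loadings[, a] <- -loadings[, a]; scores[, a] <- -scores[, a] }
  }
  dimnames(scores) <- list(rownames(V), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(colnames(V), paste0("PC", seq_len(k)))
  new("PcaModel", scores = scores, loadings = loadings,
      explainedFraction = sv$d[seq_len(k)]^2 / total,
      totalVariance = total)
}

#' @describeIn scores PCA component scores.
#' @export
setMethod("scores", "PcaModel", function(x, ...) x@scores)

#' @describeIn loadings PCA loadings (orthonormal columns).
#' @export
setMethod("loadings", "PcaModel", function(x, ...) x@loadings)

#' Explained variance fractions of a PCA model
#'
#' @param x A \linkS4class{PcaModel}.
#' @return Numeric vector, one fraction of total variance per component.
#' @export
explainedFraction <- function(x) x@explainedFraction
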