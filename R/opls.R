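#' @include AllClasses.R AllGenerics.R scaling.R
NULL

## ---- NIPALS internals -----------------------------------------------------

## flip a component so the largest-magnitude weight element is positive
.signFlip <- function(w) {
  if (w[which.max(abs(w))] < 0) -1 else 1
}

## one NIPALS PLS component on (X, Y); Y assumed centered.
## Deterministic initialization from the largest-variance Y column.
.nipalsComponent <- function(X, Y, tol = 1e-10, maxit = 500L) {
  m <- ncol(Y)
  u <- if (m == 1L) Y[, 1L] else {
    Y[, which.max(apply(Y, 2L, stats::var))]
  }
  w <- NULL
  for (it in seq_len(maxit)) {
    wNew <- crossprod(X, u)[, 1L]
    nw <- sqrt(sum(wNew^2))
    if (nw < 1e-14) return(list(degenerate = TRUE))
    wNew <- wNew / nw
    tt <- X %*% wNew
    stt <- sum(tt^2)
    if (stt < 1e-14) return(list(degenerate = TRUE))
    cc <- crossprod(Y, tt)[, 1L] / stt
    if (!is.null(w) && sqrt(sum((wNew - w)^2)) < tol) { w <- wNew; break }
    w <- wNew
    if (m == 1L) break                      # single y: converged in one pass
    u <- (Y %*% cc) / sum(cc^2)
  }
  tt <- X %*% w
  stt <- sum(tt^2)
  cc <- crossprod(Y, tt)[, 1L] / stt
  p <- crossprod(X, tt)[, 1L] / stt
  s <- .signFlip(w)
  list(degenerate = FALSE, w = s * w, t = s * as.numeric(tt), p = s * p,
       c = s * cc)
}

## ---- model fitting --------------------------------------------------------

#' Fit an OPLS (orthogonal projections to latent structures) model
#'
#' NIPALS-based OPLS regression of \code{Y} on \code{X}. Component counts
#' follow the "a + b + c" convention: \code{nPredictive} predictive
#' components, \code{nOrthX} components of X variation orthogonal to Y
#' (removed from X before the predictive fit), and \code{nOrthY}
#' Y-orthogonal components (unsupported; must be 0).
#'
#' For each orthogonal component the X loading of a provisional PLS
#' component is projected orthogonal to the column space of \code{X'Y},
#' which guarantees that every orthogonal score has exactly zero covariance
#' with every response column; for a single-column Y this reduces to the
#' classical Trygg-Wold \code{w_o = p - (w'p) w} step. With
#' \code{nOrthX = 0} the model is an ordinary NIPALS PLS (PLS1 for a
#' single-column Y, PLS2 otherwise).
#'
#' \code{X} is used as given (scale it first, e.g. with
#' \code{\link{paretoScale}}); \code{Y} is mean-centered internally and the
#' centering is undone by \code{predict}.
#'
#' @param X \linkS4class{ScaledMatrix} or numeric matrix, samples x
#'   variables.
#' @param Y Numeric response matrix or vector, rows aligned with \code{X}.
#' @param nPredictive,nOrthX,nOrthY Component counts (default 1 + 0 + 0).
#' @param tol NIPALS convergence tolerance on the weight vector change.
#' @param maxit Maximum NIPALS iterations per component.
#' @return An \linkS4class{OplsModel}. \code{Q2} is \code{NA}; attach it via
#'   \code{\link{crossValidatedQ2}} or use \code{\link{fitOplsda}}.
#' @examples
#' X <- matrix(rnorm(60), 10)
#' y <- X[, 1] + rnorm(10, sd = 0.1)
#' fitOpls(X, y, nPredictive = 1, nOrthX = 1)
#' @export
fitOpls <- function(X, Y, nPredictive = 1, nOrthX = 0, nOrthY = 0,
                    tol = 1e-10, maxit = 500L) {
  if (nOrthY != 0)
    stop("Y-orthogonal components (nOrthY > 0) are not supported; use 0")
  V <- .asValuesMatrix(X)
  Y <- as.matrix(Y)
  if (nrow(V) != nrow(Y))
    stop("X and Y are misaligned: ", nrow(V), " vs ", nrow(Y), " rows")
  if (nPredictive < 1) stop("need at least one predictive component")
  n <- nrow(V); p <- ncol(V); m <- ncol(Y)
  yMeans <- colMeans(Y)
  Yc <- sweep(Y, 2L, yMeans)
  ssY <- sum(Yc^2)
  if (ssY <= 0) stop("Y has no variance")

  Xd <- V
  Wo <- matrix(0, p, 0L); Po <- matrix(0, p, 0L); To <- matrix(0, n, 0L)
  for (a in seq_len(nOrthX)) {
    comp <- .nipalsComponent(Xd, Yc, tol, maxit)
    if (comp$degenerate)
      stop("rank-deficient X: cannot extract orthogonal component ", a)
    Vxy <- crossprod(Xd, Yc)
    qrV <- qr(Vxy)
    Q <- qr.Q(qrV)[, seq_len(qrV$rank), drop = FALSE]
    wo <- comp$p - Q %*% crossprod(Q, comp$p)
    nw <- sqrt(sum(wo^2))
    if (nw < 1e-10 * max(1, sqrt(sum(comp$p^2))))
      stop("rank-deficient X: no Y-orthogonal variation left for component ",
           a)
    wo <- as.numeric(wo / nw) * .signFlip(as.numeric(wo))
    to <- as.numeric(Xd %*% wo)
    po <- as.numeric(crossprod(Xd, to)) / sum(to^2)
    Xd <- Xd - tcrossprod(to, po)
    Wo <- cbind(Wo, wo); Po <- cbind(Po, po); To <- cbind(To, to)
  }

  W <- matrix(0, p, 0L); P <- matrix(0, p, 0L)
  Tm <- matrix(0, n, 0L); C <- matrix(0, m, 0L)
  Yd <- Yc
  for (a in seq_len(nPredictive)) {
    comp <- .nipalsComponent(Xd, Yd, tol, maxit)
    if (comp$degenerate)
      stop("rank-deficient X: cannot extract predictive component ", a)
    W <- cbind(W, comp$w); Tm <- cbind(Tm, comp$t)
    P <- cbind(P, comp$p); C <- cbind(C, comp$c)
    Xd <- Xd - tcrossprod(comp$t, comp$p)
    Yd <- Yd - tcrossprod(comp$t, comp$c)
  }
  R2Y <- max(0, min(1, 1 - sum(Yd^2) / ssY))

  cn <- if (!is.null(colnames(V))) colnames(V) else paste0("V", seq_len(p))
  rn <- if (!is.null(rownames(V))) rownames(V) else paste0("S", seq_len(n))
  pc <- paste0("p", seq_len(nPredictive))
  oc <- if (nOrthX) paste0("o", seq_len(nOrthX)) else character()
  dimnames(W) <- dimnames(P) <- list(cn, pc)
  dimnames(Tm) <- list(rn, pc)
  dimnames(C) <- list(colnames(Y), pc)
  if (nOrthX) {
    dimnames(Wo) <- dimnames(Po) <- list(cn, oc)
    dimnames(To) <- list(rn, oc)
  }
  new("OplsModel", nPredictive = as.integer(nPredictive),
      nOrthX = as.integer(nOrthX), nOrthY = 0L,
      weights = W, loadings = P, scores = Tm, yLoadings = C,
      orthWeights = Wo, orthLoadings = Po, orthScores = To,
      R2Y = R2Y, Q2 = NA_real_, residuals = Xd, yMeans = yMeans,
      da = FALSE, classes = character())
}

#' Predict responses from a fitted OPLS model
#'
#' New samples are passed through the fitted orthogonal filter (each
#' orthogonal component's score is estimated and its loading removed) and
#' the predictive components are then applied sequentially, exactly
#' mirroring the training deflation. \code{newdata} must be on the same
#' scale as the training X.
#'
#' @param object An \linkS4class{OplsModel}.
#' @param newdata Numeric matrix, samples x variables.
#' @param ... Ignored.
#' @return Predicted response matrix on the original Y scale.
#' @export
setMethod("predict", "OplsModel", function(object, newdata, ...) {
  Xn <- .asValuesMatrix(newdata)
  for (a in seq_len(object@nOrthX)) {
    to <- Xn %*% object@orthWeights[, a]
    Xn <- Xn - tcrossprod(as.numeric(to), object@orthLoadings[, a])
  }
  Yp <- matrix(0, nrow(Xn), length(object@yMeans))
  for (a in seq_len(object@nPredictive)) {
    tt <- Xn %*% object@weights[, a]
    Xn <- Xn - tcrossprod(as.numeric(tt), object@loadings[, a])
    Yp <- Yp + tcrossprod(as.numeric(tt), object@yLoadings[, a])
  }
  sweep(Yp, 2L, object@yMeans, "+")
})

#' @describeIn scores Predictive (default) or orthogonal OPLS scores.
#' @export
setMethod("scores", "OplsModel",
          function(x, part = c("predictive", "orthogonal"), ...) {
            switch(match.arg(part), predictive = x@scores,
                   orthogonal = x@orthScores)
          })

#' @describeIn loadings Predictive (default) or orthogonal OPLS loadings.
#' @export
setMethod("loadings", "OplsModel",
          function(x, part = c("predictive", "orthogonal"), ...) {
            switch(match.arg(part), predictive = x@loadings,
                   orthogonal = x@orthLoadings)
          })

#' Model-quality accessors
#'
#' @param x An \linkS4class{OplsModel}.
#' @return \code{r2y}: fraction of Y variance explained in training;
#'   \code{q2}: cross-validated predictive fraction (NA if never computed).
#' @export
r2y <- function(x) x@R2Y

#' @rdname r2y
#' @export
q2 <- function(x) x@Q2
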