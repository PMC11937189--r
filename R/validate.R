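#' @include opls.R
NULL

## run expr under a fixed RNG state, restoring the caller's stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## deterministic fold assignment: seeded shuffle then round-robin, within
## strata when given (keeps class balance across folds)
.cvFolds <- function(n, folds, seed, stratify = NULL) {
  .withSeed(seed, {
    assign <- integer(n)
    groups <- if (is.null(stratify)) list(seq_len(n)) else
      split(seq_len(n), stratify)
    offset <- 0L
    for (g in groups) {
      idx <- if (length(g) > 1L) sample(g) else g
      assign[idx] <- ((offset + seq_along(idx) - 1L) %% folds) + 1L
      offset <- offset + length(idx)
    }
    assign
  })
}

#' Cross-validated Q2 of an OPLS model
#'
#' K-fold cross-validation: per fold, X and Y are re-centered on the
#' training rows, the model refit with the requested components, and the
#' held-out rows predicted. \code{Q2 = 1 - PRESS / SS} with SS the total
#' sum of squares of the (globally) centered Y; it may be negative when the
#' model predicts worse than the mean. Fold assignment is a seeded shuffle
#' followed by round-robin, stratified when \code{stratify} is given.
#'
#' @param X \linkS4class{ScaledMatrix} or matrix.
#' @param Y Response vector/matrix.
#' @param components Length-3 integer vector (predictive, X-orthogonal,
#'   Y-orthogonal), e.g. \code{c(1, 2, 0)}.
#' @param folds Number of folds (default 7); \code{folds = nrow(X)} gives
#'   leave-one-out.
#' @param seed Integer seed fixing the fold assignment.
#' @param stratify Optional factor (e.g. class labels) to stratify folds by.
#' @return Numeric Q2.
#' @export
crossValidatedQ2 <- function(X, Y, components = c(1, 0, 0), folds = 7,
                             seed = 1, stratify = NULL) {
  V <- .asValuesMatrix(X)
  Y <- as.matrix(Y)
  n <- nrow(V)
  if (folds < 2 || folds > n) stop("folds must lie in [2, samples]")
  if (!is.null(stratify) && nlevels(factor(stratify)) > 1) {
    tab <- table(factor(stratify))
    if (any(tab < 2L))
      stop("cannot stratify: class '",
           names(tab)[which.min(tab)], "' has fewer than 2 members")
  }
  assign <- .cvFolds(n, folds, seed, stratify)
  press <- 0
  for (f in sort(unique(assign))) {
    test <- assign == f
    mX <- colMeans(V[!test, , drop = FALSE])
    Xtr <- sweep(V[!test, , drop = FALSE], 2L, mX)
    Xte <- sweep(V[test, , drop = FALSE], 2L, mX)
    fit <- fitOpls(Xtr, Y[!test, , drop = FALSE],
                   nPredictive = components[1L], nOrthX = components[2L],
                   nOrthY = components[3L])
    press <- press + sum((Y[test, , drop = FALSE] - predict(fit, Xte))^2)
  }
  1 - press / sum(sweep(Y, 2L, colMeans(Y))^2)
}

## 0/1 dummy for a two-class factor; positive class = second level
.daDummy <- function(labels) {
  f <- factor(labels)
  if (nlevels(f) != 2L)
    stop("OPLS-DA needs exactly two classes, got ", nlevels(f))
  list(y = as.numeric(f == levels(f)[2L]), classes = levels(f), f = f)
}

#' Fit a two-class OPLS-DA model
#'
#' Labels are encoded as a single 0/1 dummy column (positive class = second
#' factor level), mean-centered, and regressed on \code{X} with the
#' requested components; R2Y and cross-validated Q2 are attached. The
#' conventional suitability rule for a quantitative model is R2Y > 0.65 and
#' Q2 > 0.5.
#'
#' @param X \linkS4class{ScaledMatrix} or matrix (scale first, e.g. Pareto).
#' @param labels Two-class factor / character vector, one per row of X; each
#'   class needs at least \code{folds} members.
#' @param components Length-3 component counts, default \code{c(1, 2, 0)}.
#' @param folds Cross-validation folds (default 7), stratified by class.
#' @param seed Seed for the fold assignment.
#' @return An \linkS4class{OplsModel} with \code{da = TRUE}, R2Y and Q2 set.
#' @export
fitOplsda <- function(X, labels, components = c(1, 2, 0), folds = 7,
                      seed = 1) {
  enc <- .daDummy(labels)
  if (any(table(enc$f) < folds))
    stop("each class needs at least 'folds' (", folds, ") members")
  fit <- fitOpls(X, enc$y, nPredictive = components[1L],
                 nOrthX = components[2L], nOrthY = components[3L])
  fit@Q2 <- crossValidatedQ2(X, enc$y, components, folds, seed,
                             stratify = enc$f)
  fit@da <- TRUE
  fit@classes <- enc$classes
  ## orient the predictive component toward the positive class
  if (fit@yLoadings[1L, 1L] < 0) {
    fit@weights[, 1L] <- -fit@weights[, 1L]
    fit@loadings[, 1L] <- -fit@loadings[, 1L]
    fit@scores[, 1L] <- -fit@scores[, 1L]
    fit@yLoadings[, 1L] <- -fit@yLoadings[, 1L]
  }
  fit
}

#' Permutation-test validation of an OPLS-DA model
#'
#' The class labels are randomly permuted \code{nPerm} times and the model
#' refit with identical settings (same components, folds and CV seed); each
#' round records the absolute correlation of the permuted with the original
#' dummy vector together with the refit R2Y and Q2. Ordinary least-squares
#' lines of R2Y and Q2 on that correlation -- including the unpermuted model
#' at correlation 1 -- give the R2 and Q2 intercepts; the model is declared
#' valid when the R2 intercept is below 0.3 and the Q2 intercept below 0.05.
#'
#' @inheritParams fitOplsda
#' @param nPerm Number of permutations (at least 20; 200 is the
#'   conventional choice).
#' @return A \linkS4class{PermutationSummary}.
#' @export
permutationTest <- function(X, labels, components = c(1, 2, 0), nPerm = 200,
                            folds = 7, seed = 1) {
  if (nPerm < 20) stop("need at least 20 permutations to fit intercepts")
  enc <- .daDummy(labels)
  V <- .asValuesMatrix(X)
  orig <- fitOplsda(V, labels, components, folds, seed)
  perms <- .withSeed(seed, replicate(nPerm, sample(length(enc$y)),
                                     simplify = FALSE))
  rows <- lapply(seq_len(nPerm), function(b) {
    yp <- enc$y[perms[[b]]]
    fp <- factor(enc$classes[yp + 1L], levels = enc$classes)
    fit <- fitOpls(V, yp, nPredictive = components[1L],
                   nOrthX = components[2L], nOrthY = components[3L])
    q2p <- crossValidatedQ2(V, yp, components, folds, seed, stratify = fp)
    c(correlation = abs(stats::cor(yp, enc$y)), R2Y = fit@R2Y, Q2 = q2p)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  icpt <- function(metric, origVal) {
    x <- c(tab$correlation, 1)
    y <- c(metric, origVal)
    unname(stats::coef(stats::lm(y ~ x))[1L])
  }
  r2i <- icpt(tab$R2Y, orig@R2Y)
  q2i <- icpt(tab$Q2, orig@Q2)
  new("PermutationSummary", nPermutations = as.integer(nPerm),
      permuted = tab, originalR2Y = orig@R2Y, originalQ2 = orig@Q2,
      R2Intercept = r2i, Q2Intercept = q2i,
      valid = r2i < 0.3 && q2i < 0.05)
}

#' S-plot of an OPLS(-DA) model
#'
#' For every variable, the covariance of the first predictive score with the
#' variable ("contribution", X axis) and their correlation ("confidence",
#' Y axis). Variables with extreme |p(corr)| on either sign are the
#' candidate class markers. Zero-variance variables get p(corr) 0 and a
#' flag.
#'
#' @param model A fitted \linkS4class{OplsModel}.
#' @param X The matrix the model was fit to (\linkS4class{ScaledMatrix} or
#'   matrix).
#' @return data.frame with columns \code{variable}, \code{pCov},
#'   \code{pCorr}, \code{flag}.
#' @export
sPlot <- function(model, X) {
  V <- .asValuesMatrix(X)
  if (model@nPredictive < 1L) stop("model has no predictive component")
  tt <- model@scores[, 1L]
  vars <- if (!is.null(colnames(V))) colnames(V) else
    paste0("V", seq_len(ncol(V)))
  pCov <- as.numeric(stats::cov(tt, V))
  sds <- apply(V, 2L, stats::sd)
  flag <- sds < .Machine$double.eps^0.5
  pCorr <- numeric(ncol(V))
  pCorr[!flag] <- pCov[!flag] / (stats::sd(tt) * sds[!flag])
  pCorr <- pmin(1, pmax(-1, pCorr))
  data.frame(variable = vars, pCov = pCov, pCorr = pCorr, flag = flag,
             stringsAsFactors = FALSE)
}
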