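# Independent oracles and small synthesizers used across the suite.
# Everything here is deliberately brute-force / closed-form so it can
# validate the package's own algorithms.

# Lorentzian and Gaussian line shapes on a dense axis
synthSpectrum <- function(centers, areas, widths = 0.005, lo = 0, hi = 10,
                          by = 0.001, shape = c("gauss", "lorentz"),
                          sampleId = "synth") {
  shape <- match.arg(shape)
  x <- seq(lo, hi, by = by)
  widths <- rep_len(widths, length(centers))
  y <- numeric(length(x))
  for (i in seq_along(centers)) {
    y <- y + if (shape == "gauss") {
      areas[i] * dnorm(x, centers[i], widths[i])
    } else {
      areas[i] * (widths[i] / pi) / ((x - centers[i])^2 + widths[i]^2)
    }
  }
  Spectrum1D(x, y, sampleId)
}

# trapezoid oracle
trapzOracle <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1])) / 2

# classical PLS1 (single y), textbook formulas, deflating X and y
pls1Oracle <- function(X, y, A) {
  X <- as.matrix(X); y <- as.numeric(y)
  W <- P <- matrix(0, ncol(X), A)
  Tm <- matrix(0, nrow(X), A)
  cc <- numeric(A)
  for (a in seq_len(A)) {
    w <- drop(crossprod(X, y)); w <- w / sqrt(sum(w^2))
    tt <- drop(X %*% w)
    p <- drop(crossprod(X, tt)) / sum(tt^2)
    c1 <- sum(y * tt) / sum(tt^2)
    X <- X - tcrossprod(tt, p)
    y <- y - tt * c1
    W[, a] <- w; P[, a] <- p; Tm[, a] <- tt; cc[a] <- c1
  }
  list(W = W, P = P, T = Tm, c = cc)
}

# brute-force per-pair Pearson correlation matrix
pearsonOracle <- function(A, B) {
  r <- matrix(NA_real_, ncol(A), ncol(B))
  for (i in seq_len(ncol(A)))
    for (j in seq_len(ncol(B)))
      r[i, j] <- cor(A[, i], B[, j])
  r
}

# brute-force leave-one-out Q2 built directly on fitOpls/predict
looQ2Oracle <- function(X, y, components) {
  X <- as.matrix(X); Y <- as.matrix(y)
  press <- 0
  for (i in seq_len(nrow(X))) {
    mX <- colMeans(X[-i, , drop = FALSE])
    fit <- fitOpls(sweep(X[-i, , drop = FALSE], 2, mX),
                   Y[-i, , drop = FALSE],
                   nPredictive = components[1], nOrthX = components[2])
    press <- press +
      sum((Y[i, ] - predict(fit, sweep(X[i, , drop = FALSE], 2, mX)))^2)
  }
  1 - press / sum(sweep(Y, 2, colMeans(Y))^2)
}

# small deterministic BucketMatrix / PeakTable pair for fusion tests
makeBlocks <- function(n = 12, nb = 6, nc = 3, seed = 42) {
  set.seed(seed)
  labs <- seq(2.02, by = 0.04, length.out = nb)
  B <- matrix(abs(rnorm(n * nb, 10, 2)), n)
  ids <- sprintf("S%02d", seq_len(n))
  bm <- BucketMatrix(B, ids, labs,
                     grid = bucketGrid(2, 2 + 0.04 * nb, 0.04))
  A <- matrix(abs(rnorm(n * nc, 5, 1)), n)
  pt <- PeakTable(A, ids, paste0("C", seq_len(nc)))
  list(bm = bm, pt = pt)
}

quietCohort <- function(...) generateCohort(cohortConfig(...))
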