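test_that("a response proportional to one X column is fit perfectly", {
  # disjoint-support columns (mutually orthogonal after centering), as for
  # buckets driven by different compounds: one predictive component then
  # recovers a response proportional to a single column exactly
  set.seed(1)
  X <- qr.Q(qr(scale(matrix(rnorm(50), 10), scale = FALSE)))[, 1:5]
  y <- 3 * X[, 2]
  fit <- fitOpls(X, y, nPredictive = 1)
  expect_equal(r2y(fit), 1, tolerance = 1e-10)
  expect_equal(abs(cor(scores(fit)[, 1], y)), 1, tolerance = 1e-10)
})

test_that("OPLS with zero orthogonal components equals PLS1", {
  set.seed(2)
  X <- scale(matrix(rnorm(80), 10), scale = FALSE)
  y <- rnorm(10); y <- y - mean(y)
  fit <- fitOpls(X, y, nPredictive = 3)
  ora <- pls1Oracle(X, y, 3)
  for (a in 1:3) {
    s <- sign(sum(fit@weights[, a] * ora$W[, a]))   # sign-free compare
    expect_equal(fit@weights[, a], s * ora$W[, a], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(fit@scores[, a], s * ora$T[, a], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(fit@loadings[, a], s * ora$P[, a], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(fit@yLoadings[1, a], s * ora$c[a], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("the orthogonal component recovers planted y-orthogonal variation", {
  set.seed(4)
  n <- 60; p <- 30
  w1 <- rnorm(p); w1 <- w1 / sqrt(sum(w1^2))
  w2 <- rnorm(p); w2 <- w2 - sum(w2 * w1) * w1; w2 <- w2 / sqrt(sum(w2^2))
  t1 <- rnorm(n); t2 <- rnorm(n)
  t2 <- t2 - sum(t2 * t1) * t1 / sum(t1^2)        # decorrelate from y
  X <- tcrossprod(t1, w1) + 2 * tcrossprod(t2, w2) +
    matrix(rnorm(n * p, sd = 0.01), n)
  y <- t1
  fit <- fitOpls(scale(X, scale = FALSE), y, nPredictive = 1, nOrthX = 1)
  expect_gt(abs(cor(fit@orthScores[, 1], t2)), 0.99)
  expect_lt(abs(cor(fit@orthScores[, 1], y)), 1e-8)
  expect_gt(r2y(fit), 0.99)
})

test_that("decomposition, orthogonality and R2Y invariants hold generically", {
  set.seed(6)
  for (i in 1:12) {
    n <- sample(8:20, 1); p <- sample(5:25, 1)
    m <- sample(c(1, 1, 3), 1)
    X <- scale(matrix(rnorm(n * p), n), scale = FALSE)
    Y <- matrix(rnorm(n * m), n)
    nP <- sample(1:2, 1); nO <- sample(0:2, 1)
    fit <- fitOpls(X, Y, nPredictive = nP, nOrthX = nO)

    # exact reconstruction X = T P' + To Po' + E
    rec <- fit@scores %*% t(fit@loadings) + fit@residuals
    if (nO > 0) rec <- rec + fit@orthScores %*% t(fit@orthLoadings)
    expect_equal(rec, X, tolerance = 1e-10, ignore_attr = TRUE)

    # score orthogonality (predictive and orthogonal, mutually)
    S <- cbind(fit@scores, fit@orthScores)
    G <- crossprod(S)
    offdiag <- G[upper.tri(G)]
    expect_lt(max(abs(offdiag) / max(diag(G))), 1e-8)

    # every orthogonal score has zero correlation with every response
    if (nO > 0) {
      Yc <- scale(Y, scale = FALSE)
      for (a in seq_len(nO))
        expect_lt(max(abs(cor(fit@orthScores[, a], Yc))), 1e-8)
    }
    expect_gte(fit@R2Y, 0); expect_lte(fit@R2Y, 1)
  }
})

test_that("removing orthogonal variation never hurts the training fit", {
  set.seed(8)
  for (i in 1:8) {
    X <- scale(matrix(rnorm(15 * 12), 15), scale = FALSE)
    y <- rnorm(15)
    r2 <- vapply(0:2, function(nO)
      r2y(fitOpls(X, y, nPredictive = 1, nOrthX = nO)), numeric(1))
    expect_true(all(diff(r2) >= -1e-10))
  }
})

test_that("unsupported and inconsistent inputs are rejected", {
  X <- matrix(rnorm(20), 5)
  expect_error(fitOpls(X, rnorm(5), nOrthY = 1), "not supported")
  expect_error(fitOpls(X, rnorm(4)), "misaligned")
  expect_error(fitOpls(X, rep(1, 5)), "no variance")
  # rank exhausted: more components than rank
  X1 <- cbind(c(1, 2, 3, 4, 5))
  expect_error(fitOpls(scale(X1, scale = FALSE), rnorm(5),
                       nPredictive = 1, nOrthX = 1), "rank-deficient")
})

test_that("S-plot covariance/correlation columns behave at the extremes", {
  set.seed(10)
  X <- scale(matrix(rnorm(100), 20), scale = FALSE)
  y <- X[, 1] + rnorm(20, sd = 0.2)
  fit <- fitOpls(X, y, nPredictive = 1)
  tt <- scores(fit)[, 1]
  # crafted matrix: a column equal to t, its negation, and a constant
  M <- cbind(t_like = tt, neg = -tt, const = rep(1, 20))
  sp <- sPlot(fit, M)
  expect_equal(sp$pCorr, c(1, -1, 0), tolerance = 1e-12)
  expect_identical(sp$flag, c(FALSE, FALSE, TRUE))
  # sign coherence on real data
  sp2 <- sPlot(fit, X)
  nz <- abs(sp2$pCov) > 1e-12 & !sp2$flag
  expect_true(all(sign(sp2$pCov[nz]) == sign(sp2$pCorr[nz])))
  expect_true(all(abs(sp2$pCorr) <= 1 + 1e-12))
})
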