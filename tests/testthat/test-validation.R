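test_that("cross-validated Q2 is near 1 for a noise-free linear response", {
  set.seed(1)
  X <- matrix(rnorm(60), 20)
  y <- X %*% c(1, -2, 0.5)
  expect_gt(crossValidatedQ2(X, y, components = c(3, 0, 0), folds = 5), 0.99)
})

test_that("cross-validated Q2 stays low when y is independent of X", {
  # 100 seeded replicates at n = 40: Q2 must not exceed 0.05 in >= 95%
  hits <- 0L
  for (s in 1:100) {
    set.seed(1000 + s)
    X <- matrix(rnorm(40 * 10), 40)
    y <- rnorm(40)
    q <- crossValidatedQ2(X, y, components = c(1, 0, 0), folds = 7,
                          seed = s)
    hits <- hits + (q <= 0.05)
  }
  expect_gte(hits, 95L)
})

test_that("leave-one-out cross-validation equals the brute-force oracle", {
  set.seed(2)
  X <- matrix(rnorm(14 * 6), 14)
  y <- X[, 1] - X[, 4] + rnorm(14, sd = 0.3)
  q <- crossValidatedQ2(X, y, components = c(1, 1, 0), folds = 14, seed = 9)
  expect_equal(q, looQ2Oracle(X, y, c(1, 1)), tolerance = 1e-10)
})

test_that("OPLS-DA separates separable classes and attaches Q2", {
  # disjoint bucket patterns: class A lives on columns 1-3, B on 4-6
  set.seed(3)
  n <- 20
  X <- rbind(cbind(matrix(abs(rnorm(30, 10, 0.5)), 10), matrix(0, 10, 3)),
             cbind(matrix(0, 10, 3), matrix(abs(rnorm(30, 10, 0.5)), 10)))
  lab <- rep(c("A", "B"), each = 10)
  fit <- fitOplsda(scaleColumns(X, "pareto"), lab, components = c(1, 0, 0),
                   folds = 5)
  expect_gt(r2y(fit), 0.99)
  expect_gt(q2(fit), 0.9)
  expect_true(fit@da)
  expect_identical(fit@classes, c("A", "B"))
  # positive class sits on positive scores
  expect_true(all(scores(fit)[lab == "B", 1] > 0))

  expect_error(fitOplsda(X, rep("A", n)), "two classes")
  expect_error(fitOplsda(X, lab, folds = 11), "at least")
})

test_that("the synthetic cohort meets the OPLS-DA suitability rule", {
  coh <- quietCohort(seed = 1)
  fit <- fitOplsda(paretoScale(coh$buckets), coh$classes)
  expect_gt(r2y(fit), 0.65)
  expect_gt(q2(fit), 0.5)
  # sanity envelope, not a theorem: Q2 does not exceed R2Y by much
  expect_lte(q2(fit), r2y(fit) + 0.05)
})

test_that("shuffled labels destroy Q2", {
  # at the cohort's stated size (40 + 40) label shuffling must leave no
  # predictive power in >= 95% of replicates
  coh <- quietCohort(seed = 2)
  Xs <- paretoScale(coh$buckets)
  hits <- 0L
  for (s in 1:20) {
    set.seed(2000 + s)
    lab <- sample(as.character(coh$classes))
    q <- crossValidatedQ2(Xs@values,
                          as.numeric(factor(lab)) - 1,
                          components = c(1, 2, 0), folds = 7, seed = s,
                          stratify = lab)
    hits <- hits + (q <= 0.05)
  }
  expect_gte(hits, 19L)  # >= 95%
})

test_that("permutation summary reproduces identity-permutation metrics", {
  coh <- quietCohort(nPerClass = 8, seed = 5)
  Xs <- paretoScale(coh$buckets)
  fit <- fitOplsda(Xs, coh$classes, folds = 5, seed = 7)
  # refitting with the labels "permuted" by the identity must reproduce
  # the original metrics exactly (same settings, same CV seed)
  y <- as.numeric(coh$classes == levels(coh$classes)[2])
  refit <- fitOpls(Xs@values, y, nPredictive = 1, nOrthX = 2)
  expect_equal(r2y(refit), r2y(fit), tolerance = 1e-12)
  q2again <- crossValidatedQ2(Xs@values, y, c(1, 2, 0), folds = 5,
                              seed = 7, stratify = coh$classes)
  expect_equal(q2again, q2(fit), tolerance = 1e-12)
})

test_that("permutation intercepts are computed by OLS and gate validity", {
  coh <- quietCohort(nPerClass = 10, seed = 4)
  Xs <- paretoScale(coh$buckets)
  pm <- permutationTest(Xs, coh$classes, nPerm = 30, folds = 5, seed = 11)
  expect_equal(nrow(pm@permuted), 30L)
  # recompute both intercepts from the per-permutation table
  x <- c(pm@permuted$correlation, 1)
  r2i <- unname(coef(lm(c(pm@permuted$R2Y, pm@originalR2Y) ~ x))[1])
  q2i <- unname(coef(lm(c(pm@permuted$Q2, pm@originalQ2) ~ x))[1])
  expect_equal(pm@R2Intercept, r2i, tolerance = 1e-12)
  expect_equal(pm@Q2Intercept, q2i, tolerance = 1e-12)
  expect_identical(pm@valid, r2i < 0.3 && q2i < 0.05)
  # a planted cohort must beat every permuted Q2
  expect_true(all(pm@permuted$Q2 < pm@originalQ2))

  expect_error(permutationTest(Xs, coh$classes, nPerm = 5), "at least 20")
  expect_error(permutationTest(Xs, rep("A", 20)), "two classes")
})

test_that("Q2 intercept of noise data stays below threshold across seeds", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(3000 + s)
    X <- matrix(rnorm(24 * 15), 24)
    lab <- rep(c("A", "B"), each = 12)
    pm <- permutationTest(X, lab, components = c(1, 0, 0), nPerm = 20,
                          folds = 4, seed = s)
    hits <- hits + (pm@Q2Intercept < 0.05)
  }
  expect_gte(hits, 45L)  # >= 90% of 50 replicates
})
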