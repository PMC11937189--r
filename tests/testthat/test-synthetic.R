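test_that("a noiseless single-singlet compound projects deterministically", {
  prof <- compoundProfile("solo", list(multiplet(2.30, "s", nProtons = 3)),
                          classMeans = c(GR = 2, PGR = 2), cv = 0,
                          gcResponse = 100, rtMin = 10)
  coh <- generateCohort(cohortConfig(nPerClass = 2, profiles = list(prof),
                                     baselineSd = 0, seed = 1))
  B <- bucketValues(coh$buckets)
  expect_equal(unname(B[, "2.30"]), rep(2 * 3, 4))
  expect_true(all(B[, colnames(B) != "2.30"] == 0))
})

test_that("generation is deterministic in the seed and leaves the RNG alone", {
  c1 <- quietCohort(nPerClass = 4, seed = 7)
  c2 <- quietCohort(nPerClass = 4, seed = 7)
  expect_identical(bucketValues(c1$buckets), bucketValues(c2$buckets))
  expect_identical(peakAreas(c1$peaks), peakAreas(c2$peaks))
  expect_identical(c1$truth$concentrations, c2$truth$concentrations)

  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(quietCohort(nPerClass = 3, seed = 1))
  expect_identical(rnorm(3), before)

  c3 <- quietCohort(nPerClass = 4, seed = 8)
  expect_false(identical(bucketValues(c1$buckets), bucketValues(c3$buckets)))
})

test_that("default profiles encode the processing chemistry", {
  prof <- defaultGingerProfiles()
  nm <- vapply(prof, function(p) p@name, character(1))
  cur <- prof[[which(nm == "ar-Curcumene")]]
  zin <- prof[[which(nm == "alpha-Zingiberene")]]
  # processing doubles ar-curcumene (0.65 -> 1.30) and lowers zingiberene
  expect_equal(unname(cur@classMeans["PGR"] / cur@classMeans["GR"]), 2.0)
  expect_equal(unname(zin@classMeans), c(1.19, 0.85))
  expect_gt(zin@classMeans[["GR"]], zin@classMeans[["PGR"]])

  # every profile projects onto at least one bucket of the default grid
  g <- defaultBucketGrid()
  for (p in prof) {
    buckets <- unique(unlist(lapply(p@multiplets, function(m)
      tryCatch(multipletToBuckets(m, g), error = function(e) numeric()))))
    expect_gt(length(buckets), 0)
  }
})

test_that("ground truth round-trips: planted buckets regress to R2 ~ 1", {
  coh <- generateCohort(cohortConfig(nPerClass = 10,
                                     profiles = defaultGingerProfiles(cv = 0.2),
                                     baselineSd = 1e-9, seed = 3))
  B <- bucketValues(coh$buckets)
  conc <- coh$truth$concentrations
  proj <- coh$truth$projection
  # noise-free bucket block is exactly conc %*% t(proj); with negligible
  # baseline noise the regression of each planted bucket on the known
  # concentrations is essentially perfect
  planted <- which(rowSums(proj) > 0)
  set.seed(4)
  for (j in sample(planted, 10)) {
    fitted <- conc %*% proj[j, ]
    r2 <- 1 - sum((B[, j] - fitted)^2) / sum((B[, j] - mean(B[, j]))^2)
    expect_gt(r2, 0.999999)
  }
})

test_that("emitted spectra re-bucket to the planted projection", {
  coh <- generateCohort(cohortConfig(nPerClass = 3, seed = 5),
                        emitSpectra = TRUE)
  bm <- buildBucketMatrix(coh$spectra, normalize = FALSE, reference = FALSE)
  B0 <- coh$truth$concentrations %*% t(coh$truth$projection)
  got <- bucketValues(bm)
  # narrow lines keep > 99.9% of their mass inside their bucket
  expect_equal(unname(got), unname(B0), tolerance = 2e-3)
})

test_that("cohort output containers are consistent and GC-selective", {
  coh <- quietCohort(nPerClass = 5, seed = 2)
  expect_identical(sampleIds(coh$buckets), sampleIds(coh$peaks))
  expect_identical(levels(coh$classes), c("GR", "PGR"))
  # sugars are not in the hexane-extract GC block
  expect_false(any(c("Sucrose", "Glucose") %in% compounds(coh$peaks)$name))
  expect_equal(ncol(peakAreas(coh$peaks)), 7L)
  expect_false(coh$peaks@standardized)
  expect_true(all(peakAreas(coh$peaks) >= 0))

  expect_error(cohortConfig(nPerClass = 1), "at least 2")
  expect_error(cohortConfig(classes = c("A", "A")), "distinct")
})
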