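test_that("raw heatmap equals the brute-force Pearson oracle", {
  bl <- makeBlocks(n = 15, nb = 8, nc = 4, seed = 21)
  hm <- correlationHeatmap(bl$bm, bl$pt)
  expect_equal(unname(hm@r),
               pearsonOracle(bucketValues(bl$bm), peakAreas(bl$pt)),
               tolerance = 1e-12)
  expect_identical(hm@mode, "raw")
  expect_true(all(abs(hm@r) <= 1))
})

test_that("perfect positive and negative links hit r = +/-1", {
  bl <- makeBlocks(n = 10, nb = 4, nc = 2, seed = 22)
  A <- cbind(bucketValues(bl$bm)[, 2],          # equals a bucket column
             max(bucketValues(bl$bm)) - bucketValues(bl$bm)[, 3])  # negated
  pt <- PeakTable(A, sampleIds(bl$bm), c("same", "anti"))
  hm <- correlationHeatmap(bl$bm, pt)
  expect_equal(hm@r[2, 1], 1, tolerance = 1e-12)
  expect_equal(hm@r[3, 2], -1, tolerance = 1e-12)
})

test_that("a planted r = 0.8 association is estimated within +/-0.12", {
  set.seed(23)
  n <- 80
  z <- rnorm(n); e <- rnorm(n)
  b1 <- 10 + z
  c1 <- 5 + 0.8 * z + sqrt(1 - 0.8^2) * e     # cor = 0.8 by construction
  bm <- BucketMatrix(cbind(b1, abs(rnorm(n, 10))), sprintf("s%02d", 1:n),
                     c(3.02, 2.02), grid = bucketGrid(0, 10, 0.04))
  pt <- PeakTable(cbind(c1 - min(c1) + 1), sprintf("s%02d", 1:n), "comp")
  hm <- correlationHeatmap(bm, pt)
  expect_equal(hm@r[1, 1], 0.8, tolerance = 0.12)
})

test_that("the heatmap is invariant to a consistent sample reordering", {
  bl <- makeBlocks(n = 12, nb = 5, nc = 3, seed = 24)
  hm1 <- correlationHeatmap(bl$bm, bl$pt)
  set.seed(77)
  o <- sample(seq_len(12))
  bm2 <- BucketMatrix(bucketValues(bl$bm)[o, ], sampleIds(bl$bm)[o],
                      bucketLabels(bl$bm), grid = bl$bm@grid)
  # peak table left in the original order: alignment is by sample id
  hm2 <- correlationHeatmap(bm2, bl$pt)
  expect_equal(hm2@r, hm1@r, tolerance = 1e-12)
})

test_that("fusion fits, flags sample mismatches and handles exact links", {
  # one compound exactly proportional to one bucket: perfect fit
  bl <- makeBlocks(n = 12, nb = 6, nc = 1, seed = 25)
  pt <- PeakTable(cbind(2 * bucketValues(bl$bm)[, 4]), sampleIds(bl$bm),
                  "driver")
  # the response lies in the column space of X, so a full-rank predictive
  # fit reproduces it exactly
  fit <- fuseBlocks(bl$bm, pt, components = c(6, 0, 0))
  expect_gt(r2y(fit), 1 - 1e-8)

  # default generator, seed 1: signal present
  coh <- quietCohort(seed = 1)
  ff <- fuseBlocks(coh$buckets, coh$peaks)
  expect_gt(q2(ff), 0)
  expect_gt(r2y(ff), 0)

  bad <- PeakTable(matrix(1, 3, 1), c("x1", "x2", "x3"), "c")
  expect_error(fuseBlocks(bl$bm, bad), "sample sets differ")
})

test_that("filtered mode removes orthogonal variation but keeps r in range", {
  coh <- quietCohort(nPerClass = 10, seed = 6)
  fit <- fuseBlocks(coh$buckets, coh$peaks)
  hm <- correlationHeatmap(coh$buckets, coh$peaks, mode = "opls_filtered",
                           model = fit)
  expect_identical(hm@mode, "opls_filtered")
  expect_true(all(abs(hm@r) <= 1))
  expect_error(correlationHeatmap(coh$buckets, coh$peaks,
                                  mode = "opls_filtered"), "needs a fitted")
})

test_that("marker ranking finds planted buckets, honors ties and topN", {
  # cohort in which one compound drives exactly the four buckets the
  # aromatic + methyl signals of the processed-class marker occupy
  marker <- compoundProfile(
    "marker",
    list(multiplet(7.06, "s"), multiplet(7.02, "s"),
         multiplet(2.34, "s"), multiplet(2.30, "s")),
    classMeans = c(GR = 0.6, PGR = 1.4), gcResponse = 1000, rtMin = 17.5,
    cv = 0.2)
  filler <- compoundProfile(
    "filler", list(multiplet(1.30, "s", nProtons = 6)),
    classMeans = c(GR = 5, PGR = 5), gcResponse = 800, rtMin = 30, cv = 0.2)
  coh <- generateCohort(cohortConfig(nPerClass = 20,
                                     profiles = list(marker, filler),
                                     seed = 8))
  hm <- correlationHeatmap(coh$buckets, coh$peaks)
  top4 <- rankBucketsForCompound(hm, "marker", topN = 4)
  expect_setequal(round(top4$bucket, 2), c(7.06, 7.02, 2.34, 2.30))
  expect_true(all(diff(top4$r) <= 1e-12))

  expect_equal(nrow(rankBucketsForCompound(hm, "marker", topN = 0)), 0L)
  expect_error(rankBucketsForCompound(hm, "nope"), "unknown compound")

  # exact ties order by descending ppm
  hm2 <- new("CorrelationHeatmap", r = matrix(c(1, 0.5, 1), 3, 1),
             bucketLabels = c(7.06, 3.02, 2.34), compoundNames = "c",
             mode = "raw", flags = matrix(FALSE, 3, 1))
  r2 <- rankBucketsForCompound(hm2, "c", topN = 2)
  expect_equal(r2$bucket, c(7.06, 2.34))
})

test_that("marker report annotates buckets with reference multiplets", {
  tab <- readMultipletTable(system.file("extdata", "ginger_multiplets.tsv",
                                        package = "oplsFusion"))
  coh <- quietCohort(nPerClass = 15, seed = 9)
  hm <- correlationHeatmap(coh$buckets, coh$peaks)
  rep <- rankBucketsForCompound(hm, "ar-Curcumene", topN = 5,
                                multipletTable = tab)
  expect_true("candidates" %in% names(rep))
  # the top curcumene bucket must name a curcumene multiplet as candidate
  expect_match(paste(rep$candidates, collapse = " "), "ar-Curcumene")
})

test_that("heatmap recovery: each compound's best bucket is its own", {
  for (s in 1:5) {
    coh <- quietCohort(nPerClass = 20, seed = 100 + s)
    hm <- correlationHeatmap(coh$buckets, coh$peaks)
    for (cp in compounds(coh$peaks)$name) {
      top <- rankBucketsForCompound(hm, cp, topN = 1)
      expect_true(top$bucket %in% coh$truth$markerBuckets[[cp]],
                  info = paste(s, cp))
    }
  }
})

test_that("heatmap and model exports write the promised files", {
  coh <- quietCohort(nPerClass = 5, seed = 10)
  # tiny cohort: some empty buckets are constant, so Pareto flags them
  hm <- suppressWarnings(correlationHeatmap(coh$buckets, coh$peaks))
  base <- tempfile()
  writeHeatmap(hm, base)
  expect_true(file.exists(paste0(base, ".csv")))
  long <- read.delim(paste0(base, ".long.tsv"))
  expect_identical(names(long), c("bucket", "compound", "r"))
  expect_equal(nrow(long), 240L * ncol(peakAreas(coh$peaks)))

  d <- tempfile()
  Xs <- suppressWarnings(paretoScale(coh$buckets))
  fit <- fitOplsda(Xs, coh$classes, folds = 3)
  writeOplsModel(fit, d, X = Xs)
  expect_true(all(file.exists(file.path(d, c("scores_predictive.tsv",
                                             "loadings_orthogonal.tsv",
                                             "splot.tsv", "model.json")))))
  js <- jsonlite::read_json(file.path(d, "model.json"))
  expect_equal(js$R2Y, r2y(fit), tolerance = 1e-12)
})
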