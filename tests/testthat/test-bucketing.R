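test_that("solvent referencing shifts the axis by the window-argmax offset", {
  # Lorentzian centred at 3.32: argmax of the synthesized line sits on the
  # grid point nearest 3.32, so the whole axis must shift by -0.02
  s <- synthSpectrum(3.32, 1, widths = 0.01, by = 0.002, shape = "lorentz")
  ref <- referenceToSolvent(s, 3.30, c(3.1, 3.5))
  expect_equal(ref@ppm, s@ppm - 0.02, tolerance = 1e-12)
  expect_identical(ref@intensity, s@intensity)

  # already on target: identical axis
  s2 <- synthSpectrum(3.30, 1, widths = 0.01, by = 0.002)
  expect_equal(referenceToSolvent(s2)@ppm, s2@ppm)

  # window beyond the spectral support
  s3 <- Spectrum1D(seq(0, 7, 0.01), rep(1, 701), "narrow")
  expect_error(referenceToSolvent(s3, searchWindow = c(8.0, 8.2)),
               "no solvent peak")
})

test_that("total-integral normalization hits the target and is idempotent", {
  flat <- Spectrum1D(seq(0, 10, 0.01), rep(1, 1001), "flat")
  norm <- totalIntegralNormalize(flat, 100)
  expect_equal(unique(norm@intensity), 10)

  two <- synthSpectrum(c(2.3, 7.1), c(3, 1), widths = 0.02)
  n1 <- totalIntegralNormalize(two, 100)
  expect_equal(trapzOracle(n1@ppm, abs(n1@intensity)), 100,
               tolerance = 1e-9)
  n2 <- totalIntegralNormalize(n1, 100)
  expect_equal(n2@intensity, n1@intensity, tolerance = 1e-12)

  zero <- Spectrum1D(c(0, 1), c(0, 0), "empty")
  expect_error(totalIntegralNormalize(zero), "not positive")
})

test_that("bucket integration matches trapezoid quadrature bin by bin", {
  gridAll <- bucketGrid(0, 10, 0.04)
  flat <- Spectrum1D(seq(0, 10, 0.01), rep(1, 1001), "flat")
  v <- bucketSpectrum(flat, gridAll)
  expect_length(v, 250)
  expect_equal(unname(v), rep(0.04, 250), tolerance = 1e-12)

  # default grid with water cut: 240 buckets
  expect_length(bucketSpectrum(flat, defaultBucketGrid()), 240)

  # unit-area Gaussian at a bucket centre: mass stays in its bucket
  g <- synthSpectrum(2.30, 1, widths = 0.004, by = 5e-4)
  v <- bucketSpectrum(g, defaultBucketGrid())
  expect_equal(sum(v), 1, tolerance = 1e-6)
  expect_gt(v[["2.30"]], 0.95)

  # conservation: bucket sum equals the full integral over the grid range
  set.seed(7)
  ppm <- sort(runif(400, 0, 10))
  ppm <- c(0, ppm, 10)
  y <- abs(rnorm(length(ppm)))
  sp <- Spectrum1D(ppm, y, "rand")
  vv <- bucketSpectrum(sp, gridAll)
  expect_equal(sum(vv), trapzOracle(ppm, y), tolerance = 1e-9)

  expect_error(bucketSpectrum(Spectrum1D(c(11, 12), c(1, 1), "off"),
                              gridAll), "overlap")
})

test_that("water exclusion drops exactly the overlapped bins", {
  g <- bucketGrid(0, 10, 0.04)
  expect_equal(nBuckets(g), 250)
  gw <- excludeWater(g, c(4.60, 5.00))
  expect_equal(nBuckets(gw), 240)
  dropped <- setdiff(round(bucketLabels(g), 10), round(bucketLabels(gw), 10))
  expect_equal(sort(dropped), seq(4.62, 4.98, by = 0.04), tolerance = 1e-9)

  # disjoint interval is a no-op
  expect_equal(bucketLabels(excludeWater(g, c(20, 21))), bucketLabels(g))

  # matrix method drops the columns too
  m <- BucketMatrix(matrix(1, 2, 250), c("a", "b"), bucketLabels(g),
                    grid = g)
  m2 <- excludeWater(m, c(4.60, 5.00))
  expect_equal(ncol(bucketValues(m2)), 240)
})

test_that("multiplet projection reproduces the reference bucket lists", {
  expect_equal(multipletToBuckets(multiplet(2.27, "t", 7.4)), c(2.30, 2.26))
  expect_equal(multipletToBuckets(multiplet(6.89, "dt", c(15.9, 7.0))),
               c(6.94, 6.90, 6.86))
  expect_equal(multipletToBuckets(multiplet(range = c(2.45, 2.59),
                                            pattern = "m")),
               c(2.58, 2.54, 2.50, 2.46))
  expect_equal(multipletToBuckets(multiplet(3.82, "s")), 3.82)

  expect_error(multipletToBuckets(multiplet(2.27, "t")), "requires")
  expect_error(multipletToBuckets(multiplet(0.01, "t", 400)), "cover")
})

test_that("projection is contiguous and dd is symmetric in its J pair", {
  set.seed(11)
  g <- defaultBucketGrid(water = FALSE)
  for (i in 1:50) {
    ctr <- runif(1, 0.5, 9.5)
    pat <- sample(c("d", "t", "q", "dd", "dt", "sext"), 1)
    J <- sort(runif(2, 1, 16), decreasing = TRUE)
    m <- multiplet(ctr, pat, J)
    b <- multipletToBuckets(m, g)
    # contiguity on the 0.04 lattice
    expect_equal(diff(b), rep(-0.04, length(b) - 1), tolerance = 1e-9)
    if (pat == "dd")
      expect_equal(multipletToBuckets(multiplet(ctr, "dd", rev(J)), g), b)
  }
})

test_that("packaged multiplet table rows that follow the span rule match", {
  tab <- readMultipletTable(system.file("extdata", "ginger_multiplets.tsv",
                                        package = "oplsFusion"))
  sub <- tab[tab$span_rule, ]
  expect_gt(nrow(sub), 25)
  for (i in seq_len(nrow(sub))) {
    got <- formatC(multipletToBuckets(sub$multiplet[[i]]), format = "f",
                   digits = 2)
    want <- trimws(strsplit(sub$buckets_printed[i], ",")[[1]])
    expect_equal(got, want,
                 info = paste(sub$compound[i], sub$position[i]))
  }
})

test_that("bucket matrix assembly keeps order, shape and error context", {
  specs <- lapply(1:3, function(i)
    synthSpectrum(c(3.30, 2.30, 7.1), c(5, 2, 1), widths = 0.01,
                  by = 0.002, sampleId = paste0("S", i)))
  bm <- buildBucketMatrix(specs)
  expect_s4_class(bm, "BucketMatrix")
  expect_equal(dim(bucketValues(bm)), c(3L, 240L))
  expect_equal(sampleIds(bm), c("S1", "S2", "S3"))
  # identical inputs give identical rows
  expect_equal(bucketValues(bm)[1, ], bucketValues(bm)[3, ])
  # labels descend
  expect_true(all(diff(bucketLabels(bm)) < 0))

  bad <- c(specs[1], list(Spectrum1D(c(0, 1), c(0, 0), "broken")))
  expect_error(buildBucketMatrix(bad, reference = FALSE), "broken")
})

test_that("bucket matrix CSV round-trips with two-decimal descending labels", {
  coh <- quietCohort(nPerClass = 2, seed = 3)
  f <- tempfile(fileext = ".csv")
  writeBucketMatrix(coh$buckets, f)
  hdr <- strsplit(readLines(f, n = 1), ",")[[1]]
  expect_identical(hdr[1], "sample_id")
  expect_identical(hdr[2], "9.98")
  back <- readBucketMatrix(f, grid = coh$buckets@grid)
  expect_equal(bucketValues(back), bucketValues(coh$buckets),
               tolerance = 1e-12)
})
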