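#' @include AllClasses.R AllGenerics.R
NULL

## ---- grid internals -------------------------------------------------------

.nBins <- function(grid) as.integer(round((grid@hi - grid@lo) / grid@width))

## midpoint of 0-based bin k; single definition so labels compare exactly
## across bucketLabels(), bucketSpectrum() and multipletToBuckets()
.binMid <- function(grid, k) grid@lo + k * grid@width + grid@width / 2

.binStarts <- function(grid) grid@lo + (seq_len(.nBins(grid)) - 1L) * grid@width

## keep = no positive-measure overlap with any exclusion interval; a bin that
## merely touches an exclusion endpoint is kept (this is what makes the water
## cut delta 5.00-4.60 drop exactly the ten bins 4.62...4.98)
.binKeep <- function(grid) {
  lo <- .binStarts(grid); hi <- lo + grid@width
  keep <- rep(TRUE, length(lo))
  ex <- grid@exclusions
  for (i in seq_len(nrow(ex)))
    keep <- keep & !(lo < ex[i, 2L] - 1e-12 & hi > ex[i, 1L] + 1e-12)
  keep
}

#' Number of (non-excluded) buckets of a grid
#'
#' @param grid A \linkS4class{BucketGrid}.
#' @return Integer bucket count.
#' @examples
#' nBuckets(defaultBucketGrid())  # 240
#' @export
nBuckets <- function(grid) sum(.binKeep(grid))

#' @describeIn bucketLabels Labels of the non-excluded bins of a grid,
#'   descending ppm.
#' @export
setMethod("bucketLabels", "BucketGrid", function(x, ...) {
  mids <- .binMid(x, seq_len(.nBins(x)) - 1L)
  rev(mids[.binKeep(x)])
})

#' @describeIn bucketLabels Column labels of a bucketed matrix.
#' @export
setMethod("bucketLabels", "BucketMatrix", function(x, ...) x@bucketLabels)

#' @describeIn excludeWater Add an exclusion interval to a grid.
#' @export
setMethod("excludeWater", "BucketGrid", function(x, interval = c(4.60, 5.00)) {
  iv <- sort(as.numeric(interval)[1:2])
  iv[1L] <- max(iv[1L], x@lo); iv[2L] <- min(iv[2L], x@hi)
  if (iv[1L] >= iv[2L]) return(x)          # disjoint from the grid: no-op
  bucketGrid(x@lo, x@hi, x@width,
             exclusions = c(asplit(x@exclusions, 1L), list(iv)))
})

#' @describeIn excludeWater Drop the overlapped bucket columns from a
#'   matrix (and record the exclusion on its grid).
#' @export
setMethod("excludeWater", "BucketMatrix", function(x, interval = c(4.60, 5.00)) {
  g2 <- excludeWater(x@grid, interval)
  keep <- x@bucketLabels %in% bucketLabels(g2)
  BucketMatrix(x@values[, keep, drop = FALSE], x@sampleIds,
               x@bucketLabels[keep], grid = g2)
})

## ---- spectrum operations --------------------------------------------------

#' Reference a spectrum to a solvent signal
#'
#' Uniformly shifts the ppm axis so that the maximum-intensity point inside
#' \code{searchWindow} sits exactly at \code{solventPpm}. The default window
#' and target implement referencing to residual CH3OH at delta 3.30.
#'
#' @param spec A \linkS4class{Spectrum1D}.
#' @param solventPpm Target chemical shift of the solvent line (ppm).
#' @param searchWindow Length-2 ppm window searched for the solvent maximum.
#' @return The spectrum with a shifted ppm axis; intensities unchanged.
#' @examples
#' ppm <- seq(0, 10, by = 0.002)
#' s <- Spectrum1D(ppm, dnorm(ppm, 3.32, 0.01), "S1")
#' referenceToSolvent(s)   # axis shifted by -0.02
#' @export
referenceToSolvent <- function(spec, solventPpm = 3.30,
                               searchWindow = c(3.25, 3.35)) {
  w <- sort(as.numeric(searchWindow)[1:2])
  idx <- which(spec@ppm >= w[1L] & spec@ppm <= w[2L])
  if (!length(idx)) stop("no solvent peak in window [", w[1L], ", ", w[2L], "]")
  peak <- spec@ppm[idx[which.max(spec@intensity[idx])]]
  Spectrum1D(spec@ppm + (solventPpm - peak), spec@intensity, spec@sampleId)
}

## exact trapezoidal integral of the linear interpolant over its support
.trapz <- function(x, y) sum(diff(x) * (head(y, -1L) + y[-1L])) / 2

#' Normalize a spectrum to a constant total integral
#'
#' Scales the intensities so that the trapezoidal integral of the absolute
#' intensity over the full axis equals \code{targetTotal} ("total integral
#' mode" constant-sum normalization). Idempotent for the same target.
#'
#' @param spec A \linkS4class{Spectrum1D}.
#' @param targetTotal Target total integral (default 100).
#' @return The rescaled spectrum.
#' @export
totalIntegralNormalize <- function(spec, targetTotal = 100) {
  tot <- .trapz(spec@ppm, abs(spec@intensity))
  if (!is.finite(tot) || tot <= 0)
    stop("total integral of spectrum '", spec@sampleId,
         "' is not positive; cannot normalize")
  Spectrum1D(spec@ppm, spec@intensity * (targetTotal / tot), spec@sampleId)
}

#' Integrate a spectrum over a bucket grid
#'
#' Each non-excluded bin receives the exact trapezoidal integral of the
#' spectrum's linear interpolant over that bin; bins outside the spectral
#' support integrate to zero (no extrapolation).
#'
#' @param spec A \linkS4class{Spectrum1D}.
#' @param grid A \linkS4class{BucketGrid}.
#' @return Named numeric vector, one integral per non-excluded bucket, in
#'   descending ppm order; names are two-decimal bucket labels.
#' @export
bucketSpectrum <- function(spec, grid) {
  sup <- range(spec@ppm)
  if (sup[2L] <= grid@lo || sup[1L] >= grid@hi)
    stop("spectrum '", spec@sampleId, "' does not overlap the bucket grid")
  edges <- c(.binStarts(grid), grid@hi)
  inset <- edges[edges > sup[1L] & edges < sup[2L]]
  xall <- sort(unique(c(spec@ppm, inset)))
  yall <- stats::approx(spec@ppm, spec@intensity, xout = xall)$y
  Fcum <- c(0, cumsum(diff(xall) * (head(yall, -1L) + yall[-1L]) / 2))
  Fat <- function(x) {                       # integral from support start to x
    x <- pmin(pmax(x, sup[1L]), sup[2L])
    Fcum[match(x, xall)]
  }
  a <- pmin(pmax(edges[-length(edges)], sup[1L]), sup[2L])
  b <- pmin(pmax(edges[-1L], sup[1L]), sup[2L])
  vals <- Fat(b) - Fat(a)
  keep <- .binKeep(grid)
  out <- rev(vals[keep])
  names(out) <- formatBucketLabel(bucketLabels(grid))
  out
}

## ---- multiplet projection -------------------------------------------------

## J-span of a multiplicity pattern, in Hz (outer-line to outer-line)
.multipletSpanHz <- function(pattern, J) {
  need <- function(n) if (length(J) < n)
    stop("pattern '", pattern, "' requires ", n, " coupling constant(s)")
  switch(pattern,
         s = , brs = 0,
         d = { need(1L); J[1L] },
         t = , brt = { need(1L); 2 * J[1L] },
         q = { need(1L); 3 * J[1L] },
         sext = { need(1L); 5 * J[1L] },
         dd = { need(2L); J[1L] + J[2L] },
         dt = { need(2L); J[1L] + 2 * J[2L] },
         m = 0,                              # centre-only multiplet: point
         stop("unknown pattern '", pattern, "'"))
}

#' Project a multiplet onto the bucket lattice
#'
#' Computes the ppm interval covered by a multiplet -- the outer-line span of
#' its coupling pattern (s/brs: 0; d: J1; t/brt: 2J1; q: 3J1; sext: 5J1;
#' dd: J1+J2; dt: J1+2J2) converted from Hz at the spectrometer frequency
#' and centred on its chemical shift, or the explicit range for multiplets
#' reported as ranges -- and returns the labels of every non-excluded bin it
#' overlaps. The interval is closed against half-open bins, so an endpoint
#' exactly on a bin edge counts into the higher bin.
#'
#' @param m A \linkS4class{Multiplet}.
#' @param grid A \linkS4class{BucketGrid} (default: the 0.04 ppm delta 0-10
#'   grid with water excluded).
#' @param extraHz Optional extra half-width in Hz added on each side to
#'   account for intrinsic linewidth (default 0).
#' @return Numeric bucket labels in descending ppm order.
#' @examples
#' multipletToBuckets(multiplet(2.27, "t", J = 7.4, field = 400))  # 2.30 2.26
#' multipletToBuckets(multiplet(6.89, "dt", J = c(15.9, 7.0)))     # 6.94 6.90 6.86
#' multipletToBuckets(multiplet(range = c(2.45, 2.59), pattern = "m"))
#' @export
multipletToBuckets <- function(m, grid = defaultBucketGrid(), extraHz = 0) {
  iv <- if (!is.null(m@range)) {
    m@range + c(-1, 1) * extraHz / m@field
  } else {
    half <- (.multipletSpanHz(m@pattern, m@J) / 2 + extraHz) / m@field
    m@center + c(-half, half)
  }
  if (iv[1L] < grid@lo - 1e-9 || iv[2L] > grid@hi + 1e-9)
    stop("grid does not cover the multiplet span [",
         signif(iv[1L], 6), ", ", signif(iv[2L], 6), "]")
  q <- (iv - grid@lo) / grid@width
  kLo <- floor(q[1L] + 1e-9)                  # endpoint on an edge -> higher bin
  kHi <- min(floor(q[2L] + 1e-9), .nBins(grid) - 1L)
  keep <- .binKeep(grid)
  ks <- seq.int(kLo, kHi)
  ks <- ks[keep[ks + 1L]]
  rev(.binMid(grid, ks))
}

## ---- matrix assembly ------------------------------------------------------

#' Build the bucketed data matrix from a set of spectra
#'
#' Applies, per spectrum and in this order: solvent referencing, total-
#' integral normalization, bucket integration and exclusion-region removal,
#' then stacks the bucket vectors into a \linkS4class{BucketMatrix} (rows in
#' input order). With the defaults this reproduces the standard profiling
#' matrix: CH3OH referencing at delta 3.30, constant total integral, 0.04 ppm
#' bins over delta 0-10 and the water cut, i.e. 240 buckets.
#'
#' @param specs List of \linkS4class{Spectrum1D}.
#' @param grid A \linkS4class{BucketGrid}.
#' @param normalize Apply total-integral normalization? Default \code{TRUE}.
#' @param reference Apply solvent referencing? Default \code{TRUE}.
#' @param targetTotal Total integral after normalization (default 100).
#' @param solventPpm,searchWindow Passed to \code{\link{referenceToSolvent}}.
#' @return A \linkS4class{BucketMatrix}.
#' @export
buildBucketMatrix <- function(specs, grid = defaultBucketGrid(),
                              normalize = TRUE, reference = TRUE,
                              targetTotal = 100, solventPpm = 3.30,
                              searchWindow = c(3.25, 3.35)) {
  if (!length(specs)) stop("need at least one spectrum")
  rows <- lapply(specs, function(s) {
    tryCatch({
      if (reference)
        s <- referenceToSolvent(s, solventPpm, searchWindow)
      if (normalize)
        s <- totalIntegralNormalize(s, targetTotal)
      bucketSpectrum(s, grid)
    }, error = function(e)
      stop("sample '", s@sampleId, "': ", conditionMessage(e), call. = FALSE))
  })
  BucketMatrix(do.call(rbind, rows),
               vapply(specs, function(s) s@sampleId, character(1)),
               bucketLabels(grid), grid = grid)
}

#' @describeIn sampleIds Row ids of a bucket matrix.
#' @export
setMethod("sampleIds", "BucketMatrix", function(x) x@sampleIds)

#' @describeIn sampleIds Sample id of a spectrum.
#' @export
setMethod("sampleIds", "Spectrum1D", function(x) x@sampleId)

#' @describeIn bucketValues Samples x buckets matrix.
#' @export
setMethod("bucketValues", "BucketMatrix", function(x) x@values)
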