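#' @include AllClasses.R bucketing.R validate.R
NULL

#' Reference compound profiles for the simulated ginger cohort
#'
#' Nine constituents of dried (GR) versus steamed/processed (PGR) ginger
#' rhizome with literature-style multiplet definitions (400 MHz), GC
#' response factors and class-dependent mean concentrations. Directionality
#' follows the known processing chemistry: alpha-zingiberene is oxidized to
#' ar-curcumene during processing, so zingiberene is higher in GR
#' (means 1.19 vs 0.85) and ar-curcumene higher in PGR (0.65 vs 1.30,
#' a 2.0-fold increase); [6]-gingerol dehydrates toward [6]-shogaol.
#' Sugars and fatty acids are class-neutral bulk constituents; the sugars
#' carry no GC response (hexane-extract volatiles only).
#'
#' @param cv Relative biological noise applied to every profile
#'   (default 0.2).
#' @return List of \linkS4class{CompoundProfile}.
#' @export
defaultGingerProfiles <- function(cv = 0.2) {
  mp <- multiplet
  mr <- function(lo, hi, nH) multiplet(range = c(lo, hi), pattern = "m",
                                       nProtons = nH)
  list(
    compoundProfile("Sucrose", list(
      mp(5.38, "d", 3.8), mp(3.63, "d", 12.1), mp(3.59, "d", 12.1),
      mp(4.09, "d", 8.1), mp(4.01, "dd", c(8.1, 7.9)),
      mr(3.67, 3.84, 7), mp(3.41, "dd", c(9.8, 3.8)), mr(3.34, 3.37, 1)),
      classMeans = c(GR = 50, PGR = 50), cv = cv),
    compoundProfile("Glucose", list(
      mp(5.09, "d", 3.7), mp(4.46, "d", 7.8), mr(3.74, 3.80, 1),
      mr(3.63, 3.70, 1), mp(3.34, "dd", c(3.7, 9.5)), mr(3.10, 3.14, 1)),
      classMeans = c(GR = 30, PGR = 30), cv = cv),
    compoundProfile("Stearic acid", list(
      mp(2.27, "t", 7.4, nProtons = 2), mr(1.54, 1.64, 2),
      mr(1.22, 1.38, 26), mr(0.85, 0.93, 3)),
      classMeans = c(GR = 5, PGR = 5), gcResponse = 900, rtMin = 33.8,
      cv = cv),
    compoundProfile("Oleic acid", list(
      mr(5.29, 5.39, 2), mp(2.27, "t", 7.4, nProtons = 2),
      mr(1.97, 2.07, 4), mr(1.54, 1.63, 2), mr(1.21, 1.41, 20),
      mr(0.85, 0.93, 3)),
      classMeans = c(GR = 8, PGR = 8), gcResponse = 1100, rtMin = 33.5,
      cv = cv),
    compoundProfile("Linoleic acid", list(
      mr(5.27, 5.40, 4), mp(2.77, "t", 6.1, nProtons = 2),
      mp(2.27, "t", 7.4, nProtons = 2), mr(2.01, 2.09, 4),
      mr(1.54, 1.63, 2), mr(1.24, 1.42, 14), mr(0.85, 0.93, 3)),
      classMeans = c(GR = 6, PGR = 6), gcResponse = 1000, rtMin = 33.2,
      cv = cv),
    compoundProfile("6-Gingerol", list(
      mp(6.77, "d", 1.9), mp(6.68, "d", 8.0), mp(6.61, "dd", c(8.0, 1.9)),
      mp(3.99, "m"), mp(3.82, "s", nProtons = 3),
      mp(2.77, "brs", nProtons = 4), mr(2.45, 2.59, 2), mr(1.37, 1.43, 2),
      mr(1.21, 1.35, 6), mp(0.90, "t", 6.7, nProtons = 3)),
      classMeans = c(GR = 4, PGR = 3.2), gcResponse = 1200, rtMin = 30.74,
      cv = cv),
    compoundProfile("6-Shogaol", list(
      mp(6.89, "dt", c(15.9, 7.0)), mp(6.77, "d", 1.9), mp(6.68, "d", 8.0),
      mp(6.61, "dd", c(8.0, 1.9)), mp(6.10, "dt", c(15.9, 1.5)),
      mp(3.82, "s", nProtons = 3), mr(2.78, 2.94, 2), mr(2.17, 2.27, 2),
      mr(1.41, 1.51, 2), mr(1.25, 1.38, 4), mp(0.90, "t", 6.7,
                                               nProtons = 3)),
      classMeans = c(GR = 1.5, PGR = 2.1), gcResponse = 1200, rtMin = 29.87,
      cv = cv),
    compoundProfile("alpha-Zingiberene", list(
      mp(5.62, "dd", c(9.9, 3.0)), mr(1.88, 2.07, 1), mr(2.17, 2.26, 1),
      mp(5.77, "m"), mp(5.42, "brs"), mr(1.48, 1.58, 1), mr(1.12, 1.22, 1),
      mr(1.97, 2.07, 1), mr(5.05, 5.13, 1), mp(1.60, "s", nProtons = 3),
      mr(1.65, 1.69, 3), mp(0.88, "d", 6.9, nProtons = 3),
      mr(1.66, 1.70, 3)),
      classMeans = c(GR = 1.19, PGR = 0.85), gcResponse = 1500,
      rtMin = 17.89, cv = cv),
    compoundProfile("ar-Curcumene", list(
      mp(7.07, "d", 8.3, nProtons = 2), mp(7.02, "d", 8.3, nProtons = 2),
      mp(2.62, "sext", 7.0), mr(1.53, 1.59, 2), mr(1.78, 1.90, 2),
      mr(5.05, 5.11, 1), mp(1.48, "brs", nProtons = 3),
      mp(1.65, "d", 1.1, nProtons = 3), mp(1.19, "d", 6.9, nProtons = 3),
      mp(2.29, "s", nProtons = 3)),
      classMeans = c(GR = 0.65, PGR = 1.30), gcResponse = 1500,
      rtMin = 17.57, cv = cv)
  )
}

#' Configuration of the simulated two-class cohort
#'
#' The stated world of the simulator: a GR/PGR design of
#' \code{2 * nPerClass} samples whose compound concentrations drive both
#' the NMR bucket intensities (through multiplet-to-bucket projection) and
#' the GC-MS peak areas.
#'
#' @param nPerClass Samples per class (default 40, echoing the 80-sample
#'   crude-drug design; at least 2).
#' @param classes Two class names; the second is the "positive"/processed
#'   class. Default \code{c("GR", "PGR")}.
#' @param profiles List of \linkS4class{CompoundProfile} (default
#'   \code{\link{defaultGingerProfiles}()}).
#' @param baselineSd Additive Gaussian baseline noise on bucket values;
#'   \code{NULL} (default) means 1 percent of the median positive
#'   noise-free bucket intensity.
#' @param gcCv Relative log-normal instrumental noise on GC areas
#'   (default 0.1).
#' @param isArea Constant internal-standard area (default 1e4).
#' @param grid Bucket lattice (default the 240-bucket grid).
#' @param seed Integer seed fixing all randomness.
#' @return A validated list of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(nPerClass = 40, classes = c("GR", "PGR"),
                         profiles = defaultGingerProfiles(),
                         baselineSd = NULL, gcCv = 0.1, isArea = 1e4,
                         grid = defaultBucketGrid(), seed = 1) {
  if (nPerClass < 2) stop("nPerClass must be at least 2")
  if (length(classes) != 2L || classes[1L] == classes[2L])
    stop("exactly two distinct class names required")
  if (!length(profiles) ||
      !all(vapply(profiles, is, logical(1), "CompoundProfile")))
    stop("profiles must be a non-empty list of CompoundProfile")
  for (p in profiles)
    if (!all(classes %in% names(p@classMeans)))
      stop("profile '", p@name, "' lacks a class mean for some class")
  structure(list(nPerClass = as.integer(nPerClass), classes = classes,
                 profiles = profiles, baselineSd = baselineSd,
                 gcCv = gcCv, isArea = isArea, grid = grid,
                 seed = as.integer(seed)),
            class = "CohortConfig")
}

## protons-per-bucket projection of one profile onto the grid; each
## multiplet's protons are split equally over the buckets it overlaps
.profileProjection <- function(profile, grid, labels) {
  proj <- stats::setNames(numeric(length(labels)),
                          formatBucketLabel(labels))
  for (m in profile@multiplets) {
    bks <- tryCatch(multipletToBuckets(m, grid), error = function(e) numeric())
    if (!length(bks)) next
    idx <- match(formatBucketLabel(bks), names(proj))
    proj[idx] <- proj[idx] + m@nProtons / length(bks)
  }
  proj
}

## log-normal draw with arithmetic mean mu and relative sd cv
.rlnormMean <- function(n, mu, cv) {
  if (mu <= 0) return(rep(0, n))
  if (cv <= 0) return(rep(mu, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mu) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate a paired NMR + GC-MS cohort with known ground truth
#'
#' Per sample, compound concentrations are drawn log-normally around the
#' class means; the bucket row is the sum over compounds of concentration
#' times the compound's protons-per-bucket projection plus additive
#' Gaussian baseline noise (clipped at zero), and each GC peak area is
#' concentration times the GC response times multiplicative log-normal
#' noise, with a constant internal-standard area. All randomness is fixed
#' by the config seed; the caller's RNG stream is left untouched.
#'
#' @param cfg A \code{\link{cohortConfig}}.
#' @param emitSpectra Also synthesize full-resolution spectra (narrow
#'   Gaussian lines at the planted bucket centres, 0.0025 ppm axis) so the
#'   bucketing pipeline itself can be exercised? Default \code{FALSE}.
#' @return List with elements \code{buckets} (\linkS4class{BucketMatrix}),
#'   \code{peaks} (\linkS4class{PeakTable}, not IS-standardized),
#'   \code{classes} (factor), \code{truth} (list: \code{concentrations}
#'   matrix, \code{projection} buckets x compounds matrix,
#'   \code{markerBuckets} per-compound planted labels, \code{baselineSd})
#'   and, when requested, \code{spectra}.
#' @examples
#' coh <- generateCohort(cohortConfig(nPerClass = 5, seed = 1))
#' dim(bucketValues(coh$buckets))  # 10 x 240
#' @export
generateCohort <- function(cfg, emitSpectra = FALSE) {
  if (!inherits(cfg, "CohortConfig")) cfg <- do.call(cohortConfig, cfg)
  grid <- cfg$grid
  labels <- bucketLabels(grid)
  nms <- vapply(cfg$profiles, function(p) p@name, character(1))
  proj <- vapply(cfg$profiles, .profileProjection, numeric(length(labels)),
                 grid = grid, labels = labels)
  colnames(proj) <- nms
  empty <- colSums(proj) == 0
  if (any(empty))
    stop("profile(s) project onto no bucket: ",
         paste(nms[empty], collapse = ", "))
  n <- 2L * cfg$nPerClass
  cls <- factor(rep(cfg$classes, each = cfg$nPerClass),
                levels = cfg$classes)
  ids <- paste0(rep(cfg$classes, each = cfg$nPerClass),
                sprintf("%02d", rep(seq_len(cfg$nPerClass), 2L)))

  .withSeed(cfg$seed, {
    conc <- vapply(cfg$profiles, function(p)
      as.numeric(unlist(lapply(cfg$classes, function(cl)
        .rlnormMean(cfg$nPerClass, p@classMeans[[cl]], p@cv)))),
      numeric(n))
    colnames(conc) <- nms; rownames(conc) <- ids

    B0 <- conc %*% t(proj)                       # noise-free bucket block
    bsd <- cfg$baselineSd
    if (is.null(bsd)) {
      pos <- B0[B0 > 0]
      bsd <- if (length(pos)) 0.01 * stats::median(pos) else 0
    }
    B <- pmax(B0 + matrix(stats::rnorm(length(B0), sd = bsd), nrow(B0)), 0)

    gcSel <- which(!is.na(vapply(cfg$profiles, function(p) p@gcResponse,
                                 numeric(1))))
    resp <- vapply(cfg$profiles[gcSel], function(p) p@gcResponse, numeric(1))
    rts <- vapply(cfg$profiles[gcSel], function(p) p@rtMin, numeric(1))
    s2 <- log(1 + cfg$gcCv^2)
    noise <- matrix(stats::rlnorm(n * length(gcSel), -s2 / 2, sqrt(s2)), n)
    areas <- sweep(conc[, gcSel, drop = FALSE], 2L, resp, "*") * noise

    spectra <- NULL
    if (emitSpectra) {
      x <- seq(grid@lo, grid@hi, by = 0.0025)
      act <- which(rowSums(proj) > 0)            # buckets with any signal
      G <- vapply(labels[act], function(ctr)
        stats::dnorm(x, mean = ctr, sd = 0.004), numeric(length(x)))
      I <- tcrossprod(G, B0[, act, drop = FALSE])  # points x samples
      spectra <- lapply(seq_len(n), function(i)
        Spectrum1D(x, I[, i], ids[i]))
      names(spectra) <- ids
    }

    markers <- lapply(cfg$profiles, function(p) {
      b <- unique(unlist(lapply(p@multiplets, function(m)
        tryCatch(multipletToBuckets(m, grid), error = function(e) numeric()))))
      sort(b, decreasing = TRUE)
    })
    names(markers) <- nms

    out <- list(
      buckets = BucketMatrix(B, ids, labels, grid = grid),
      peaks = PeakTable(areas, ids,
                        data.frame(name = nms[gcSel], rt_min = rts,
                                   stringsAsFactors = FALSE),
                        isAreas = rep(cfg$isArea, n), standardized = FALSE),
      classes = cls,
      truth = list(concentrations = conc, projection = proj,
                   markerBuckets = markers, baselineSd = bsd,
                   config = cfg))
    if (emitSpectra) out$spectra <- spectra
    out
  })
}
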