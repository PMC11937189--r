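#' @include fusion.R synthetic.R quantify.R io-nmr.R
NULL

#' Default pipeline configuration
#'
#' All tunables of the end-to-end workflow with their standard-profiling
#' defaults: 0.04 ppm buckets over delta 0-10, water exclusion delta
#' 4.60-5.00, CH3OH referencing at delta 3.30, constant total integral 100,
#' Pareto scaling, 1 + 2 + 0 OPLS components, 7-fold stratified
#' cross-validation, 200 permutations and the raw-Pearson heatmap mode.
#' Every paper-silent default (folds, intercept regression, heatmap mode)
#' is an explicit entry here.
#'
#' @param ... Named overrides of any default entry.
#' @return A list of class \code{"RunConfig"}.
#' @examples
#' defaultRunConfig(n_permutations = 50, seed = 7)
#' @export
defaultRunConfig <- function(...) {
  cfg <- list(
    grid_lo = 0, grid_hi = 10, grid_width = 0.04,
    water_lo = 4.60, water_hi = 5.00,
    solvent_ppm = 3.30, solvent_window_lo = 3.25, solvent_window_hi = 3.35,
    target_total = 100,
    scaling = "pareto",
    components = c(1, 2, 0),
    folds = 7,
    n_permutations = 200,
    heatmap_mode = "raw",
    marker_compound = NA_character_,
    top_n = 10,
    seed = 1,
    simulate = FALSE,
    n_per_class = 40,
    spectra_manifest = NA_character_,
    bucket_matrix = NA_character_,
    peak_table = NA_character_,
    labels_file = NA_character_,
    out_dir = "oplsfusion_out")
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "RunConfig")
}

#' Read / write a run configuration
#'
#' Configurations are stored as DCF ("key: value") text, the native R
#' key-value format; \code{components} is written in the "a + b + c"
#' notation. Unknown keys are rejected; missing keys take their defaults,
#' so the round-trip is stable.
#'
#' @param path File path.
#' @return \code{readRunConfig}: a \code{"RunConfig"} list.
#' @export
readRunConfig <- function(path) {
  d <- read.dcf(path)
  kv <- stats::setNames(as.list(d[1L, ]), colnames(d))
  def <- defaultRunConfig()
  bad <- setdiff(names(kv), names(def))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  for (k in names(kv)) {
    v <- trimws(kv[[k]])
    def[[k]] <- if (k == "components") {
      as.numeric(strsplit(gsub("\\s", "", v), "\\+")[[1L]])
    } else if (is.numeric(def[[k]])) as.numeric(v)
    else if (is.logical(def[[k]])) as.logical(v)
    else v
  }
  def
}

#' @rdname readRunConfig
#' @param cfg A \code{"RunConfig"} list.
#' @return \code{writeRunConfig}: the path, invisibly.
#' @export
writeRunConfig <- function(cfg, path) {
  out <- lapply(cfg, function(v)
    if (length(v) == 3L && is.numeric(v)) paste(v, collapse = " + ")
    else as.character(v))
  write.dcf(as.data.frame(out, check.names = FALSE), path)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the end-to-end profiling workflow
#'
#' Executes bucketing (or bucket-matrix import, or simulation), GC table
#' import and IS standardization, Pareto scaling, PCA, OPLS-DA with
#' permutation validation and S-plot, the fusion heatmap and the marker
#' report, writing all artifacts plus a JSON manifest of the model metrics
#' into \code{cfg$out_dir}. On a stage failure the partially written
#' outputs are removed and the error is re-thrown with a stage tag.
#'
#' Inputs may be given in-memory (\code{buckets}, \code{peaks},
#' \code{classes}) or through the config paths; with
#' \code{cfg$simulate = TRUE} a synthetic cohort is generated at
#' \code{cfg$seed}.
#'
#' @param cfg A \code{"RunConfig"} (default \code{defaultRunConfig()}).
#' @param buckets Optional \linkS4class{BucketMatrix}.
#' @param peaks Optional \linkS4class{PeakTable}.
#' @param classes Optional class factor aligned with the bucket matrix
#'   rows.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(cfg = defaultRunConfig(), buckets = NULL,
                        peaks = NULL, classes = NULL) {
  outDir <- cfg$out_dir
  fresh <- !dir.exists(outDir)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(if (fresh) outDir else written, recursive = TRUE))
  reg <- function(p) { written <<- c(written, p); p }

  grid <- .stage("grid", {
    g <- bucketGrid(cfg$grid_lo, cfg$grid_hi, cfg$grid_width)
    excludeWater(g, c(cfg$water_lo, cfg$water_hi))
  })

  inp <- .stage("input", {
    if (isTRUE(cfg$simulate)) {
      coh <- generateCohort(cohortConfig(nPerClass = cfg$n_per_class,
                                         grid = grid, seed = cfg$seed))
      list(buckets = coh$buckets, peaks = coh$peaks, classes = coh$classes)
    } else {
      if (is.null(buckets)) {
        if (!is.na(cfg$spectra_manifest)) {
          specs <- readSpectrumManifest(cfg$spectra_manifest)
          buckets <- buildBucketMatrix(
            specs, grid, targetTotal = cfg$target_total,
            solventPpm = cfg$solvent_ppm,
            searchWindow = c(cfg$solvent_window_lo, cfg$solvent_window_hi))
        } else if (!is.na(cfg$bucket_matrix)) {
          buckets <- readBucketMatrix(cfg$bucket_matrix, grid = grid)
        } else stop("no NMR input: give buckets, spectra_manifest or ",
                    "bucket_matrix")
      }
      if (is.null(peaks) && !is.na(cfg$peak_table))
        peaks <- readPeakTable(cfg$peak_table)
      if (is.null(classes)) {
        if (is.na(cfg$labels_file)) stop("no class labels given")
        lab <- utils::read.table(cfg$labels_file, header = TRUE,
                                 sep = .sniffSep(cfg$labels_file),
                                 stringsAsFactors = FALSE)
        classes <- factor(lab[[2L]][match(sampleIds(buckets), lab[[1L]])])
      }
      list(buckets = buckets, peaks = peaks, classes = classes)
    }
  })
  buckets <- inp$buckets; peaks <- inp$peaks; classes <- inp$classes

  writeBucketMatrix(buckets, reg(file.path(outDir, "bucket_matrix.csv")))
  Xs <- .stage("scaling", scaleColumns(bucketValues(buckets), cfg$scaling))

  pca <- .stage("pca", fitPca(Xs, k = min(3L, nrow(Xs@values) - 1L)))
  utils::write.csv(data.frame(sample_id = sampleIds(buckets),
                              scores(pca), check.names = FALSE),
                   reg(file.path(outDir, "pca_scores.csv")),
                   row.names = FALSE, quote = FALSE)

  da <- .stage("oplsda", fitOplsda(Xs, classes, cfg$components,
                                   cfg$folds, cfg$seed))
  writeOplsModel(da, reg(file.path(outDir, "oplsda")), X = Xs)
  perm <- .stage("permutation",
                 permutationTest(Xs, classes, cfg$components,
                                 cfg$n_permutations, cfg$folds, cfg$seed))
  utils::write.table(perm@permuted,
                     reg(file.path(outDir, "permutations.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  hm <- NULL; marker <- NULL; fusionFit <- NULL
  if (!is.null(peaks)) {
    peaks <- .stage("gc", isStandardize(peaks))
    fusionFit <- .stage("fusion",
                        fuseBlocks(buckets, peaks, cfg$components,
                                   cfg$scaling, cfg$folds, cfg$seed))
    hm <- .stage("heatmap", {
      correlationHeatmap(buckets, peaks, mode = cfg$heatmap_mode,
                         model = fusionFit, scaling = cfg$scaling)
    })
    writeHeatmap(hm, file.path(outDir, "heatmap"))
    reg(file.path(outDir, "heatmap.csv"))
    reg(file.path(outDir, "heatmap.long.tsv"))
    mc <- cfg$marker_compound
    if (is.na(mc)) {
      ## default marker: compound most shifted toward the positive class
      Yz <- scale(peakAreas(peaks))
      dz <- colMeans(Yz[classes == levels(classes)[2L], , drop = FALSE]) -
        colMeans(Yz[classes == levels(classes)[1L], , drop = FALSE])
      mc <- colnames(Yz)[which.max(dz)]
    }
    marker <- .stage("marker",
                     rankBucketsForCompound(hm, mc, topN = cfg$top_n))
    utils::write.table(cbind(compound = mc, marker),
                       reg(file.path(outDir, "marker_report.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  manifest <- list(
    seed = cfg$seed,
    components = paste(cfg$components, collapse = " + "),
    n_samples = length(sampleIds(buckets)),
    n_buckets = length(bucketLabels(buckets)),
    pca_explained = round(explainedFraction(pca), 4),
    R2Y = r2y(da), Q2 = q2(da),
    permutation = list(n = perm@nPermutations,
                       R2_intercept = perm@R2Intercept,
                       Q2_intercept = perm@Q2Intercept,
                       valid = perm@valid),
    fusion = if (!is.null(fusionFit))
      list(R2Y = r2y(fusionFit), Q2 = q2(fusionFit),
           heatmap_mode = hm@mode, marker_compound = mc),
    heatmap_mode = if (!is.null(hm)) hm@mode else NA)
  jsonlite::write_json(manifest, reg(file.path(outDir, "manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ok <- TRUE
  invisible(manifest)
}
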