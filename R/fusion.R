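#' @include validate.R gcms.R bucketing.R
NULL

## align a BucketMatrix and a PeakTable by sample id; error on mismatch
.alignBlocks <- function(nmr, gc) {
  a <- sampleIds(nmr); b <- sampleIds(gc)
  onlyA <- setdiff(a, b); onlyB <- setdiff(b, a)
  if (length(onlyA) || length(onlyB))
    stop("sample sets differ between blocks; NMR-only: [",
         paste(onlyA, collapse = ", "), "], GC-only: [",
         paste(onlyB, collapse = ", "), "]")
  list(nmr = nmr@values[a, , drop = FALSE],
       gc = gc@areas[match(a, b), , drop = FALSE],
       samples = a)
}

#' Fuse the NMR and GC-MS blocks through an OPLS model
#'
#' Regresses the GC-MS compound block (Y) on the NMR bucket block (X)
#' through OPLS after Pareto-scaling both blocks: the cross-platform model
#' behind the bucket-by-compound correlation heatmap. The GC block is
#' IS-standardized first if it is not already.
#'
#' @param nmr A \linkS4class{BucketMatrix}.
#' @param gc A \linkS4class{PeakTable} (samples reconciled by id; at least
#'   3 shared samples).
#' @param components Length-3 component counts (default \code{c(1, 2, 0)}).
#' @param scaling Scaling applied to both blocks (default \code{"pareto"}).
#' @param folds,seed Cross-validation settings for the attached Q2.
#' @return An \linkS4class{OplsModel} with R2Y and Q2 attached.
#' @export
fuseBlocks <- function(nmr, gc, components = c(1, 2, 0), scaling = "pareto",
                       folds = 7, seed = 1) {
  if (!gc@standardized) gc <- isStandardize(gc)
  al <- .alignBlocks(nmr, gc)
  if (length(al$samples) < 3L) stop("fusion needs at least 3 samples")
  Xs <- scaleColumns(al$nmr, scaling)
  Ys <- scaleColumns(al$gc, scaling)
  fit <- fitOpls(Xs, Ys@values, nPredictive = components[1L],
                 nOrthX = components[2L], nOrthY = components[3L])
  fit@Q2 <- crossValidatedQ2(Xs, Ys@values, components, folds, seed)
  fit
}

#' Bucket x compound correlation heatmap
#'
#' Pearson correlation across samples between every NMR bucket and every
#' IS-standardized GC-MS compound. In \code{"raw"} mode the correlations
#' are computed directly; in \code{"opls_filtered"} mode the supplied OPLS
#' model's Y-orthogonal variation is first removed from the bucket block
#' (\code{X - sum(t_o p_o')}), leaving only the Y-correlated part of X.
#' Zero-variance columns yield r = 0 with a flag.
#'
#' @param nmr A \linkS4class{BucketMatrix}.
#' @param gc A \linkS4class{PeakTable}.
#' @param mode \code{"raw"} (default) or \code{"opls_filtered"}.
#' @param model For filtered mode, the \linkS4class{OplsModel} from
#'   \code{\link{fuseBlocks}} (fit on the Pareto-scaled blocks).
#' @param scaling Column scaling applied before correlating (Pearson r is
#'   itself scale-invariant; this only matters for the filtered mode, whose
#'   model lives on the scaled blocks). Default \code{"pareto"}.
#' @return A \linkS4class{CorrelationHeatmap}.
#' @export
correlationHeatmap <- function(nmr, gc, mode = c("raw", "opls_filtered"),
                               model = NULL, scaling = "pareto") {
  mode <- match.arg(mode)
  if (!gc@standardized) gc <- isStandardize(gc)
  al <- .alignBlocks(nmr, gc)
  X <- scaleColumns(al$nmr, scaling)@values
  Y <- scaleColumns(al$gc, scaling)@values
  if (mode == "opls_filtered") {
    if (is.null(model))
      stop("opls_filtered mode needs a fitted model from fuseBlocks()")
    for (a in seq_len(model@nOrthX)) {
      to <- X %*% model@orthWeights[, a]
      X <- X - tcrossprod(as.numeric(to), model@orthLoadings[, a])
    }
  }
  sdX <- apply(X, 2L, stats::sd)
  sdY <- apply(Y, 2L, stats::sd)
  zX <- sdX < .Machine$double.eps^0.5
  zY <- sdY < .Machine$double.eps^0.5
  r <- matrix(0, ncol(X), ncol(Y))
  if (any(!zX) && any(!zY))
    r[!zX, !zY] <- stats::cor(X[, !zX, drop = FALSE], Y[, !zY, drop = FALSE])
  r[] <- pmin(1, pmax(-1, as.numeric(r)))
  flags <- outer(zX, zY, "|")
  new("CorrelationHeatmap", r = r, bucketLabels = nmr@bucketLabels,
      compoundNames = colnames(al$gc), mode = mode, flags = flags)
}

#' @describeIn bucketLabels Row labels of a correlation heatmap.
#' @export
setMethod("bucketLabels", "CorrelationHeatmap", function(x, ...)
  x@bucketLabels)

#' @describeIn compounds Column (compound) names of a heatmap.
#' @export
setMethod("compounds", "CorrelationHeatmap", function(x) x@compoundNames)

#' Rank buckets most correlated with a compound
#'
#' Orders the heatmap column of one compound by descending correlation
#' (ties broken by descending ppm) and reports the top buckets -- the
#' workflow that assigns unidentified NMR signals to a GC-identified
#' compound. When a multiplet table is supplied, each reported bucket is
#' annotated with the reference multiplets whose lattice projection
#' contains it.
#'
#' @param hm A \linkS4class{CorrelationHeatmap}.
#' @param compound Compound name (must be a heatmap column).
#' @param topN Number of buckets to report.
#' @param multipletTable Optional data.frame from
#'   \code{\link{readMultipletTable}} used for candidate assignment.
#' @param grid Grid for projecting the multiplet table (default the
#'   standard 240-bucket grid).
#' @return data.frame with columns \code{bucket} (label), \code{r},
#'   \code{rank} and, when a table is given, \code{candidates}
#'   (semicolon-separated "compound:position" matches).
#' @export
rankBucketsForCompound <- function(hm, compound, topN = 10,
                                   multipletTable = NULL,
                                   grid = defaultBucketGrid()) {
  j <- match(compound, hm@compoundNames)
  if (is.na(j)) stop("unknown compound '", compound, "'")
  o <- order(-hm@r[, j], -hm@bucketLabels)
  o <- head(o, max(0L, topN))
  rep <- data.frame(bucket = hm@bucketLabels[o], r = hm@r[o, j],
                    rank = seq_along(o), stringsAsFactors = FALSE)
  if (!is.null(multipletTable) && nrow(rep)) {
    proj <- lapply(multipletTable$multiplet, function(m)
      tryCatch(multipletToBuckets(m, grid), error = function(e) numeric()))
    rep$candidates <- vapply(rep$bucket, function(b) {
      hit <- vapply(proj, function(p) any(abs(p - b) < 1e-9), logical(1))
      paste(paste0(multipletTable$compound[hit], ":",
                   multipletTable$position[hit]), collapse = ";")
    }, character(1))
  }
  rep
}

#' Export a correlation heatmap
#'
#' Writes a wide CSV (rows = bucket labels, columns = compounds, cells = r
#' to 3 decimals) and a long TSV (\code{bucket}, \code{compound}, \code{r})
#' for plotting.
#'
#' @param hm A \linkS4class{CorrelationHeatmap}.
#' @param path Base path; \code{.csv} and \code{.long.tsv} are appended.
#' @return Invisibly, the two paths written.
#' @export
writeHeatmap <- function(hm, path) {
  wide <- data.frame(bucket = formatBucketLabel(hm@bucketLabels),
                     round(hm@r, 3), check.names = FALSE)
  names(wide)[-1L] <- hm@compoundNames
  p1 <- paste0(path, ".csv")
  utils::write.csv(wide, p1, row.names = FALSE, quote = FALSE)
  long <- expand.grid(bucket = formatBucketLabel(hm@bucketLabels),
                      compound = hm@compoundNames, stringsAsFactors = FALSE)
  long$r <- round(as.numeric(hm@r), 3)
  p2 <- paste0(path, ".long.tsv")
  utils::write.table(long, p2, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}

#' Export an OPLS model as delimited text plus a JSON summary
#'
#' Writes score and loading tables (predictive and orthogonal parts), the
#' S-plot table when \code{X} is supplied, and a JSON summary with component
#' counts, R2Y and Q2.
#'
#' @param model An \linkS4class{OplsModel}.
#' @param dir Output directory (created if needed).
#' @param X Optional training matrix for the S-plot table.
#' @return Invisibly, the directory.
#' @export
writeOplsModel <- function(model, dir, X = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    data.frame(id = rownames(x), x, check.names = FALSE),
    file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(model@scores, "scores_predictive.tsv")
  wt(model@loadings, "loadings_predictive.tsv")
  if (model@nOrthX) {
    wt(model@orthScores, "scores_orthogonal.tsv")
    wt(model@orthLoadings, "loadings_orthogonal.tsv")
  }
  if (!is.null(X)) {
    sp <- sPlot(model, X)
    utils::write.table(sp, file.path(dir, "splot.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  summ <- list(components = c(predictive = model@nPredictive,
                              orth_x = model@nOrthX, orth_y = model@nOrthY),
               R2Y = model@R2Y, Q2 = model@Q2, da = model@da,
               classes = model@classes)
  jsonlite::write_json(summ, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
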