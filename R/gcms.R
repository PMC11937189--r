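#' @include AllClasses.R AllGenerics.R io-nmr.R
NULL

#' @describeIn sampleIds Row ids of a peak table.
#' @export
setMethod("sampleIds", "PeakTable", function(x) x@sampleIds)

#' @describeIn peakAreas Samples x compounds area matrix.
#' @export
setMethod("peakAreas", "PeakTable", function(x) x@areas)

#' @describeIn compounds Compound metadata of a peak table.
#' @export
setMethod("compounds", "PeakTable", function(x) x@compounds)

#' Read a GC peak table
#'
#' Long format: columns \code{sample_id}, \code{compound}, \code{rt_min},
#' \code{area} and either an \code{is_area} column (constant within sample)
#' or an IS compound named via \code{isName}. Wide format: one row per
#' sample, first column \code{sample_id}, an \code{IS} column, remaining
#' columns compound areas (retention times then unknown). Compounds absent
#' from a sample get area 0 with a missingness flag.
#'
#' @param path File path (CSV or TSV; separator sniffed).
#' @param isName In long format, a compound name to treat as the internal
#'   standard instead of an \code{is_area} column.
#' @return A \linkS4class{PeakTable} (not yet IS-standardized).
#' @export
readPeakTable <- function(path, isName = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = .sniffSep(path),
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("sample_id", "compound", "area") %in% names(d))) {   # long
    if (!"rt_min" %in% names(d)) d$rt_min <- NA_real_
    if (!is.null(isName)) {
      isRows <- d$compound == isName
      if (!any(isRows)) stop("IS compound '", isName, "' not found")
      isTab <- d[isRows, ]
      d <- d[!isRows, ]
      d$is_area <- isTab$area[match(d$sample_id, isTab$sample_id)]
    }
    if (!"is_area" %in% names(d))
      stop("long-format table needs an is_area column or isName")
    samples <- unique(d$sample_id)
    comp <- unique(d[c("compound", "rt_min")])
    comp <- comp[!duplicated(comp$compound), ]
    areas <- matrix(0, length(samples), nrow(comp),
                    dimnames = list(samples, comp$compound))
    miss <- matrix(TRUE, length(samples), nrow(comp))
    i <- cbind(match(d$sample_id, samples), match(d$compound, comp$compound))
    areas[i] <- d$area
    miss[i] <- FALSE
    isA <- d$is_area[match(samples, d$sample_id)]
    pt <- PeakTable(areas, samples,
                    data.frame(name = comp$compound, rt_min = comp$rt_min,
                               stringsAsFactors = FALSE),
                    isAreas = isA, standardized = FALSE)
    pt@compounds$missing_flag <- colSums(miss) > 0L
    pt
  } else {                                                       # wide
    idc <- names(d)[1L]
    isCol <- grep("^(IS|is_area)$", names(d), value = TRUE)
    if (!length(isCol)) stop("wide-format table needs an IS column")
    compCols <- setdiff(names(d), c(idc, isCol[1L]))
    PeakTable(as.matrix(d[compCols]), d[[idc]], compCols,
              isAreas = d[[isCol[1L]]], standardized = FALSE)
  }
}

#' Read an n-alkane ladder
#'
#' Two-column delimited text: carbon number, retention time (minutes).
#'
#' @param path File path.
#' @return An \linkS4class{AlkaneLadder}.
#' @export
readAlkaneLadder <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = .sniffSep(path))
  alkaneLadder(d[[1L]], d[[2L]])
}

#' Internal-standard standardization
#'
#' Divides every peak area by its sample's internal-standard area and sets
#' the IS areas to 1, making the table scale-free across injections.
#' Idempotent.
#'
#' @param pt A \linkS4class{PeakTable}.
#' @return The standardized \linkS4class{PeakTable}.
#' @export
isStandardize <- function(pt) {
  bad <- which(pt@isAreas <= 0)
  if (length(bad))
    stop("zero internal-standard area for sample(s): ",
         paste(pt@sampleIds[bad], collapse = ", "))
  out <- pt
  out@areas <- pt@areas / pt@isAreas
  out@isAreas <- rep(1, length(pt@isAreas))
  out@standardized <- TRUE
  out
}

#' Linear retention index
#'
#' Linear (temperature-programmed) retention index against a bracketing
#' n-alkane pair: \code{RI = 100 * (n + (rt - rt_n) / (rt_(n+1) - rt_n))}.
#' At an alkane's own retention time the index is exactly 100 times its
#' carbon number. No extrapolation outside the ladder.
#'
#' @param rt Retention time(s) in minutes (vectorized).
#' @param ladder An \linkS4class{AlkaneLadder}.
#' @return Numeric retention indices.
#' @examples
#' retentionIndex(5.5, alkaneLadder(9:10, c(5, 6)))  # 950
#' @export
retentionIndex <- function(rt, ladder) {
  if (any(rt < min(ladder@rts) | rt > max(ladder@rts)))
    stop("retention time outside alkane ladder: extrapolation not supported")
  i <- findInterval(rt, ladder@rts, rightmost.closed = TRUE)
  frac <- (rt - ladder@rts[i]) / (ladder@rts[i + 1L] - ladder@rts[i])
  100 * (ladder@carbons[i] +
           frac * (ladder@carbons[i + 1L] - ladder@carbons[i]))
}

#' Attach retention indices to a peak table
#'
#' Computes the linear retention index for every compound whose retention
#' time falls inside the ladder; compounds outside the ladder (or without a
#' retention time) keep \code{ri = NA} and are flagged.
#'
#' @param pt A \linkS4class{PeakTable}.
#' @param ladder An \linkS4class{AlkaneLadder}.
#' @return The peak table with \code{ri} and \code{ri_flag} columns in its
#'   compound metadata.
#' @export
annotateRI <- function(pt, ladder) {
  rt <- pt@compounds$rt_min
  ok <- !is.na(rt) & rt >= min(ladder@rts) & rt <= max(ladder@rts)
  ri <- rep(NA_real_, length(rt))
  if (any(ok)) ri[ok] <- retentionIndex(rt[ok], ladder)
  out <- pt
  out@compounds$ri <- ri
  out@compounds$ri_flag <- !ok
  out
}
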