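#' @include AllClasses.R
NULL

setMethod("show", "Spectrum1D", function(object) {
  cat("Spectrum1D '", object@sampleId, "': ", length(object@ppm),
      " points, ", sprintf("%.2f", min(object@ppm)), " to ",
      sprintf("%.2f", max(object@ppm)), " ppm\n", sep = "")
})

setMethod("show", "BucketGrid", function(object) {
  cat("BucketGrid: ", object@width, " ppm bins over [", object@lo, ", ",
      object@hi, "] ppm; ", nBuckets(object), " buckets", sep = "")
  if (nrow(object@exclusions))
    cat(" (", nrow(object@exclusions), " exclusion region(s))", sep = "")
  cat("\n")
})

setMethod("show", "BucketMatrix", function(object) {
  cat("BucketMatrix: ", nrow(object@values), " samples x ",
      ncol(object@values), " buckets (",
      sprintf("%.2f", max(object@bucketLabels)), " ... ",
      sprintf("%.2f", min(object@bucketLabels)), " ppm)\n", sep = "")
})

setMethod("show", "Multiplet", function(object) {
  pos <- if (is.null(object@range)) sprintf("%.2f", object@center) else
    paste0(sprintf("%.2f", object@range[2L]), "-",
           sprintf("%.2f", object@range[1L]))
  J <- if (length(object@J)) paste0(", J = ",
                                    paste(object@J, collapse = ", "),
                                    " Hz") else ""
  cat("Multiplet: delta ", pos, " ", object@pattern, J, ", ",
      object@nProtons, "H @ ", object@field, " MHz\n", sep = "")
})

setMethod("show", "PeakTable", function(object) {
  cat("PeakTable: ", nrow(object@areas), " samples x ", ncol(object@areas),
      " compounds", if (object@standardized) " (IS-standardized)", "\n",
      sep = "")
})

setMethod("show", "AlkaneLadder", function(object) {
  cat("AlkaneLadder: C", min(object@carbons), "-C", max(object@carbons),
      ", ", length(object@carbons), " alkanes\n", sep = "")
})

setMethod("show", "ScaledMatrix", function(object) {
  cat("ScaledMatrix (", object@scaling, "): ", nrow(object@values),
      " x ", ncol(object@values), sep = "")
  if (any(object@constantCols))
    cat("; ", sum(object@constantCols), " constant column(s)", sep = "")
  cat("\n")
})

setMethod("show", "PcaModel", function(object) {
  cat("PcaModel: ", ncol(object@scores), " components; explained ",
      paste(sprintf("%.1f%%", 100 * object@explainedFraction),
            collapse = " / "), "\n", sep = "")
})

setMethod("show", "OplsModel", function(object) {
  kind <- if (object@da) "OPLS-DA" else
    if (object@nOrthX > 0) "OPLS" else "PLS"
  cat(kind, " model (", object@nPredictive, " + ", object@nOrthX, " + ",
      object@nOrthY, " components): R2Y = ", sprintf("%.3f", object@R2Y),
      if (!is.na(object@Q2)) sprintf(", Q2 = %.3f", object@Q2), "\n",
      sep = "")
  if (object@da)
    cat("  classes: ", object@classes[1L], " (-) vs ", object@classes[2L],
        " (+)\n", sep = "")
})

setMethod("show", "PermutationSummary", function(object) {
  cat("PermutationSummary: ", object@nPermutations, " permutations\n",
      "  R2 intercept = ", sprintf("%.3f", object@R2Intercept),
      " (< 0.3), Q2 intercept = ", sprintf("%.3f", object@Q2Intercept),
      " (< 0.05) -> ", if (object@valid) "VALID" else "NOT VALID", "\n",
      sep = "")
})

setMethod("show", "CorrelationHeatmap", function(object) {
  cat("CorrelationHeatmap (", object@mode, "): ", nrow(object@r),
      " buckets x ", ncol(object@r), " compounds\n", sep = "")
})

setMethod("show", "CalibrationCurve", function(object) {
  cat("CalibrationCurve '", object@analyte, "': area = ",
      sprintf("%.4g", object@slope), " * conc + ",
      sprintf("%.4g", object@intercept), ", R2 = ",
      sprintf("%.4f", object@rSquared), " (", object@n, " points)\n",
      sep = "")
})

setMethod("show", "CompoundProfile", function(object) {
  cat("CompoundProfile '", object@name, "': ", length(object@multiplets),
      " multiplets; means ",
      paste(names(object@classMeans), sprintf("%.3g", object@classMeans),
            sep = "=", collapse = ", "),
      if (!is.na(object@gcResponse)) " (GC-detectable)", "\n", sep = "")
})
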