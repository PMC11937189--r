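#' @include AllClasses.R
NULL

#' Fit a GC-FID calibration curve
#'
#' Unweighted ordinary least squares of peak area on concentration over an
#' external-standard dilution series. A good curve has R2 close to 1 and an
#' intercept close to 0.
#'
#' @param concs Concentrations in mg/mL (at least 3 points, at least 2
#'   distinct values).
#' @param areas Peak areas, same length.
#' @param analyte Analyte name.
#' @return A \linkS4class{CalibrationCurve}.
#' @examples
#' fitCalibration(c(1, 0.1, 0.01), c(2.0, 0.2, 0.02))
#' @export
fitCalibration <- function(concs, areas, analyte = "analyte") {
  if (length(concs) != length(areas)) stop("concs and areas differ in length")
  if (length(concs) < 3L) stop("calibration needs at least 3 points")
  if (length(unique(concs)) < 2L)
    stop("calibration needs at least 2 distinct concentrations")
  fit <- stats::lm(areas ~ concs)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((areas - mean(areas))^2)
  new("CalibrationCurve", analyte = as.character(analyte),
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      rSquared = min(1, max(0, r2)), range = range(concs),
      n = length(concs))
}

#' Absolute content from a calibration curve
#'
#' Inverts the calibration line (\code{concentration = (area - intercept) /
#' slope}) and converts the extract concentration into content per gram of
#' dry material: \code{content = concentration * volume_mL / mass_g}. With
#' the standard protocol (10 mg extracted in 1 mL) a 0.0119 mg/mL extract
#' reads as 1.19 mg/g. Replicate areas of one sample are summarized by mean
#' and standard deviation on the content scale.
#'
#' @param area Peak area(s); several values are treated as replicates of
#'   the same sample.
#' @param curve A \linkS4class{CalibrationCurve}.
#' @param massG Dry sample mass in grams (default 0.010).
#' @param volumeML Extraction volume in mL (default 1).
#' @param sampleId Sample identifier.
#' @return data.frame with one row: \code{sample_id}, \code{analyte},
#'   \code{concentration_mg_per_mL} (mean), \code{content_mg_per_g},
#'   \code{sd}, \code{n}, \code{extrapolated} (any area outside the
#'   calibrated range).
#' @export
quantifyContent <- function(area, curve, massG = 0.010, volumeML = 1,
                            sampleId = "sample") {
  if (abs(curve@slope) < .Machine$double.eps)
    stop("calibration slope is zero; cannot invert")
  if (massG <= 0 || volumeML <= 0) stop("mass and volume must be positive")
  conc <- (area - curve@intercept) / curve@slope
  content <- conc * volumeML / massG
  calArea <- curve@intercept + curve@slope * curve@range
  lo <- min(calArea); hi <- max(calArea)
  data.frame(sample_id = sampleId, analyte = curve@analyte,
             concentration_mg_per_mL = mean(conc),
             content_mg_per_g = mean(content),
             sd = if (length(area) > 1L) stats::sd(content) else NA_real_,
             n = length(area),
             extrapolated = any(area < lo - 1e-12 | area > hi + 1e-12),
             stringsAsFactors = FALSE)
}

#' Read a calibration table
#'
#' CSV/TSV with columns \code{analyte}, \code{conc_mg_per_mL}, \code{area};
#' one curve is fit per analyte.
#'
#' @param path File path.
#' @return Named list of \linkS4class{CalibrationCurve}.
#' @export
readCalibrationTable <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = .sniffSep(path),
                         stringsAsFactors = FALSE)
  need <- c("analyte", "conc_mg_per_mL", "area")
  if (!all(need %in% names(d)))
    stop("calibration table needs columns: ", paste(need, collapse = ", "))
  out <- lapply(split(d, d$analyte), function(g)
    fitCalibration(g$conc_mg_per_mL, g$area, analyte = g$analyte[1L]))
  out
}
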