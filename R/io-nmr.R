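#' @include AllClasses.R bucketing.R
NULL

.readDelim <- function(path, header = TRUE) {
  utils::read.table(path, header = header, sep = "", quote = "\"",
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

## sniff comma vs whitespace/tab separation from the first data line
.sniffSep <- function(path) {
  l <- readLines(path, n = 5L)
  l <- l[!grepl("^\\s*(#|$)", l)]
  if (length(l) && grepl(",", l[1L])) "," else ""
}

#' Read a 1D spectrum from two-column delimited text
#'
#' Expects columns (ppm, intensity); comma, tab or whitespace separated, an
#' optional header line is detected and skipped. A descending ppm axis is
#' reversed on read.
#'
#' @param path File path.
#' @param sampleId Sample identifier; defaults to the file name without
#'   extension.
#' @return A \linkS4class{Spectrum1D}.
#' @export
readSpectrum <- function(path, sampleId = NULL) {
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  sep <- .sniffSep(path)
  first <- scan(path, what = "character", nlines = 1L, sep = sep,
                quiet = TRUE, comment.char = "#")
  header <- suppressWarnings(any(is.na(as.numeric(first))))
  d <- utils::read.table(path, header = header, sep = sep,
                         comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("spectrum file needs two columns (ppm, intensity)")
  Spectrum1D(d[[1L]], d[[2L]], sampleId)
}

#' Read a manifest of spectra
#'
#' The manifest maps sample ids to spectrum files: delimited text with
#' columns \code{sample_id} and \code{path} (relative paths resolved against
#' the manifest's directory).
#'
#' @param path Manifest file path.
#' @return Named list of \linkS4class{Spectrum1D}.
#' @export
readSpectrumManifest <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = .sniffSep(path),
                         stringsAsFactors = FALSE)
  if (!all(c("sample_id", "path") %in% names(d)))
    stop("manifest needs columns sample_id and path")
  base <- dirname(path)
  specs <- lapply(seq_len(nrow(d)), function(i) {
    p <- d$path[i]
    if (!file.exists(p)) p <- file.path(base, d$path[i])
    readSpectrum(p, d$sample_id[i])
  })
  names(specs) <- d$sample_id
  specs
}

#' Write / read a bucket matrix as CSV
#'
#' First column \code{sample_id}; remaining headers are two-decimal bucket
#' labels in descending ppm.
#'
#' @param x A \linkS4class{BucketMatrix}.
#' @param path Output (input) file path.
#' @return \code{writeBucketMatrix}: the path, invisibly.
#' @export
writeBucketMatrix <- function(x, path) {
  d <- data.frame(sample_id = x@sampleIds, x@values, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeBucketMatrix
#' @param grid Grid to attach on read; by default reconstructed as a plain
#'   lattice spanning the read labels (exclusions inferred from missing
#'   columns are not recovered).
#' @return \code{readBucketMatrix}: a \linkS4class{BucketMatrix}.
#' @export
readBucketMatrix <- function(path, grid = NULL) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labs <- as.numeric(names(d)[-1L])
  if (anyNA(labs)) stop("bucket matrix headers must be numeric ppm labels")
  if (is.null(grid)) {
    w <- stats::median(abs(diff(sort(labs))))
    lo <- floor((min(labs) - w / 2) / w) * w
    hi <- ceiling((max(labs) + w / 2) / w) * w
    grid <- bucketGrid(lo, hi, w)
  }
  BucketMatrix(as.matrix(d[-1L]), d[[1L]], labs, grid = grid)
}

#' Read a multiplet table
#'
#' Delimited table with columns \code{compound}, \code{position},
#' \code{center_or_range} (a ppm value or a "lo-hi" range), \code{pattern},
#' \code{J_list} (semicolon-separated Hz, may be empty), \code{n_protons}
#' and optionally \code{field} (MHz, default 400). The packaged reference
#' table of ginger-constituent multiplets is at
#' \code{system.file("extdata", "ginger_multiplets.tsv", package =
#' "oplsFusion")}.
#'
#' @param path File path.
#' @param field Default spectrometer frequency (MHz) when no column present.
#' @return data.frame with a list-column \code{multiplet} of
#'   \linkS4class{Multiplet} objects.
#' @export
readMultipletTable <- function(path, field = 400) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("compound", "position", "center_or_range", "pattern",
            "J_list", "n_protons")
  if (!all(need %in% names(d)))
    stop("multiplet table needs columns: ", paste(need, collapse = ", "))
  if (!"field" %in% names(d)) d$field <- field
  d$multiplet <- lapply(seq_len(nrow(d)), function(i) {
    cr <- gsub("\\s", "", as.character(d$center_or_range[i]))
    J <- if (nzchar(d$J_list[i]) && !is.na(d$J_list[i]))
      as.numeric(strsplit(as.character(d$J_list[i]), ";")[[1L]]) else numeric()
    if (grepl("^[0-9.]+-[0-9.]+$", cr)) {
      rg <- as.numeric(strsplit(cr, "-")[[1L]])
      multiplet(range = rg, pattern = d$pattern[i], J = J,
                field = d$field[i], nProtons = d$n_protons[i])
    } else {
      multiplet(center = as.numeric(cr), pattern = d$pattern[i], J = J,
                field = d$field[i], nProtons = d$n_protons[i])
    }
  })
  d
}
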