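#' Construct a mass spectrum
#'
#' A `spectrum` holds one sample's paired m/z and intensity series together
#' with a processing log recording every transformation applied to it.
#'
#' @param mz Numeric vector of m/z values (Thomson), strictly increasing.
#' @param intensity Numeric vector of non-negative, finite intensities,
#'   same length as `mz`.
#' @param sample_id Sample identifier.
#' @param processing_log Character vector of applied processing step names.
#' @return An object of class `spectrum`: a list with elements `mz`,
#'   `intensity`, `sample_id` and `processing_log`.
#' @examples
#' s <- spectrum(c(1000, 1001, 1002), c(5, 7, 6), "s1")
#' s
#' @export
spectrum <- function(mz, intensity, sample_id = "sample",
                     processing_log = character()) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("`mz` and `intensity` must have the same length", call. = FALSE)
  }
  if (anyNA(mz) || any(!is.finite(mz))) {
    stop("`mz` must be finite", call. = FALSE)
  }
  if (anyNA(intensity) || any(!is.finite(intensity))) {
    stop("`intensity` must be finite", call. = FALSE)
  }
  bad <- which(diff(mz) <= 0)
  if (length(bad)) {
    stop(sprintf("`mz` must be strictly increasing; violated at position %d (m/z %.6g after %.6g)",
                 bad[1] + 1L, mz[bad[1] + 1L], mz[bad[1]]), call. = FALSE)
  }
  structure(
    list(mz = mz, intensity = intensity,
         sample_id = as.character(sample_id),
         processing_log = as.character(processing_log)),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s: %d points, m/z %.1f-%.1f\n",
              x$sample_id, length(x$mz), min(x$mz), max(x$mz)))
  if (length(x$processing_log)) {
    cat("  processing:", paste(x$processing_log, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$mz)

log_step <- function(s, step) {
  s$processing_log <- c(s$processing_log, step)
  s
}

#' Read a spectrum from a two-column delimited text file
#'
#' The canonical on-disk format is plain text with two numeric columns
#' (m/z, intensity), whitespace- or comma-delimited, with an optional
#' single header line. Intensities are stored raw; any normalization is an
#' explicit, logged pipeline step, never implicit at I/O.
#'
#' @param path Path to the spectrum file.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, sample_id = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("spectrum file not found: %s", path), call. = FALSE)
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    stop(sprintf("%s: empty spectrum file", path), call. = FALSE)
  }
  parse_line <- function(ln) {
    fields <- strsplit(trimws(ln), "[,;\t ]+")[[1]]
    suppressWarnings(as.numeric(fields))
  }
  first <- parse_line(lines[1])
  start <- 1L
  if (anyNA(first)) {
    # a single non-numeric leading line is treated as a header
    start <- 2L
    if (length(lines) < 2L) {
      stop(sprintf("%s: no numeric data rows", path), call. = FALSE)
    }
  }
  rows <- lapply(seq(start, length(lines)), function(i) {
    v <- parse_line(lines[i])
    if (length(v) < 2L || anyNA(v[1:2])) {
      stop(sprintf("%s: unparsable spectrum line %d: '%s'", path, i, lines[i]),
           call. = FALSE)
    }
    v[1:2]
  })
  if (length(rows) < 2L) {
    stop(sprintf("%s: a spectrum needs at least 2 points, found %d",
                 path, length(rows)), call. = FALSE)
  }
  m <- do.call(rbind, rows)
  bad <- which(diff(m[, 1]) <= 0)
  if (length(bad)) {
    stop(sprintf("%s: m/z not strictly increasing at data row %d (line %d)",
                 path, bad[1] + 1L, bad[1] + start), call. = FALSE)
  }
  spectrum(m[, 1], m[, 2], sample_id = sample_id)
}

#' Write a spectrum to a two-column delimited text file
#'
#' @param s A [spectrum()].
#' @param path Output path.
#' @param digits Significant digits used when formatting.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, digits = 10) {
  stopifnot(inherits(s, "spectrum"))
  dat <- cbind(format(s$mz, digits = digits, trim = TRUE, scientific = FALSE),
               format(s$intensity, digits = digits, trim = TRUE))
  ok <- tryCatch({
    writeLines(paste(dat[, 1], dat[, 2]), con = path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop(sprintf("failed to write spectrum file: %s", path), call. = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with columns `sample_id`, `label`, `cohort`, `file`;
#' `file` paths are interpreted relative to the manifest's directory unless
#' absolute. Labels are restricted to the vocabulary `case` / `control` and
#' sample ids must be unique.
#'
#' @param path Path to the manifest CSV.
#' @return A data.frame with columns `sample_id`, `label`, `cohort`, `file`
#'   (`file` resolved against the manifest directory).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("manifest not found: %s", path), call. = FALSE)
  }
  man <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE,
                    strip.white = TRUE)
  required <- c("sample_id", "label", "cohort", "file")
  missing <- setdiff(required, names(man))
  if (length(missing)) {
    stop(sprintf("manifest is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  man <- man[required]
  man$sample_id <- as.character(man$sample_id)
  bad <- setdiff(unique(man$label), c("case", "control"))
  if (length(bad)) {
    stop(sprintf("unknown label(s) %s: labels must be one of {case, control}",
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  dup <- unique(man$sample_id[duplicated(man$sample_id)])
  if (length(dup)) {
    stop(sprintf("duplicated sample_id(s) in manifest: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  rel <- !grepl("^(/|[A-Za-z]:)", man$file)
  man$file[rel] <- file.path(dirname(path), man$file[rel])
  man
}
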