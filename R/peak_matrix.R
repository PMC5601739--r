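new_peak_matrix <- function(intensities, sample_ids, labels, peaks,
                            cohort_id = "cohort") {
  stopifnot(is.matrix(intensities),
            nrow(intensities) == length(sample_ids),
            length(sample_ids) == length(labels),
            ncol(intensities) == nrow(peaks))
  dimnames(intensities) <- list(as.character(sample_ids),
                                sprintf("%.1f", peaks$mz_ref))
  structure(list(intensities = intensities,
                 sample_ids = as.character(sample_ids),
                 labels = as.character(labels),
                 peaks = peaks, cohort_id = cohort_id),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("<peak_matrix> %s: %d samples (%d case / %d control) x %d reference peaks\n",
              x$cohort_id, nrow(x$intensities),
              sum(x$labels == "case"), sum(x$labels == "control"),
              ncol(x$intensities)))
  invisible(x)
}

#' @export
dim.peak_matrix <- function(x) dim(x$intensities)

#' Align per-sample peak lists into reference peaks
#'
#' Pools all detected peak m/z values, sorts them, and clusters by
#' single-linkage gaps: a cluster is broken whenever the gap to the next
#' peak exceeds `tol_rel` times the running cluster mean. Within a
#' cluster, each sample contributes at most one member (its most intense
#' peak). The reference m/z is the mean of the member m/z values.
#'
#' @param peaklists List of `peak_list` objects from [detect_peaks()].
#' @param tol_rel Relative m/z tolerance, in (0, 0.01]; default 0.001
#'   (a 0.1% maximum mass shift).
#' @return A data.frame of reference peaks with columns `mz_ref`,
#'   `n_present`, `presence_frac`, sorted by `mz_ref`, with `tol_rel` and
#'   `n_samples` attached as attributes.
#' @export
align_peaks <- function(peaklists, tol_rel = 0.001) {
  if (tol_rel <= 0 || tol_rel > 0.01) {
    stop("tol_rel must be in (0, 0.01]", call. = FALSE)
  }
  n_samples <- length(peaklists)
  pooled <- do.call(rbind, lapply(seq_along(peaklists), function(i) {
    pl <- peaklists[[i]]
    if (!nrow(pl)) return(NULL)
    data.frame(mz = pl$mz, intensity = pl$intensity, sample = i)
  }))
  empty <- data.frame(mz_ref = numeric(), n_present = integer(),
                      presence_frac = numeric())
  if (is.null(pooled) || !nrow(pooled)) {
    return(structure(empty, tol_rel = tol_rel, n_samples = n_samples))
  }
  pooled <- pooled[order(pooled$mz), , drop = FALSE]
  cluster <- integer(nrow(pooled))
  cur <- 1L; csum <- pooled$mz[1]; cn <- 1L
  cluster[1] <- cur
  for (i in seq_len(nrow(pooled) - 1L)) {
    gap <- pooled$mz[i + 1L] - pooled$mz[i]
    if (gap > tol_rel * (csum / cn)) {
      cur <- cur + 1L; csum <- 0; cn <- 0L
    }
    cluster[i + 1L] <- cur
    csum <- csum + pooled$mz[i + 1L]; cn <- cn + 1L
  }
  refs <- do.call(rbind, lapply(split(pooled, cluster), function(g) {
    # one member per sample: the most intense wins
    g <- g[order(g$sample, -g$intensity), , drop = FALSE]
    g <- g[!duplicated(g$sample), , drop = FALSE]
    data.frame(mz_ref = mean(g$mz), n_present = nrow(g),
               presence_frac = nrow(g) / n_samples)
  }))
  refs <- refs[order(refs$mz_ref), , drop = FALSE]
  rownames(refs) <- NULL
  structure(refs, tol_rel = tol_rel, n_samples = n_samples)
}

#' Build the samples-by-peaks intensity matrix
#'
#' Cell (i, j) holds the intensity of sample i's peak matched to reference
#' peak j (the nearest reference within the alignment tolerance; the most
#' intense candidate wins when a sample has several), or 0 when the sample
#' has no matching peak. Row order follows the input order; absent peaks
#' are encoded as zero, not missing.
#'
#' @param peaklists List of `peak_list` objects.
#' @param labels Class labels (`"case"`/`"control"`), one per peak list.
#' @param refs Reference peaks from [align_peaks()] over the same lists.
#' @param sample_ids Optional sample identifiers.
#' @param cohort_id Cohort identifier.
#' @return A `peak_matrix`.
#' @export
build_matrix <- function(peaklists, labels, refs, sample_ids = NULL,
                         cohort_id = "cohort") {
  if (length(peaklists) != length(labels)) {
    stop("`peaklists` and `labels` must have the same length", call. = FALSE)
  }
  tol_rel <- attr(refs, "tol_rel")
  if (is.null(tol_rel)) tol_rel <- 0.001
  if (is.null(sample_ids)) {
    sample_ids <- vapply(seq_along(peaklists), function(i) {
      id <- attr(peaklists[[i]], "sample_id")
      if (is.null(id)) sprintf("sample_%03d", i) else id
    }, character(1))
  }
  X <- matrix(0, nrow = length(peaklists), ncol = nrow(refs),
              dimnames = list(sample_ids, sprintf("%.1f", refs$mz_ref)))
  for (i in seq_along(peaklists)) {
    pl <- peaklists[[i]]
    if (!nrow(pl)) next
    j <- match_mz(pl$mz, refs$mz_ref, tol_rel)
    ok <- !is.na(j)
    for (k in which(ok)) {
      if (pl$intensity[k] > X[i, j[k]]) X[i, j[k]] <- pl$intensity[k]
    }
  }
  new_peak_matrix(X, sample_ids, labels, as.data.frame(refs), cohort_id)
}

# nearest reference within rel tolerance; NA when none matches
match_mz <- function(mz, ref_mz, tol_rel) {
  vapply(mz, function(m) {
    d <- abs(ref_mz - m)
    j <- which.min(d)
    if (length(j) && d[j] <= tol_rel * ref_mz[j]) j else NA_integer_
  }, integer(1))
}

#' Filter reference peaks by presence fraction
#'
#' Retains the reference peaks detected in at least `min_frac` of the
#' samples (boundary included: a peak present in exactly half the samples
#' survives `min_frac = 0.5`). Column order is preserved; raising
#' `min_frac` never adds a column.
#'
#' @param m A `peak_matrix`.
#' @param min_frac Minimum presence fraction, in (0, 1].
#' @return The filtered `peak_matrix`.
#' @export
presence_filter <- function(m, min_frac = 0.5) {
  stopifnot(inherits(m, "peak_matrix"))
  if (min_frac <= 0 || min_frac > 1) {
    stop("min_frac must be in (0, 1]", call. = FALSE)
  }
  keep <- m$peaks$presence_frac >= min_frac
  m$intensities <- m$intensities[, keep, drop = FALSE]
  m$peaks <- m$peaks[keep, , drop = FALSE]
  rownames(m$peaks) <- NULL
  m
}

#' Write / read a peak matrix as CSV
#'
#' The CSV starts with `sample_id`, `label`, `cohort` columns followed by
#' one column per reference peak, named by its m/z rounded to one decimal.
#'
#' @param m A `peak_matrix`.
#' @param path Output path.
#' @return `path` invisibly (write); a `peak_matrix` (read).
#' @export
write_matrix_csv <- function(m, path) {
  stopifnot(inherits(m, "peak_matrix"))
  df <- data.frame(sample_id = m$sample_ids, label = m$labels,
                   cohort = rep(m$cohort_id, length(m$sample_ids)),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(m$intensities, check.names = FALSE))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", check.names = FALSE,
                   stringsAsFactors = FALSE)
  meta <- c("sample_id", "label", "cohort")
  if (!all(meta %in% names(df))) {
    stop("matrix CSV must start with sample_id,label,cohort columns",
         call. = FALSE)
  }
  mzs <- setdiff(names(df), meta)
  X <- as.matrix(df[mzs])
  storage.mode(X) <- "double"
  rownames(X) <- df$sample_id
  n <- nrow(X)
  peaks <- data.frame(mz_ref = as.numeric(mzs),
                      n_present = colSums(X > 0),
                      presence_frac = colSums(X > 0) / n)
  rownames(peaks) <- NULL
  new_peak_matrix(X, df$sample_id, df$label, peaks,
                  cohort_id = if (length(unique(df$cohort)) == 1L)
                    df$cohort[1] else "mixed")
}
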