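#' Choose a two-sample test via a Shapiro-Wilk normality gate
#'
#' Returns `"t"` when both groups pass the Shapiro-Wilk normality test at
#' `alpha`, otherwise `"mann_whitney"`. Degenerate (constant) groups, for
#' which normality is undefined, fall through to the rank test.
#'
#' @param x,y Numeric samples, each of length >= 3.
#' @param alpha Normality test level (default 0.05).
#' @return `"t"` or `"mann_whitney"`.
#' @export
shapiro_gate <- function(x, y, alpha = 0.05) {
  if (length(x) < 3 || length(y) < 3) {
    stop("the normality gate needs at least 3 observations per group",
         call. = FALSE)
  }
  normal <- function(v) {
    if (length(unique(v)) < 3) return(FALSE)
    if (length(v) > 5000) v <- v[seq(1, length(v), length.out = 5000)]
    shapiro.test(v)$p.value > alpha
  }
  if (normal(x) && normal(y)) "t" else "mann_whitney"
}

#' Pooled-variance two-sample Student t test
#'
#' Two-tailed Student t test with pooled variance, from raw samples.
#' Under zero pooled variance the P-value is 1 for equal means and 0
#' otherwise.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return Two-tailed P-value.
#' @seealso [two_sample_t_summary()] for the summary-statistics form.
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  two_sample_t_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
}

#' @rdname two_sample_t
#' @param mean_x,sd_x,n_x,mean_y,sd_y,n_y Group summary statistics.
#' @export
two_sample_t_summary <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y) {
  stopifnot(n_x >= 2, n_y >= 2, sd_x >= 0, sd_y >= 0)
  df <- n_x + n_y - 2
  sp2 <- ((n_x - 1) * sd_x^2 + (n_y - 1) * sd_y^2) / df
  if (sp2 == 0) return(if (mean_x == mean_y) 1 else 0)
  t_stat <- (mean_x - mean_y) / sqrt(sp2 * (1 / n_x + 1 / n_y))
  2 * pt(-abs(t_stat), df)
}

#' Mann-Whitney U test
#'
#' The U statistic counts pairs where an `x` value exceeds a `y` value,
#' with half credit for ties. For small samples (`n_x + n_y <= 12`) the
#' two-tailed P-value is exact, from the full permutation distribution of
#' U over all label assignments (so ties are handled exactly); otherwise a
#' tie-corrected normal approximation is used. The two-tailed P is twice
#' the smaller tail probability, capped at 1.
#'
#' @param x,y Numeric samples, each non-empty.
#' @return List with elements `U` and `p_value`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n_x <- length(x); n_y <- length(y); N <- n_x + n_y
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n_x)]) - n_x * (n_x + 1) / 2
  if (N <= 12) {
    u_all <- permutation_u(pooled, n_x)
    p <- 2 * min(mean(u_all <= U + 1e-9), mean(u_all >= U - 1e-9))
    p <- min(p, 1)
  } else {
    mu <- n_x * n_y / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n_x * n_y / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- min(2 * pnorm(-abs(z)), 1)
    }
  }
  list(U = U, p_value = p)
}

# U statistics over all C(N, n_x) assignments of the pooled values
permutation_u <- function(pooled, n_x) {
  r <- rank(pooled)
  idx <- utils::combn(length(pooled), n_x)
  colSums(matrix(r[idx], nrow = n_x)) - n_x * (n_x + 1) / 2
}

#' ROC area under the curve with Hanley-McNeil confidence interval
#'
#' Rank-based (trapezoid) AUC with half credit for ties, oriented
#' case-high: AUC is the probability that a randomly chosen case scores
#' above a randomly chosen control. Identical to the Mann-Whitney U of
#' cases over controls divided by `n_case * n_control`. The 95% CI uses
#' the Hanley-McNeil standard error, clipped to \[0, 1\]. The raw
#' orientation is reported — an AUC below 0.5 means controls score
#' higher.
#'
#' @param scores Numeric scores.
#' @param labels `"case"`/`"control"` per score (or logical, TRUE = case).
#' @return List with `auc` and `ci = c(low, high)`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "case", "control")
  is_case <- labels == "case"
  n1 <- sum(is_case); n2 <- sum(!is_case)
  if (n1 == 0 || n2 == 0) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores)
  U <- sum(r[is_case]) - n1 * (n1 + 1) / 2
  A <- U / (n1 * n2)
  q1 <- A / (2 - A)
  q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + (n1 - 1) * (q1 - A^2) + (n2 - 1) * (q2 - A^2)) /
               (n1 * n2))
  ci <- c(max(0, A - 1.96 * se), min(1, A + 1.96 * se))
  list(auc = A, ci = ci)
}

#' Univariate candidate-peak selection
#'
#' For every reference peak: choose the test by the Shapiro-Wilk gate,
#' compute the two-tailed P-value, the group means and the tendency
#' (up = higher in cases), and the per-peak ROC AUC with its
#' Hanley-McNeil CI. Returns the peaks with `P < alpha`, sorted by m/z.
#' No multiple-testing adjustment is applied by default; set
#' `adjust = "BH"` for a Benjamini-Hochberg screen instead.
#'
#' @param m A `peak_matrix` containing both classes.
#' @param alpha Significance screen level (default 0.05).
#' @param all Return all peaks (with a `significant` flag) instead of
#'   only the significant ones.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data.frame with columns `mz_ref`, `tendency`, `mean_case`,
#'   `mean_control`, `p_value`, `test_used`, `auc`, `auc_lo`, `auc_hi`
#'   (and `significant` when `all = TRUE`).
#' @export
select_candidates <- function(m, alpha = 0.05, all = FALSE,
                              adjust = c("none", "BH")) {
  stopifnot(inherits(m, "peak_matrix"))
  adjust <- match.arg(adjust)
  is_case <- m$labels == "case"
  if (!any(is_case) || all(is_case)) {
    stop("the matrix must contain both cases and controls", call. = FALSE)
  }
  stats <- lapply(seq_len(ncol(m$intensities)), function(j) {
    v <- m$intensities[, j]
    x <- v[is_case]; y <- v[!is_case]
    test <- shapiro_gate(x, y)
    p <- if (test == "t") two_sample_t(x, y) else mann_whitney(x, y)$p_value
    a <- roc_auc(v, m$labels)
    data.frame(mz_ref = m$peaks$mz_ref[j],
               tendency = if (mean(x) > mean(y)) "up" else "down",
               mean_case = mean(x), mean_control = mean(y),
               p_value = p, test_used = test,
               auc = a$auc, auc_lo = a$ci[1], auc_hi = a$ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, stats)
  p_screen <- if (adjust == "BH") stats::p.adjust(out$p_value, "BH") else out$p_value
  out$significant <- p_screen < alpha
  out <- out[order(out$mz_ref), , drop = FALSE]
  rownames(out) <- NULL
  if (all) out else {
    res <- out[out$significant, setdiff(names(out), "significant"),
               drop = FALSE]
    rownames(res) <- NULL
    res
  }
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson chi-square without continuity correction, df = 1, two-tailed,
#' on the table `rbind(c(a, b), c(c, d))` (rows = groups). A table with
#' a zero column margin carries no association information and returns
#' P = 1.
#'
#' @param a,b,c,d Non-negative integer cell counts; rows are groups.
#' @return Two-tailed P-value.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (a + b == 0 || c + d == 0) {
    stop("each group (row) must contain at least one observation",
         call. = FALSE)
  }
  if (a + c == 0 || b + d == 0) return(1)
  N <- a + b + c + d
  chi2 <- N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  pchisq(chi2, df = 1, lower.tail = FALSE)
}
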