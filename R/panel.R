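#' Fit a peptide diagnostic panel by stepwise logistic regression
#'
#' The central fitting function of the package. Starting from the
#' intercept-only model, candidate peaks are added one at a time: at each
#' step the candidate with the smallest likelihood-ratio P-value against
#' the current model enters if that P-value is below `p_enter`; after
#' every addition, any included peak whose Wald P-value exceeds
#' `p_remove` is removed (worst first, refitting after each removal).
#' The procedure stops when no addition or removal changes the set, and
#' is deterministic: ties are broken by ascending m/z. Defaults follow
#' the conventional SPSS-style stepwise thresholds (entry P < 0.05,
#' removal P > 0.10).
#'
#' @param m A `peak_matrix` with both classes (case = positive).
#' @param candidates Candidate reference m/z values (default: all peaks
#'   of `m`, typically the significant peaks from [select_candidates()]).
#' @param p_enter Likelihood-ratio entry threshold.
#' @param p_remove Wald removal threshold; must satisfy
#'   `0 < p_enter <= p_remove < 1`.
#' @param cutoff Probability threshold used later for classification.
#' @param scale Optional multiplicative rescaling applied to all
#'   intensities before fitting (coefficients are reported on the scaled
#'   features). Intensity units of serum profiling are arbitrary, so the
#'   coefficient scale is a reporting choice.
#' @return An object of class `peptide_panel` with components
#'   `peak_mzs`, `beta`, `intercept`, `se`, `or_`, `or_ci`, `p_wald`,
#'   `cutoff`, `scale`, `loglik`, `n`, `cohort_id`.
#' @seealso [odds_ratios()], [predict.peptide_panel()],
#'   [external_validate()]
#' @export
fit_panel <- function(m, candidates = NULL, p_enter = 0.05, p_remove = 0.10,
                      cutoff = 0.5, scale = 1) {
  stopifnot(inherits(m, "peak_matrix"))
  if (!(p_enter > 0 && p_enter <= p_remove && p_remove < 1)) {
    stop("need 0 < p_enter <= p_remove < 1", call. = FALSE)
  }
  if (is.null(candidates)) candidates <- m$peaks$mz_ref
  candidates <- sort(candidates)
  col_of <- match_mz(candidates, m$peaks$mz_ref, 0.001)
  if (anyNA(col_of)) {
    stop(sprintf("candidate m/z not found in the matrix: %s",
                 paste(candidates[is.na(col_of)], collapse = ", ")),
         call. = FALSE)
  }
  X <- m$intensities[, col_of, drop = FALSE] * scale
  colnames(X) <- sprintf("%.1f", candidates)
  y <- m$labels == "case"
  usable <- apply(X, 2, sd) > 0
  pool <- which(usable)

  fit_set <- function(cols) {
    if (!length(cols)) {
      p0 <- mean(y)
      return(list(beta = numeric(), intercept = log(p0 / (1 - p0)),
                  se = setNames(sqrt(1 / (length(y) * p0 * (1 - p0))),
                                "(Intercept)"),
                  loglik = sum(y * log(p0) + (1 - y) * log(1 - p0)),
                  fitted = rep(p0, length(y))))
    }
    fit_logistic(X[, cols, drop = FALSE], y)
  }

  included <- integer()
  fit <- fit_set(included)
  seen <- character()
  repeat {
    sig <- paste(sort(included), collapse = ",")
    if (sig %in% seen) break  # cycling guard
    seen <- c(seen, sig)
    changed <- FALSE
    # forward: best likelihood-ratio candidate
    remaining <- setdiff(pool, included)
    if (length(remaining)) {
      lrt_p <- vapply(remaining, function(j) {
        f1 <- tryCatch(fit_set(c(included, j)), error = function(e) NULL)
        if (is.null(f1)) return(NA_real_)
        pchisq(2 * (f1$loglik - fit$loglik), df = 1, lower.tail = FALSE)
      }, numeric(1))
      ok <- which(!is.na(lrt_p))
      if (length(ok)) {
        best <- ok[which.min(lrt_p[ok])]  # ties: lowest m/z (pool is sorted)
        if (lrt_p[best] < p_enter) {
          included <- sort(c(included, remaining[best]))
          fit <- fit_set(included)
          changed <- TRUE
        }
      }
    }
    # backward: drop Wald-nonsignificant members, worst first
    repeat {
      if (!length(included)) break
      wald_p <- 2 * pnorm(-abs(fit$beta / fit$se[-1]))
      worst <- which.max(wald_p)
      if (wald_p[worst] <= p_remove) break
      included <- included[-worst]
      fit <- fit_set(included)
      changed <- TRUE
    }
    if (!changed) break
  }
  if (!length(included)) {
    warning("no candidate met the entry criterion; returning an intercept-only panel")
  }
  mzs <- candidates[included]
  beta <- fit$beta
  se_b <- if (length(included)) fit$se[-1] else numeric()
  or_ci <- cbind(low = exp(beta - 1.96 * se_b),
                 high = exp(beta + 1.96 * se_b))
  structure(list(
    peak_mzs = mzs,
    beta = beta,
    intercept = fit$intercept,
    se = fit$se,
    or_ = exp(beta),
    or_ci = or_ci,
    p_wald = if (length(included)) 2 * pnorm(-abs(beta / se_b)) else numeric(),
    p_wald_intercept = 2 * pnorm(-abs(fit$intercept / fit$se[1])),
    cutoff = cutoff, scale = scale,
    loglik = fit$loglik, n = length(y),
    n_case = sum(y), n_control = sum(!y),
    cohort_id = m$cohort_id,
    p_enter = p_enter, p_remove = p_remove
  ), class = "peptide_panel")
}

#' Construct a peptide panel from known coefficients
#'
#' Builds a `peptide_panel` directly from coefficients, e.g. to apply a
#' published panel to new data or to inspect a reported coefficient
#' table. Standard errors are optional; without them the odds-ratio CIs
#' and Wald P-values are `NA`.
#'
#' @param peak_mzs Reference m/z per panel peak.
#' @param beta Logistic coefficient per peak (log-odds per intensity
#'   unit).
#' @param intercept Intercept (log-odds).
#' @param se Optional standard errors, intercept first, length
#'   `length(beta) + 1`.
#' @param cutoff Classification probability cutoff (default 0.5).
#' @param scale Feature scale (default 1).
#' @return A `peptide_panel`.
#' @export
peptide_panel <- function(peak_mzs, beta, intercept, se = NULL,
                          cutoff = 0.5, scale = 1) {
  stopifnot(length(peak_mzs) == length(beta), is.finite(intercept))
  if (is.null(se)) se <- rep(NA_real_, length(beta) + 1)
  stopifnot(length(se) == length(beta) + 1)
  names(beta) <- sprintf("%.1f", peak_mzs)
  names(se) <- c("(Intercept)", names(beta))
  se_b <- se[-1]
  structure(list(
    peak_mzs = peak_mzs, beta = beta, intercept = intercept, se = se,
    or_ = exp(beta),
    or_ci = cbind(low = exp(beta - 1.96 * se_b),
                  high = exp(beta + 1.96 * se_b)),
    p_wald = 2 * pnorm(-abs(beta / se_b)),
    p_wald_intercept = 2 * pnorm(-abs(intercept / se[1])),
    cutoff = cutoff, scale = scale,
    loglik = NA_real_, n = NA_integer_,
    n_case = NA_integer_, n_control = NA_integer_,
    cohort_id = "external", p_enter = NA_real_, p_remove = NA_real_
  ), class = "peptide_panel")
}

#' @export
print.peptide_panel <- function(x, ...) {
  cat(sprintf("Peptide diagnostic panel (%d peaks; trained on %s, %d case / %d control)\n",
              length(x$peak_mzs), x$cohort_id, x$n_case, x$n_control))
  print(odds_ratios(x), row.names = FALSE)
  cat(sprintf("Classification cutoff: %.2f   log-likelihood: %.3f\n",
              x$cutoff, x$loglik))
  invisible(x)
}

#' @export
summary.peptide_panel <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.peptide_panel <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$beta)
}

#' Odds-ratio table of a fitted panel
#'
#' One row per panel peak plus the constant term: coefficient, odds
#' ratio `exp(beta)`, its Wald 95% CI `exp(beta +/- 1.96 se)`, and the
#' Wald P-value, rounded to 3 decimals as conventionally reported.
#'
#' @param model A `peptide_panel`.
#' @param digits Decimals in the returned table (default 3).
#' @return A data.frame with columns `mz`, `beta`, `OR`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
odds_ratios <- function(model, digits = 3) {
  stopifnot(inherits(model, "peptide_panel"))
  k <- length(model$peak_mzs)
  df <- data.frame(
    mz = c(sprintf("%.1f", model$peak_mzs), "Constant"),
    beta = round(c(model$beta, model$intercept), digits),
    OR = round(exp(c(model$beta, model$intercept)), digits),
    ci_low = c(round(model$or_ci[, "low"], digits), NA)[seq_len(k + 1)],
    ci_high = c(round(model$or_ci[, "high"], digits), NA)[seq_len(k + 1)],
    p_value = round(c(model$p_wald, model$p_wald_intercept), digits),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

# intensity columns for the panel's peaks, matched within 0.1% rel tol;
# unmatched peaks become zero columns with a warning
panel_design <- function(model, m) {
  X <- matrix(0, nrow = nrow(m$intensities), ncol = length(model$peak_mzs),
              dimnames = list(m$sample_ids, sprintf("%.1f", model$peak_mzs)))
  if (!length(model$peak_mzs)) return(X)
  j <- match_mz(model$peak_mzs, m$peaks$mz_ref, 0.001)
  if (anyNA(j)) {
    warning(sprintf("panel peak(s) %s not matched in the matrix; using zero intensities",
                    paste(sprintf("%.1f", model$peak_mzs[is.na(j)]),
                          collapse = ", ")))
  }
  for (k in which(!is.na(j))) X[, k] <- m$intensities[, j[k]]
  X * model$scale
}

#' Predict from a peptide panel
#'
#' @param object A `peptide_panel`.
#' @param newdata A `peak_matrix` (peaks matched to the panel by nearest
#'   m/z within 0.1% relative tolerance) or a plain intensity matrix with
#'   one column per panel peak.
#' @param type `"response"` (probability of case), `"link"` (log-odds),
#'   or `"class"` (label at the panel's cutoff).
#' @param ... Unused.
#' @return Numeric vector of predictions (or labels for `type="class"`).
#' @export
predict.peptide_panel <- function(object, newdata,
                                  type = c("response", "link", "class"),
                                  ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "peak_matrix")) {
    panel_design(object, newdata)
  } else {
    as.matrix(newdata) * object$scale
  }
  if (ncol(X) != length(object$peak_mzs)) {
    stop("newdata must provide one column per panel peak", call. = FALSE)
  }
  eta <- object$intercept + if (ncol(X)) drop(X %*% object$beta) else 0
  eta <- rep_len(eta, nrow(X))
  switch(type,
         link = eta,
         response = 1 / (1 + exp(-eta)),
         class = ifelse(1 / (1 + exp(-eta)) >= object$cutoff,
                        "case", "control"))
}

#' Diagnostic performance from a confusion matrix
#'
#' Builds the full performance summary (accuracy, sensitivity,
#' specificity with Wald 95% binomial CIs, plus an optional ROC AUC)
#' from the four confusion counts, with cases as the positive class.
#'
#' @param tp,fp,fn,tn Confusion counts: true/false positives,
#'   false/true negatives.
#' @param auc,auc_ci Optional panel ROC AUC and its CI.
#' @return An object of class `diag_perf`.
#' @export
diag_performance <- function(tp, fp, fn, tn, auc = NA_real_,
                             auc_ci = c(NA_real_, NA_real_)) {
  counts <- c(tp, fp, fn, tn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  n_pos <- tp + fn; n_neg <- tn + fp
  wald_ci <- function(p, n) {
    if (n == 0) return(c(NA_real_, NA_real_))
    half <- 1.96 * sqrt(p * (1 - p) / n)
    c(max(0, p - half), min(1, p + half))
  }
  sens <- if (n_pos > 0) tp / n_pos else NA_real_
  spec <- if (n_neg > 0) tn / n_neg else NA_real_
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    accuracy = (tp + tn) / sum(counts),
    sensitivity = sens, specificity = spec,
    sens_ci = wald_ci(sens, n_pos), spec_ci = wald_ci(spec, n_neg),
    auc = auc, auc_ci = auc_ci
  ), class = "diag_perf")
}

#' Evaluate predicted against true labels
#'
#' Counts the confusion matrix (case = positive class) and summarizes it
#' via [diag_performance()]. When `scores` are supplied, the ROC AUC of
#' the scores (case-high) and its Hanley-McNeil CI are included.
#'
#' @param pred_labels,true_labels `"case"`/`"control"` vectors of equal
#'   length; the truth must contain both classes.
#' @param scores Optional continuous scores (e.g. panel probabilities).
#' @return A `diag_perf`.
#' @export
evaluate <- function(pred_labels, true_labels, scores = NULL) {
  if (length(pred_labels) != length(true_labels)) {
    stop("prediction and truth lengths differ", call. = FALSE)
  }
  if (!all(c("case", "control") %in% true_labels)) {
    stop("the truth must contain both classes", call. = FALSE)
  }
  tp <- sum(pred_labels == "case" & true_labels == "case")
  fp <- sum(pred_labels == "case" & true_labels == "control")
  fn <- sum(pred_labels == "control" & true_labels == "case")
  tn <- sum(pred_labels == "control" & true_labels == "control")
  if (!is.null(scores)) {
    a <- roc_auc(scores, true_labels)
    diag_performance(tp, fp, fn, tn, auc = a$auc, auc_ci = a$ci)
  } else {
    diag_performance(tp, fp, fn, tn)
  }
}

#' @export
print.diag_perf <- function(x, ...) {
  pct <- function(p) sprintf("%.1f%%", 100 * p)
  ci <- function(v) if (anyNA(v)) "" else
    sprintf(" (%.1f%%-%.1f%%)", 100 * v[1], 100 * v[2])
  cat("Diagnostic performance (case = positive)\n")
  cat(sprintf("  confusion: TP=%d FP=%d FN=%d TN=%d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  accuracy    %s\n", pct(x$accuracy)))
  cat(sprintf("  sensitivity %s%s\n", pct(x$sensitivity), ci(x$sens_ci)))
  cat(sprintf("  specificity %s%s\n", pct(x$specificity), ci(x$spec_ci)))
  if (!is.na(x$auc)) {
    cat(sprintf("  AUC         %.3f%s\n", x$auc,
                if (anyNA(x$auc_ci)) "" else
                  sprintf(" (%.3f-%.3f)", x$auc_ci[1], x$auc_ci[2])))
  }
  invisible(x)
}

#' Validate a frozen panel on an external cohort
#'
#' Applies the fitted panel without any refitting: panel peaks are
#' matched to the validation matrix by nearest reference m/z within 0.1%
#' relative tolerance (unmatched peaks contribute zero intensity, with a
#' warning), predicted probabilities are classified at the panel's
#' cutoff, and the confusion summary plus the panel ROC AUC on the
#' validation probabilities are returned.
#'
#' @param model A `peptide_panel`.
#' @param m_val The validation `peak_matrix`.
#' @return A `diag_perf`.
#' @export
external_validate <- function(model, m_val) {
  stopifnot(inherits(model, "peptide_panel"), inherits(m_val, "peak_matrix"))
  prob <- predict(model, m_val, type = "response")
  pred <- ifelse(prob >= model$cutoff, "case", "control")
  evaluate(pred, m_val$labels, scores = prob)
}

#' Save / load a peptide panel as JSON
#'
#' The JSON model file stores the selected peak m/z values, the
#' coefficients, standard errors, cutoff and feature scale, so a frozen
#' panel can be applied elsewhere.
#'
#' @param model A `peptide_panel`.
#' @param path File path.
#' @return `path` invisibly (write); a `peptide_panel` (read).
#' @export
write_panel <- function(model, path) {
  stopifnot(inherits(model, "peptide_panel"))
  payload <- unclass(model)
  payload$or_ci <- NULL  # reconstructed on read
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$beta <- setNames(as.numeric(p$beta), sprintf("%.1f", p$peak_mzs))
  p$se <- setNames(as.numeric(p$se),
                   c("(Intercept)", sprintf("%.1f", p$peak_mzs)))
  se_b <- if (length(p$beta)) p$se[-1] else numeric()
  p$or_ <- exp(p$beta)
  p$or_ci <- cbind(low = exp(p$beta - 1.96 * se_b),
                   high = exp(p$beta + 1.96 * se_b))
  structure(p, class = "peptide_panel")
}
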