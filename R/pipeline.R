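#' Run the discovery analysis end to end
#'
#' Orchestrates the full discovery-cohort workflow: preprocess every
#' spectrum, align the per-sample peak lists into reference peaks, build
#' the intensity matrix, apply the presence filter, screen candidates
#' univariately, fit the stepwise logistic panel on the significant
#' peaks, and self-evaluate the panel on its training cohort. The stage
#' funnel (total detected peaks, aligned reference peaks, peaks
#' surviving the presence filter, significant candidates, final panel
#' size) is recorded in the result.
#'
#' @param x A `spectrum_set` from [generate_cohort()] or a manifest
#'   data.frame from [read_manifest()].
#' @param params [preprocess_params()].
#' @param min_frac Presence-filter threshold (default 0.5).
#' @param alpha Univariate screen level (default 0.05).
#' @param p_enter,p_remove Stepwise thresholds (defaults 0.05 / 0.10).
#' @param cutoff Classification probability cutoff (default 0.5).
#' @param scale Feature scale passed to [fit_panel()].
#' @return An object of class `discovery_run`: list with `matrix`
#'   (filtered `peak_matrix`), `stats` (full univariate table),
#'   `candidates` (significant peaks), `panel` (`peptide_panel`),
#'   `performance` (training `diag_perf`) and `funnel` (named counts).
#' @export
run_discovery <- function(x, params = preprocess_params(), min_frac = 0.5,
                          alpha = 0.05, p_enter = 0.05, p_remove = 0.10,
                          cutoff = 0.5, scale = 1) {
  pre <- preprocess_cohort(x, params)
  n_detected <- sum(vapply(pre$peaklists, nrow, integer(1)))
  refs <- align_peaks(pre$peaklists, params$align_tol_rel)
  mat <- build_matrix(pre$peaklists, pre$labels, refs,
                      sample_ids = pre$sample_ids,
                      cohort_id = pre$cohort_id)
  mat_f <- presence_filter(mat, min_frac)
  stats <- select_candidates(mat_f, alpha, all = TRUE)
  candidates <- stats[stats$significant, , drop = FALSE]
  panel <- if (nrow(candidates)) {
    fit_panel(mat_f, candidates$mz_ref, p_enter = p_enter,
              p_remove = p_remove, cutoff = cutoff, scale = scale)
  } else {
    warning("no significant candidate peaks; fitting an intercept-only panel")
    fit_panel(mat_f, numeric(), p_enter = p_enter, p_remove = p_remove,
              cutoff = cutoff, scale = scale)
  }
  perf <- external_validate(panel, mat_f)  # self-evaluation on training data
  structure(list(
    matrix = mat_f, stats = stats, candidates = candidates,
    panel = panel, performance = perf,
    funnel = c(detected_peaks = n_detected,
               reference_peaks = nrow(refs),
               presence_filtered = ncol(mat_f$intensities),
               significant = nrow(candidates),
               panel_size = length(panel$peak_mzs)),
    params = params, alpha = alpha, min_frac = min_frac
  ), class = "discovery_run")
}

#' @export
print.discovery_run <- function(x, ...) {
  cat("Discovery run\n")
  f <- x$funnel
  cat(sprintf("  funnel: %d detected -> %d reference -> %d (presence >= %.0f%%) -> %d significant -> %d in panel\n",
              f[["detected_peaks"]], f[["reference_peaks"]],
              f[["presence_filtered"]], 100 * x$min_frac,
              f[["significant"]], f[["panel_size"]]))
  print(x$panel)
  cat("Training-cohort performance:\n")
  print(x$performance)
  invisible(x)
}

#' Validate a frozen panel on an external cohort
#'
#' Preprocesses the validation cohort with the same parameters, builds
#' its peak matrix (no presence filter, so panel peaks are never dropped
#' before matching), and evaluates the frozen panel via
#' [external_validate()].
#'
#' @param model A fitted `peptide_panel` (or a path to a panel JSON
#'   written by [write_panel()]).
#' @param x A `spectrum_set` or manifest data.frame for the validation
#'   cohort.
#' @param params [preprocess_params()]; use the discovery settings.
#' @return A `diag_perf`.
#' @export
run_validation <- function(model, x, params = preprocess_params()) {
  if (is.character(model)) {
    if (!file.exists(model)) {
      stop(sprintf("model file not found: %s", model), call. = FALSE)
    }
    model <- read_panel(model)
  }
  stopifnot(inherits(model, "peptide_panel"))
  pre <- preprocess_cohort(x, params)
  refs <- align_peaks(pre$peaklists, params$align_tol_rel)
  mat <- build_matrix(pre$peaklists, pre$labels, refs,
                      sample_ids = pre$sample_ids, cohort_id = pre$cohort_id)
  external_validate(model, mat)
}

#' Human-readable report of a discovery (and optional validation) run
#'
#' Produces a Markdown report with the stage funnel, the candidate-peak
#' table, the panel odds-ratio table, and the diagnostic-performance
#' blocks for the training cohort and, if given, an external validation
#' cohort.
#'
#' @param run A `discovery_run`.
#' @param validation Optional `diag_perf` from [run_validation()].
#' @param path Optional file to write the report to.
#' @return Character vector of Markdown lines, invisibly.
#' @export
panel_report <- function(run, validation = NULL, path = NULL) {
  stopifnot(inherits(run, "discovery_run"))
  pct <- function(p) sprintf("%.1f%%", 100 * p)
  perf_block <- function(p, title) {
    c(sprintf("## %s", title),
      sprintf("- confusion: TP=%d FP=%d FN=%d TN=%d", p$tp, p$fp, p$fn, p$tn),
      sprintf("- accuracy: %s", pct(p$accuracy)),
      sprintf("- sensitivity: %s (%s-%s)", pct(p$sensitivity),
              pct(p$sens_ci[1]), pct(p$sens_ci[2])),
      sprintf("- specificity: %s (%s-%s)", pct(p$specificity),
              pct(p$spec_ci[1]), pct(p$spec_ci[2])),
      if (!is.na(p$auc)) sprintf("- AUC: %.3f (%.3f-%.3f)",
                                 p$auc, p$auc_ci[1], p$auc_ci[2]),
      "")
  }
  tab <- function(df) {
    c(paste("|", paste(names(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      vapply(seq_len(nrow(df)), function(i) {
        paste("|", paste(vapply(df[i, ], function(v) {
          if (is.numeric(v)) format(signif(v, 4)) else as.character(v)
        }, character(1)), collapse = " | "), "|")
      }, character(1)))
  }
  f <- run$funnel
  lines <- c(
    "# Peptide diagnostic panel report", "",
    "## Stage funnel",
    sprintf("- detected peaks (all samples): %d", f[["detected_peaks"]]),
    sprintf("- aligned reference peaks: %d", f[["reference_peaks"]]),
    sprintf("- peaks present in >= %.0f%% of samples: %d",
            100 * run$min_frac, f[["presence_filtered"]]),
    sprintf("- significant candidates (P < %g): %d", run$alpha,
            f[["significant"]]),
    sprintf("- peaks in final panel: %d", f[["panel_size"]]), "",
    "## Candidate peaks", tab(run$candidates), "",
    "## Panel", tab(odds_ratios(run$panel)), "",
    perf_block(run$performance, "Training-cohort performance"))
  if (!is.null(validation)) {
    lines <- c(lines, perf_block(validation, "External-validation performance"))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
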