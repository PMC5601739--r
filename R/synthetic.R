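#' Describe one simulated peptide peak
#'
#' A peak specification gives the class-conditional intensity model for one
#' peptide signal: a Gaussian profile in m/z whose apex height is drawn from
#' a log-normal distribution parameterized by the class mean and a
#' coefficient of variation, present in a spectrum with a class-specific
#' Bernoulli probability.
#'
#' @param mz_center Peak center (Thomson).
#' @param mean_case,mean_control Mean apex intensity in cases / controls
#'   (arbitrary intensity units, >= 0).
#' @param cv Coefficient of variation of the log-normal apex height (> 0).
#' @param presence_case,presence_control Probability that the peak is
#'   present in a case / control spectrum, in \[0, 1\].
#' @param width_sigma Gaussian shape parameter (Th). Default scales with
#'   mass, `mz_center * 5e-4`, mimicking roughly constant resolving power.
#' @return A one-row data.frame with the fields above.
#' @export
peak_spec <- function(mz_center, mean_case, mean_control, cv = 0.8,
                      presence_case = 0.95, presence_control = 0.95,
                      width_sigma = mz_center * 5e-4) {
  stopifnot(is.finite(mz_center), mz_center > 0,
            is.finite(mean_case), mean_case >= 0,
            is.finite(mean_control), mean_control >= 0,
            is.finite(cv), cv > 0,
            presence_case >= 0, presence_case <= 1,
            presence_control >= 0, presence_control <= 1,
            is.finite(width_sigma), width_sigma > 0)
  data.frame(mz_center = mz_center, mean_case = mean_case,
             mean_control = mean_control, cv = cv,
             presence_case = presence_case,
             presence_control = presence_control,
             width_sigma = width_sigma)
}

# The ten class-discriminative peptide peaks used as the default planted
# signal: discovery-cohort group mean intensities (case, control) and the
# per-peak discovery ROC AUC used to calibrate the intensity spread.
DISCRIMINATIVE_PEAKS <- data.frame(
  mz       = c(1895.3, 1944.0, 2020.9, 2080.7, 2104.5,
               2656.8, 3154.9, 3238.5, 3875.9, 4042.8),
  tendency = c("up", "down", "up", "down", "down",
               "down", "down", "up", "down", "down"),
  mean_case    = c(2664.8, 858.5, 3328.8, 295.8, 132.8,
                   565.6, 145.8, 1015.9, 349.7, 271.5),
  mean_control = c(374.7, 3103.8, 320.5, 1187.9, 544.7,
                   704.3, 1566.3, 451.2, 557.3, 940.5),
  auc = c(0.838, 0.906, 0.746, 0.896, 0.906,
          0.673, 0.980, 0.623, 0.733, 0.859),
  stringsAsFactors = FALSE
)

# cv of a log-normal intensity such that two same-cv log-normals whose
# means differ by ratio r discriminate with the given ROC AUC:
# AUC = Phi(|ln r| / (sqrt(2) sigma)), sigma^2 = log(1 + cv^2)
calibrate_cv <- function(mean_case, mean_control, auc) {
  stopifnot(auc > 0.5, auc < 1, mean_case > 0, mean_control > 0)
  sigma <- abs(log(mean_case / mean_control)) / (sqrt(2) * qnorm(auc))
  sqrt(expm1(sigma^2))
}

# m/z values of the five peaks retained in the published diagnostic panel.
PANEL_MZ <- c(1895.3, 2020.9, 2080.7, 2656.8, 3238.5)

#' Default peak specifications for a simulated serum peptidome cohort
#'
#' Returns the planted signal structure the generator uses by default:
#' ten class-discriminative peaks whose class means follow the discovery
#' cohort's reported group averages and whose log-normal spread is
#' calibrated so each peak's two-class ROC AUC matches the reported
#' per-peak discovery AUC (under the log-normal model
#' `AUC = Phi(|ln r| / (sqrt(2) sigma))` for mean ratio `r`), plus
#' `n_nuisance` shared-mean peaks present in most spectra (these survive
#' a 50% presence filter but carry no class signal) and `n_rare`
#' low-presence background peaks (these exercise the presence-filter
#' funnel and are dropped by it).
#'
#' @param cv Log-normal coefficient of variation of the nuisance and
#'   background peaks (the discriminative peaks use their calibrated,
#'   AUC-matched cv).
#' @param n_nuisance Number of common, non-discriminative peaks (>= 0).
#' @param n_rare Number of low-presence background peaks (>= 0).
#' @param rare_presence Presence probability for background peaks.
#' @return A data.frame of [peak_spec()] rows with an extra logical column
#'   `discriminative`.
#' @export
default_peak_specs <- function(cv = 0.8, n_nuisance = 12, n_rare = 202,
                               rare_presence = 0.15) {
  stopifnot(n_nuisance >= 0, n_rare >= 0)
  disc <- do.call(rbind, lapply(seq_len(nrow(DISCRIMINATIVE_PEAKS)), function(i) {
    p <- DISCRIMINATIVE_PEAKS[i, ]
    peak_spec(p$mz, p$mean_case, p$mean_control,
              cv = calibrate_cv(p$mean_case, p$mean_control, p$auc))
  }))
  disc$discriminative <- TRUE
  specs <- disc
  taken <- specs$mz_center
  # deterministic, collision-free placement of background peaks on a
  # low-discrepancy sequence over the acquisition range
  place <- function(n, lo, hi) {
    if (n == 0) return(numeric())
    pos <- lo + ((seq_len(n) * 0.6180339887498949) %% 1) * (hi - lo)
    for (i in seq_along(pos)) {
      while (any(abs(pos[i] - taken) < 12)) pos[i] <- pos[i] + 13.7
      taken <<- c(taken, pos[i])
    }
    round(pos, 1)
  }
  if (n_nuisance > 0) {
    nuis <- do.call(rbind, lapply(place(n_nuisance, 1200, 9000), function(m) {
      peak_spec(m, 800, 800, cv = cv)
    }))
    nuis$discriminative <- FALSE
    specs <- rbind(specs, nuis)
  }
  if (n_rare > 0) {
    rare <- do.call(rbind, lapply(place(n_rare, 1050, 9800), function(m) {
      peak_spec(m, 400, 400, cv = cv,
                presence_case = rare_presence,
                presence_control = rare_presence)
    }))
    rare$discriminative <- FALSE
    specs <- rbind(specs, rare)
  }
  specs[order(specs$mz_center), , drop = FALSE]
}

#' Configuration of a simulated two-class spectral cohort
#'
#' Bundles everything [generate_cohort()] needs: cohort sizes, the m/z
#' acquisition grid, the planted peak structure, and the noise model
#' (additive baseline, Gaussian noise, per-spectrum total-ion-current
#' variation, and per-spectrum mass-calibration jitter).
#'
#' @param n_cases,n_controls Samples per class.
#' @param mz_min,mz_max Acquisition range (Th); default 1000-10000.
#' @param sampling_step Grid spacing (Th); default 1.
#' @param peak_specs Peak table as returned by [default_peak_specs()].
#' @param baseline_amplitude,baseline_decay Additive baseline
#'   `A * exp(-(mz - mz_min) / tau)`; amplitude in intensity units, decay
#'   constant tau in Th.
#' @param noise_sd Standard deviation of additive Gaussian point noise.
#' @param tic_variation_cv Coefficient of variation of the per-spectrum
#'   multiplicative intensity factor (log-normal, mean 1).
#' @param mz_jitter_max_rel Maximum relative per-spectrum mass shift;
#'   default 0.001 (0.1%), matching the alignment tolerance the downstream
#'   pipeline assumes.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 100, n_controls = 100,
                          mz_min = 1000, mz_max = 10000,
                          sampling_step = 1,
                          peak_specs = default_peak_specs(),
                          baseline_amplitude = 200, baseline_decay = 1500,
                          noise_sd = 10, tic_variation_cv = 0.15,
                          mz_jitter_max_rel = 0.001, seed = 1L) {
  num_ok <- function(x) length(x) == 1 && is.finite(x)
  if (!num_ok(n_cases) || !num_ok(n_controls) || n_cases < 0 || n_controls < 0) {
    stop("cohort sizes must be finite and non-negative", call. = FALSE)
  }
  if (!num_ok(mz_min) || !num_ok(mz_max) || mz_min >= mz_max) {
    stop("need mz_min < mz_max", call. = FALSE)
  }
  if (!num_ok(sampling_step) || sampling_step <= 0) {
    stop("sampling_step must be positive", call. = FALSE)
  }
  for (p in c("baseline_amplitude", "baseline_decay", "noise_sd",
              "tic_variation_cv", "mz_jitter_max_rel")) {
    v <- get(p)
    if (!num_ok(v) || v < 0) {
      stop(sprintf("%s must be finite and non-negative", p), call. = FALSE)
    }
  }
  if (baseline_decay == 0) baseline_decay <- 1  # degenerate: irrelevant when A = 0
  stopifnot(is.data.frame(peak_specs),
            all(c("mz_center", "mean_case", "mean_control", "cv",
                  "presence_case", "presence_control",
                  "width_sigma") %in% names(peak_specs)))
  if (any(peak_specs$mz_center < mz_min | peak_specs$mz_center > mz_max)) {
    stop("all peak centers must lie within [mz_min, mz_max]", call. = FALSE)
  }
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         mz_min = mz_min, mz_max = mz_max, sampling_step = sampling_step,
         peak_specs = peak_specs,
         baseline_amplitude = baseline_amplitude,
         baseline_decay = baseline_decay,
         noise_sd = noise_sd, tic_variation_cv = tic_variation_cv,
         mz_jitter_max_rel = mz_jitter_max_rel,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# run expr with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

rlnorm_mean_cv <- function(n, mean, cv) {
  if (mean == 0) return(rep(0, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a labelled two-class spectral cohort
#'
#' Each spectrum is the sum of the present peaks' Gaussian profiles (apex
#' heights log-normal around the class mean, per-peak Bernoulli presence),
#' an exponentially decaying baseline and additive Gaussian noise, all
#' scaled by a per-spectrum total-ion-current factor. Each spectrum's peak
#' positions are shifted by one uniform relative mass-calibration error
#' drawn in `[-mz_jitter_max_rel, +mz_jitter_max_rel]`. Identical
#' configurations (including the seed) give bit-identical output.
#'
#' @param config A [cohort_config()].
#' @param cohort_id Cohort identifier stored with the set.
#' @return An object of class `spectrum_set`: list with `spectra` (list of
#'   [spectrum()]), `labels` (`"case"`/`"control"`), `cohort_id`, and
#'   `truth` (the generating configuration, for parameter-recovery tests).
#' @examples
#' cfg <- cohort_config(n_cases = 2, n_controls = 2, mz_max = 3000,
#'                      peak_specs = default_peak_specs(n_rare = 0),
#'                      seed = 7)
#' set <- generate_cohort(cfg)
#' set$labels
#' @export
generate_cohort <- function(config, cohort_id = "discovery") {
  stopifnot(inherits(config, "cohort_config"))
  grid <- seq(config$mz_min, config$mz_max, by = config$sampling_step)
  specs <- config$peak_specs
  n <- config$n_cases + config$n_controls
  labels <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  ids <- sprintf("%s_%s_%03d", cohort_id,
                 ifelse(labels == "case", "case", "ctrl"),
                 c(seq_len(config$n_cases), seq_len(config$n_controls)))
  spectra <- with_seed(config$seed, {
    lapply(seq_len(n), function(i) {
      is_case <- labels[i] == "case"
      shift <- runif(1, -config$mz_jitter_max_rel, config$mz_jitter_max_rel)
      y <- config$baseline_amplitude *
        exp(-(grid - config$mz_min) / config$baseline_decay)
      pres_p <- if (is_case) specs$presence_case else specs$presence_control
      means <- if (is_case) specs$mean_case else specs$mean_control
      present <- rbinom(nrow(specs), 1, pres_p) == 1
      heights <- vapply(seq_len(nrow(specs)), function(j) {
        rlnorm_mean_cv(1, means[j], specs$cv[j])
      }, numeric(1))
      for (j in which(present & heights > 0)) {
        ctr <- specs$mz_center[j] * (1 + shift)
        sg <- specs$width_sigma[j]
        lo <- max(1L, findInterval(ctr - 6 * sg, grid))
        hi <- min(length(grid), findInterval(ctr + 6 * sg, grid) + 1L)
        idx <- lo:hi
        y[idx] <- y[idx] + heights[j] * exp(-(grid[idx] - ctr)^2 / (2 * sg^2))
      }
      if (config$noise_sd > 0) y <- y + rnorm(length(grid), 0, config$noise_sd)
      tic <- if (config$tic_variation_cv > 0) {
        rlnorm_mean_cv(1, 1, config$tic_variation_cv)
      } else 1
      spectrum(grid, pmax(y * tic, 0), sample_id = ids[i],
               processing_log = "simulated")
    })
  })
  structure(list(spectra = spectra, labels = labels,
                 cohort_id = cohort_id, truth = config),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %s: %d spectra (%d case / %d control)\n",
              x$cohort_id, length(x$spectra),
              sum(x$labels == "case"), sum(x$labels == "control")))
  invisible(x)
}

#' Write a spectrum set to disk
#'
#' Writes one two-column text file per spectrum plus a `manifest.csv`
#' naming them, in the on-disk contract [read_manifest()] consumes.
#'
#' @param set A `spectrum_set` from [generate_cohort()].
#' @param directory Output directory (created if missing).
#' @return The manifest data.frame, invisibly.
#' @export
write_cohort <- function(set, directory) {
  stopifnot(inherits(set, "spectrum_set"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(set$spectra))
  for (i in seq_along(set$spectra)) {
    s <- set$spectra[[i]]
    files[i] <- paste0(s$sample_id, ".txt")
    write_spectrum(s, file.path(directory, files[i]))
  }
  man <- data.frame(
    sample_id = vapply(set$spectra, `[[`, character(1), "sample_id"),
    label = set$labels, cohort = rep(set$cohort_id, length(files)),
    file = files, stringsAsFactors = FALSE)
  write.table(man, file.path(directory, "manifest.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  invisible(man)
}

#' Simulate a peak matrix with informative and redundant columns
#'
#' A matrix-level companion to [generate_cohort()] for studying stepwise
#' panel selection. Five informative peaks (the diagnostic-panel m/z
#' values, at the discovery-cohort intensity levels and tendencies) carry
#' independent effects through a planted linear logistic law: disease
#' status is drawn as `Bernoulli(plogis(b0 + sum(beta_j x_j)))` with
#' `beta_j` nonzero only for the informative peaks (sign = tendency,
#' magnitude `signal / sd(x_j)`). Five redundant peaks are noisy
#' multiples of the informative ones: they separate the classes
#' marginally but are conditionally independent of the outcome given
#' their parents, so a correct selection keeps only the informative
#' five. Exact class quotas are met by retrospective (case-control)
#' sampling from the planted law, which preserves the logistic form.
#'
#' @param n_cases,n_controls Samples per class.
#' @param redundancy_noise_cv Coefficient of variation of the
#'   multiplicative log-normal noise linking each redundant column to its
#'   informative parent.
#' @param signal Per-peak effect size in standard-deviation units of the
#'   linear predictor (|beta_j| * sd(x_j)).
#' @param cv Log-normal coefficient of variation of the peak intensities.
#' @param seed Integer seed.
#' @return A [peak_matrix][build_matrix()] whose `peaks` table carries a
#'   logical `informative` column (the ground truth).
#' @export
simulate_panel_matrix <- function(n_cases = 100, n_controls = 100,
                                  redundancy_noise_cv = 0.5, signal = 1,
                                  cv = 0.6, seed = 1L) {
  info <- DISCRIMINATIVE_PEAKS[DISCRIMINATIVE_PEAKS$mz %in% PANEL_MZ, ]
  red_mz <- c(1502.4, 2301.6, 2888.2, 3410.8, 4499.5)
  means <- (info$mean_case + info$mean_control) / 2
  sds <- means * cv
  beta <- ifelse(info$tendency == "up", 1, -1) * signal / sds
  b0 <- -sum(beta * means)
  sdlog_r <- sqrt(log1p(redundancy_noise_cv^2))
  out <- with_seed(seed, {
    xi_case <- NULL; xi_ctrl <- NULL
    while (is.null(xi_case) || nrow(xi_case) < n_cases ||
           nrow(xi_ctrl) < n_controls) {
      batch <- 2 * (n_cases + n_controls)
      xb <- sapply(seq_along(means), function(j) {
        rlnorm_mean_cv(batch, means[j], cv)
      })
      p <- 1 / (1 + exp(-(b0 + drop(xb %*% beta))))
      yb <- rbinom(batch, 1, p) == 1
      xi_case <- rbind(xi_case, xb[yb, , drop = FALSE])
      xi_ctrl <- rbind(xi_ctrl, xb[!yb, , drop = FALSE])
    }
    xi <- rbind(xi_case[seq_len(n_cases), , drop = FALSE],
                xi_ctrl[seq_len(n_controls), , drop = FALSE])
    xr <- sapply(seq_along(means), function(j) {
      xi[, j] * rlnorm(nrow(xi), -sdlog_r^2 / 2, sdlog_r)
    })
    cbind(xi, xr)
  })
  n <- n_cases + n_controls
  labels <- rep(c("case", "control"), c(n_cases, n_controls))
  mzs <- c(info$mz, red_mz)
  ord <- order(mzs)
  X <- out[, ord, drop = FALSE]
  mzs <- mzs[ord]
  peaks <- data.frame(mz_ref = mzs, n_present = n, presence_frac = 1,
                      informative = rep(c(TRUE, FALSE), each = 5)[ord])
  new_peak_matrix(X,
                  sample_ids = sprintf("sim_%03d", seq_len(n)),
                  labels = labels, peaks = peaks, cohort_id = "simulated")
}
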